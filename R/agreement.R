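#' Mean visual score from marginal count tables
#'
#' Visual image quality is scored per patient on a four-point scale
#' (0 non-diagnostic, 1 poor, 2 moderate, 3 good) by each reader; published
#' reader studies report the per-reader counts at each score level. The mean
#' score for a condition is the rating-weighted mean over all readers:
#' `sum(score * count) / sum(count)`.
#'
#' @param marginals Tibble with columns `reader`, `score`, `count`, and
#'   optionally `condition`. With a `condition` column, one mean per
#'   condition is returned.
#' @param n_patients If given, each reader's counts must sum to this number
#'   of patients (consistency check on transcribed fixtures).
#' @return A tibble with columns `condition` (if present) and `mean_score`.
#' @export
mean_visual_score <- function(marginals, n_patients = NULL) {
  m <- tibble::as_tibble(marginals)
  need <- c("reader", "score", "count")
  if (!all(need %in% names(m))) {
    stop("`marginals` needs columns reader, score, count", call. = FALSE)
  }
  if (!all(m$score %in% 0:3)) stop("scores must be in 0..3", call. = FALSE)
  if (any(m$count < 0)) stop("counts must be >= 0", call. = FALSE)
  grouping <- intersect("condition", names(m))
  if (!is.null(n_patients)) {
    totals <- m |>
      dplyr::summarise(total = sum(.data$count),
                       .by = dplyr::all_of(c(grouping, "reader")))
    if (!all(totals$total == n_patients)) {
      stop("inconsistent fixture: reader counts do not sum to `n_patients`",
           call. = FALSE)
    }
  }
  m |>
    dplyr::summarise(
      mean_score = sum(.data$score * .data$count) / sum(.data$count),
      .by = dplyr::all_of(grouping)
    )
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `kappa = (po - pe) / (1 - pe)` from the joint
#' contingency table of two raters' categorical scores, with `po` the
#' observed diagonal fraction and `pe` the expected agreement from the
#' marginal distributions. Unweighted.
#'
#' @param joint Square numeric matrix: rows = rater 1 categories, columns =
#'   rater 2 categories; or a data frame / tibble with two rating columns,
#'   which is tabulated first.
#' @return A `cohens_kappa` object (fields `kappa`, `p_observed`,
#'   `p_expected`, `n`); use [generics::tidy()] for a tibble.
#' @export
cohens_kappa <- function(joint) {
  if (is.data.frame(joint)) {
    if (ncol(joint) != 2) stop("rating data frame must have two columns", call. = FALSE)
    lev <- sort(unique(c(joint[[1]], joint[[2]])))
    joint <- table(factor(joint[[1]], lev), factor(joint[[2]], lev))
  }
  joint <- as.matrix(joint)
  if (nrow(joint) != ncol(joint)) stop("`joint` must be square", call. = FALSE)
  n <- sum(joint)
  if (n <= 0) stop("`joint` must have a positive total", call. = FALSE)
  p <- joint / n
  po <- sum(diag(p))
  pe <- sum(rowSums(p) * colSums(p))
  if (1 - pe < .Machine$double.eps^0.5) {
    stop("kappa undefined: degenerate margins (pe = 1)", call. = FALSE)
  }
  structure(list(kappa = (po - pe) / (1 - pe), p_observed = po,
                 p_expected = pe, n = n),
            class = "cohens_kappa")
}

#' @export
print.cohens_kappa <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.4f (po = %.3f, pe = %.3f, n = %d)\n",
              x$kappa, x$p_observed, x$p_expected, x$n))
  invisible(x)
}

#' Intraclass correlation ICC(A,1)
#'
#' Two-way mixed-effects, absolute-agreement, single-rater intraclass
#' correlation from the two-way ANOVA decomposition:
#' `ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`
#' with `MSR` the between-subject, `MSC` the between-rater and `MSE` the
#' residual mean squares. The confidence interval is the standard F-based
#' interval with Satterthwaite degrees of freedom.
#'
#' @param ratings Numeric matrix or data frame, `n` subjects x `k` raters,
#'   no missing cells.
#' @param conf_level Confidence level for the interval.
#' @return An `icc` object (fields `icc`, `conf_low`, `conf_high`, mean
#'   squares, `n`, `k`); use [generics::tidy()] for a tibble.
#' @export
icc_absolute_single <- function(ratings, conf_level = 0.95) {
  x <- as.matrix(ratings)
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 raters", call. = FALSE)
  if (anyNA(x)) stop("missing cells are not supported", call. = FALSE)
  gm <- mean(x)
  rowm <- rowMeans(x); colm <- colMeans(x)
  MSR <- k * sum((rowm - gm)^2) / (n - 1)
  MSC <- n * sum((colm - gm)^2) / (k - 1)
  SSE <- sum((x - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + gm)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
  if (abs(denom) < .Machine$double.eps) {
    stop("ICC undefined: zero total variance", call. = FALSE)
  }
  icc <- (MSR - MSE) / denom
  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- qf(1 - alpha / 2, n - 1, v)
  FU <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  structure(list(icc = icc, conf_low = lower, conf_high = upper,
                 conf_level = conf_level,
                 MSR = MSR, MSC = MSC, MSE = MSE, n = n, k = k),
            class = "icc")
}

#' @export
print.icc <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.4f (%.0f%% CI %.4f-%.4f), n = %d subjects, k = %d raters\n",
              x$icc, 100 * x$conf_level, x$conf_low, x$conf_high, x$n, x$k))
  invisible(x)
}

#' Lesion detectability relative to a reference condition
#'
#' Fraction of reference lesions still detected under a test condition, per
#' reader (`100 * detected / reference`) and pooled over readers
#' (`100 * sum(detected) / sum(reference)`).
#'
#' @param counts Tibble with columns `reader`, `condition`,
#'   `lesions_detected`.
#' @param condition Condition label to evaluate.
#' @param reference_condition Label of the reference condition.
#' @return Tibble with columns `reader` (reader id or `"pooled"`),
#'   `detected`, `reference`, `detectability_pct`.
#' @export
detectability_fraction <- function(counts, condition, reference_condition) {
  ct <- tibble::as_tibble(counts)
  need <- c("reader", "condition", "lesions_detected")
  if (!all(need %in% names(ct))) {
    stop("`counts` needs columns reader, condition, lesions_detected", call. = FALSE)
  }
  test <- dplyr::filter(ct, .data$condition == !!condition)
  ref <- dplyr::filter(ct, .data$condition == !!reference_condition)
  if (nrow(ref) == 0 || any(ref$lesions_detected <= 0)) {
    stop("reference condition missing or has zero lesions", call. = FALSE)
  }
  per <- dplyr::inner_join(
    dplyr::select(test, "reader", detected = "lesions_detected"),
    dplyr::select(ref, "reader", reference = "lesions_detected"),
    by = "reader"
  )
  if (nrow(per) == 0) stop("no matching readers between conditions", call. = FALSE)
  pooled <- tibble::tibble(
    reader = "pooled",
    detected = sum(per$detected),
    reference = sum(per$reference)
  )
  dplyr::bind_rows(dplyr::mutate(per, reader = as.character(.data$reader)), pooled) |>
    dplyr::mutate(detectability_pct = 100 * .data$detected / .data$reference)
}

#' Reader visual-score fixture
#'
#' Marginal visual-score counts for two readers and 25 patients across the
#' four conditions of the reader study (activity reduction plus its optimal
#' penalisation factor), transcribed from the published reader-study table.
#'
#' @return Tibble: `condition`, `reduction_pct`, `beta`, `reader`, `score`,
#'   `count`.
#' @export
reader_scores_fixture <- function() {
  path <- system.file("extdata", "table2_scores.csv", package = "petiq",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
}

#' Reader lesion-count fixture
#'
#' Total lesions detected per reader and condition in the reader study,
#' transcribed from the published lesion-detectability table. The reference
#' condition is 0% reduction at penalisation factor 300.
#'
#' @return Tibble: `condition`, `reduction_pct`, `beta`, `reader`,
#'   `lesions_detected`.
#' @export
lesion_counts_fixture <- function() {
  path <- system.file("extdata", "table3_lesions.csv", package = "petiq",
                      mustWork = TRUE)
  fix <- utils::read.csv(path, comment.char = "#")
  fix$reader <- as.character(fix$reader)
  tibble::as_tibble(fix)
}
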