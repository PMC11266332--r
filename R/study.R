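#' Run the phantom image-quality grid
#'
#' Full phantom pipeline over the cartesian product of activity reductions
#' and penalisation factors: simulate the acquisition, thin counts to emulate
#' each reduction, apply the beta noise-suppression surrogate, measure sphere
#' and background VOIs, and compute contrast recovery, background variability
#' and contrast-to-noise per sphere. Deterministic for a given seed.
#'
#' @param spec A [nema_phantom_spec()].
#' @param acq An [acquisition_config()].
#' @param betas Penalisation factors.
#' @param reductions Activity-reduction fractions in `[0, 1)`.
#' @param sigma_ref_mm Surrogate smoothing width at beta 300.
#' @param seed Base seed for the Poisson draw and per-reduction thinning.
#' @param voxel_size,dim Grid passed to [build_nema_phantom()].
#' @return A `phantom_grid` tibble: one row per
#'   (reduction, beta, sphere) with columns `ratio`, `reduction_pct`,
#'   `beta`, `sphere_diameter_mm`, `cr`, `bv`, `cnr`.
#' @export
run_phantom_grid <- function(spec, acq,
                             betas = c(150, 300, 450, 600),
                             reductions = c(0, 0.17, 0.33, 0.50, 0.67),
                             sigma_ref_mm = 3, seed = 1L,
                             voxel_size = c(2.34, 2.34, 2.78), dim = NULL) {
  truth <- build_nema_phantom(spec, voxel_size = voxel_size, dim = dim)
  acq$seed <- as.integer(seed)
  counts0 <- simulate_acquisition(truth, acq)
  sphere_vois <- lapply(seq_along(spec$sphere_diameters), function(i) {
    make_sphere_voi(truth, spec$sphere_centers[i, ], spec$sphere_diameters[i])
  })
  bg_vois <- place_background_vois(spec, truth)
  aH <- spec$activities$spheres
  aB <- spec$activities$background

  rows <- purrr::map(seq_along(reductions), function(ri) {
    r <- reductions[ri]
    counts <- thin_counts(counts0, r, seed = as.integer(seed) + ri)
    conc <- counts_to_concentration(counts)
    purrr::map(betas, function(b) {
      img <- beta_smooth(conc, b, sigma_ref_mm = sigma_ref_mm)
      bg_stats <- purrr::map_dfr(bg_vois, ~ voi_stats(img, .x))
      bv <- background_variability(bg_stats)
      ch <- vapply(sphere_vois, function(v) voi_stats(img, v)$mean, numeric(1))
      cb <- mean(bg_stats$mean)
      cr <- contrast_recovery(ch, cb, aH, aB)
      tibble::tibble(
        ratio = spec$ratio,
        reduction_pct = round(100 * r),
        beta = b,
        sphere_diameter_mm = spec$sphere_diameters,
        cr = cr, bv = bv, cnr = cnr(cr, bv)
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  class(rows) <- c("phantom_grid", class(rows))
  attr(rows, "seed") <- as.integer(seed)
  rows
}

#' Run the synthetic patient grid
#'
#' Per patient and condition: simulate, thin, smooth, convert back to SUV and
#' measure the fixed 3 cm liver VOI and the half-maximum lesion VOIs. Lesion
#' and liver VOIs are constructed once on the reference reconstruction and
#' frozen across all conditions, as in clinical reading.
#'
#' @param specs A [patient_spec()] or list of them.
#' @param acq An [acquisition_config()].
#' @param betas,reductions Study grid.
#' @param reference Named list giving the reference condition
#'   (`reduction_pct`, `beta`) used to freeze lesion VOIs.
#' @param sigma_ref_mm Surrogate smoothing width at beta 300.
#' @param seed Base seed.
#' @param voxel_size,dim Grid passed to [build_patient_volume()].
#' @return A `patient_grid` tibble: one row per
#'   (patient, reduction, beta, lesion) with liver noise, lesion SUVmax,
#'   SNR (NA with `snr_defined = FALSE` in the zero-noise limit) and SBR.
#' @export
run_patient_grid <- function(specs, acq,
                             betas = c(150, 300, 450, 600),
                             reductions = c(0, 0.17, 0.33, 0.50, 0.67),
                             reference = list(reduction_pct = 0, beta = 300),
                             sigma_ref_mm = 3, seed = 1L,
                             voxel_size = c(2.34, 2.34, 2.78), dim = NULL) {
  if (inherits(specs, "patient_spec")) specs <- list(specs)
  ref_r <- reference$reduction_pct / 100

  out <- purrr::imap(specs, function(spec, pi) {
    pid <- if (is.null(names(specs))) paste0("patient", pi) else names(specs)[pi]
    truth <- build_patient_volume(spec, voxel_size = voxel_size, dim = dim,
                                  psf_fwhm_mm = acq$psf_fwhm_mm)
    conc <- activity_volume(
      truth$data * spec$injected_MBq / spec$weight_kg,
      truth$spacing, truth$origin, units = "kBq/ml"
    )
    acq$seed <- as.integer(seed) + 1000L * as_index(pi)
    counts0 <- simulate_acquisition(conc, acq)
    to_suv <- function(img) {
      activity_volume(
        suv_from_concentration(img$data, spec$injected_MBq, spec$weight_kg),
        img$spacing, img$origin, units = "SUV"
      )
    }
    recon <- function(r, b) {
      counts <- thin_counts(counts0, r, seed = acq$seed + round(100 * r))
      to_suv(beta_smooth(counts_to_concentration(counts), b,
                         sigma_ref_mm = sigma_ref_mm))
    }
    liver_voi <- make_sphere_voi(truth, spec$liver_voi_center, 30)
    ref_img <- recon(ref_r, reference$beta)
    lesion_vois <- lapply(seq_len(nrow(spec$lesions)), function(i) {
      threshold_lesion_voi(
        ref_img, c(spec$lesions$x[i], spec$lesions$y[i], spec$lesions$z[i]),
        liver_voi = liver_voi
      )
    })

    grid <- tidyr::expand_grid(r = reductions, beta = betas)
    purrr::pmap(grid, function(r, beta) {
      img <- recon(r, beta)
      ls <- voi_stats(img, liver_voi)
      noise <- liver_noise(ls$sd, ls$mean)
      suvmax <- vapply(lesion_vois, function(v) max(img$data[v$mask]), numeric(1))
      tibble::tibble(
        patient = pid,
        reduction_pct = round(100 * r),
        beta = beta,
        lesion_id = seq_along(suvmax),
        diameter_mm = spec$lesions$diameter_mm,
        liver_suvmean = ls$mean,
        liver_noise = noise,
        lesion_suvmax = suvmax,
        snr_defined = noise > 0,
        lesion_snr = ifelse(noise > 0, suvmax / noise, NA_real_),
        lesion_sbr = lesion_sbr(suvmax, ls$mean)
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  class(out) <- c("patient_grid", class(out))
  attr(out, "seed") <- as.integer(seed)
  attr(out, "reference") <- reference
  out
}

as_index <- function(i) if (is.character(i)) match(i, i) else as.integer(i)

#' Step-1 selection of the optimal penalisation factor per reduction
#'
#' For each activity-reduction level, a penalisation factor is eligible when
#' every single rating is at least `score_threshold` (sufficient visual
#' image quality) and pooled lesion detectability against the reference
#' condition exceeds `detectability_threshold` percent. Among eligible
#' factors, the one whose mean lesion SUVmax is closest to the reference
#' SUVmax is selected (smallest factor on ties). Reductions with no eligible
#' factor are flagged.
#'
#' @param scores Long tibble: `patient`, `reader`, `reduction_pct`, `beta`,
#'   `score`.
#' @param lesions Tibble: `reduction_pct`, `beta`, `lesions_detected`
#'   (totals; may also carry `reader` rows, which are summed).
#' @param suvmax Tibble: `reduction_pct`, `beta`, `mean_suvmax`.
#' @param reference_suvmax Reference (comparison-scanner) mean lesion SUVmax.
#' @param reference Named list: the reference condition for detectability.
#' @param score_threshold Minimum acceptable rating (inclusive).
#' @param detectability_threshold Detectability must strictly exceed this
#'   percentage.
#' @return A `beta_selection` object: `$eligibility` (one row per condition)
#'   and `$optimal` (one row per reduction, `beta = NA` when none eligible).
#' @export
select_optimal_beta <- function(scores, lesions, suvmax, reference_suvmax,
                                reference = list(reduction_pct = 0, beta = 300),
                                score_threshold = 2,
                                detectability_threshold = 90) {
  scores <- tibble::as_tibble(scores)
  lesions <- tibble::as_tibble(lesions)
  suvmax <- tibble::as_tibble(suvmax)

  conds <- dplyr::distinct(scores, .data$reduction_pct, .data$beta)
  full_grid <- tidyr::expand_grid(
    reduction_pct = unique(scores$reduction_pct),
    beta = unique(scores$beta)
  )
  if (nrow(dplyr::anti_join(full_grid, conds,
                            by = c("reduction_pct", "beta"))) > 0) {
    stop("scores are missing conditions from the reduction x beta grid",
         call. = FALSE)
  }

  det_tot <- lesions |>
    dplyr::summarise(detected = sum(.data$lesions_detected),
                     .by = c("reduction_pct", "beta"))
  ref_det <- det_tot |>
    dplyr::filter(.data$reduction_pct == reference$reduction_pct,
                  .data$beta == reference$beta)
  if (nrow(ref_det) != 1 || ref_det$detected <= 0) {
    stop("reference condition missing from `lesions` or has no lesions",
         call. = FALSE)
  }

  elig <- scores |>
    dplyr::summarise(
      min_score = min(.data$score),
      all_scores_ok = all(.data$score >= score_threshold),
      .by = c("reduction_pct", "beta")
    ) |>
    dplyr::left_join(det_tot, by = c("reduction_pct", "beta")) |>
    dplyr::mutate(
      detectability_pct = 100 * .data$detected / ref_det$detected,
      detectability_ok = .data$detectability_pct > detectability_threshold,
      eligible = .data$all_scores_ok & .data$detectability_ok
    ) |>
    dplyr::left_join(suvmax, by = c("reduction_pct", "beta")) |>
    dplyr::mutate(suvmax_diff = abs(.data$mean_suvmax - reference_suvmax))

  optimal <- elig |>
    dplyr::arrange(.data$reduction_pct, .data$suvmax_diff, .data$beta) |>
    dplyr::summarise(
      n_eligible = sum(.data$eligible),
      beta = if (any(.data$eligible)) .data$beta[.data$eligible][1] else NA_real_,
      suvmax_diff = if (any(.data$eligible)) .data$suvmax_diff[.data$eligible][1] else NA_real_,
      .by = "reduction_pct"
    ) |>
    dplyr::arrange(.data$reduction_pct)

  structure(list(eligibility = elig, optimal = optimal),
            class = "beta_selection",
            reference = reference,
            reference_suvmax = reference_suvmax,
            thresholds = list(score = score_threshold,
                              detectability = detectability_threshold))
}

#' @export
print.beta_selection <- function(x, ...) {
  cat("Optimal penalisation factor per activity reduction:\n")
  print(x$optimal)
  invisible(x)
}

#' Friedman chi-squared statistic
#'
#' Classic (untied) Friedman statistic
#' `12 / (n k (k+1)) * sum(Rj^2) - 3 n (k+1)` from within-subject average
#' ranks, with `Rj` the column rank sums.
#'
#' @param x Numeric matrix, `n` subjects x `k` conditions.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
friedman_statistic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 conditions", call. = FALSE)
  ranks <- t(apply(x, 1, rank))
  Rj <- colSums(ranks)
  stat <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  list(statistic = stat, df = k - 1,
       p_value = pchisq(stat, df = k - 1, lower.tail = FALSE))
}

#' Compare conditions with a reference, with a normality gate
#'
#' The standard paired design: each subject is measured under every
#' condition. Every condition group is first tested for normality
#' (Shapiro-Wilk). If all groups pass, a repeated-measures ANOVA is run
#' (Greenhouse-Geisser corrected when Mauchly's sphericity test rejects)
#' followed by Dunnett's test of each condition against the reference.
#' Otherwise a Friedman test is run followed by Dunn's multiple-comparison
#' test against the reference.
#'
#' @param data Long data frame.
#' @param value,subject,condition Bare column names (tidy evaluation).
#' @param reference Reference condition label.
#' @param alpha Significance level for the gate, sphericity test and flags.
#' @return A `ref_comparison` object; [generics::tidy()] gives the
#'   per-condition comparisons, [generics::glance()] the omnibus test.
#' @export
compare_to_reference <- function(data, value, subject, condition, reference,
                                 alpha = 0.05) {
  df <- tibble::tibble(
    value = dplyr::pull(data, {{ value }}),
    subject = as.character(dplyr::pull(data, {{ subject }})),
    condition = as.character(dplyr::pull(data, {{ condition }}))
  )
  reference <- as.character(reference)
  conds <- unique(df$condition)
  if (!reference %in% conds) stop("`reference` not among conditions", call. = FALSE)
  wide <- tidyr::pivot_wider(df, names_from = "condition", values_from = "value")
  x <- as.matrix(wide[, conds, drop = FALSE])
  n <- nrow(x); k <- ncol(x)
  if (n < 3) stop("insufficient data: need >= 3 subjects", call. = FALSE)
  if (anyNA(x)) stop("unbalanced design: every subject needs every condition",
                     call. = FALSE)

  gate <- tibble::tibble(
    condition = conds,
    shapiro_p = apply(x, 2, function(col) {
      if (sd(col) == 0) return(0)  # degenerate: treat as non-normal
      stats::shapiro.test(col)$p.value
    })
  ) |> dplyr::mutate(normal = .data$shapiro_p > alpha)

  others <- setdiff(conds, reference)
  if (all(gate$normal)) {
    res <- rm_anova_dunnett(x, conds, reference, alpha)
  } else {
    res <- friedman_dunn(x, conds, reference)
  }
  comparisons <- res$comparisons |>
    dplyr::mutate(significant = .data$p_adj <= alpha)
  structure(list(
    method = res$method, gate = gate,
    statistic = res$statistic, df = res$df, p_value = res$p_value,
    epsilon = res$epsilon, mauchly_p = res$mauchly_p,
    comparisons = comparisons,
    reference = reference, alpha = alpha, n = n, k = k
  ), class = "ref_comparison")
}

rm_anova_dunnett <- function(x, conds, reference, alpha) {
  n <- nrow(x); k <- ncol(x)
  gm <- mean(x); rowm <- rowMeans(x); colm <- colMeans(x)
  names(colm) <- conds
  MSC <- n * sum((colm - gm)^2) / (k - 1)
  SSE <- sum((x - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + gm)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  others <- setdiff(conds, reference)
  tol <- 1e-10 * (stats::var(as.vector(x)) + .Machine$double.xmin)
  if (MSE < tol) {
    # zero within-subject residual: identical columns (no differences) or
    # exactly reproduced shifts (certain differences); no noise to test against
    est <- colm[others] - colm[reference]
    comparisons <- tibble::tibble(
      condition = others, estimate = as.numeric(est),
      statistic = ifelse(est == 0, 0, Inf),
      p_adj = ifelse(est == 0, 1, 0)
    )
    return(list(method = "rm_anova",
                statistic = if (MSC < tol) 0 else Inf,
                df = c(df1, df2),
                p_value = if (MSC < tol) 1 else 0,
                epsilon = 1, mauchly_p = NA_real_, comparisons = comparisons))
  }
  Fstat <- MSC / MSE
  mauchly_p <- tryCatch({
    fit <- stats::lm(x ~ 1)
    suppressWarnings(stats::mauchly.test(fit, X = ~1)$p.value)
  }, error = function(e) NA_real_)
  eps <- 1
  if (is.finite(mauchly_p) && mauchly_p < alpha) {
    S <- stats::cov(x)
    D <- diag(k) - matrix(1 / k, k, k)
    SD <- D %*% S %*% D
    eps <- sum(diag(SD))^2 / ((k - 1) * sum(SD * SD))
  }
  p <- stats::pf(Fstat, eps * df1, eps * df2, lower.tail = FALSE)

  long <- data.frame(
    value = as.vector(x),
    subject = factor(rep(seq_len(n), times = k)),
    condition = stats::relevel(factor(rep(conds, each = n), levels = conds),
                               ref = reference)
  )
  fit <- lme4::lmer(value ~ condition + (1 | subject), data = long,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(condition = "Dunnett"))
  sm <- summary(gl)
  lab <- sub(" - .*$", "", names(sm$test$coefficients))
  comparisons <- tibble::tibble(
    condition = lab,
    estimate = as.numeric(sm$test$coefficients),
    statistic = as.numeric(sm$test$tstat),
    p_adj = as.numeric(sm$test$pvalues)
  )
  list(method = "rm_anova", statistic = Fstat, df = c(df1, df2), p_value = p,
       epsilon = eps, mauchly_p = mauchly_p, comparisons = comparisons)
}

friedman_dunn <- function(x, conds, reference) {
  n <- nrow(x); k <- ncol(x)
  fr <- friedman_statistic(x)
  ranks <- t(apply(x, 1, rank))
  mean_ranks <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (6 * n))
  others <- setdiff(conds, reference)
  z <- (mean_ranks[others] - mean_ranks[reference]) / se
  p_adj <- pmin(1, (k - 1) * 2 * stats::pnorm(-abs(z)))
  comparisons <- tibble::tibble(
    condition = others,
    estimate = mean_ranks[others] - mean_ranks[reference],
    statistic = as.numeric(z),
    p_adj = as.numeric(p_adj)
  )
  list(method = "friedman", statistic = fr$statistic, df = fr$df,
       p_value = fr$p_value, epsilon = NA_real_, mauchly_p = NA_real_,
       comparisons = comparisons)
}

#' @export
print.ref_comparison <- function(x, ...) {
  cat(sprintf("%s vs reference '%s': statistic = %.4g, p = %.4g\n",
              x$method, x$reference, x$statistic, x$p_value))
  print(x$comparisons)
  invisible(x)
}

#' Final activity-reduction recommendation
#'
#' The recommended condition is the largest activity reduction whose selected
#' penalisation factor shows neither a significantly lower mean visual score
#' nor significantly lower lesion detectability than the reference condition.
#' Falls back to the reference when nothing qualifies.
#'
#' @param selection A [select_optimal_beta()] result.
#' @param score_tests,detectability_tests Tibbles with columns
#'   `reduction_pct` and `significant` (TRUE when significantly worse than
#'   the reference).
#' @return A `dose_recommendation` tibble with one row: `reduction_pct`,
#'   `beta`, `reason`.
#' @export
final_recommendation <- function(selection, score_tests, detectability_tests) {
  stopifnot(inherits(selection, "beta_selection"))
  ref <- attr(selection, "reference")
  score_tests <- tibble::as_tibble(score_tests)
  detectability_tests <- tibble::as_tibble(detectability_tests)

  cand <- selection$optimal |>
    dplyr::filter(!is.na(.data$beta),
                  .data$reduction_pct != ref$reduction_pct) |>
    dplyr::left_join(
      dplyr::select(score_tests, "reduction_pct", score_sig = "significant"),
      by = "reduction_pct") |>
    dplyr::left_join(
      dplyr::select(detectability_tests, "reduction_pct", det_sig = "significant"),
      by = "reduction_pct") |>
    dplyr::filter(!is.na(.data$score_sig), !is.na(.data$det_sig),
                  !.data$score_sig, !.data$det_sig)

  if (nrow(cand) == 0) {
    out <- tibble::tibble(
      reduction_pct = ref$reduction_pct, beta = ref$beta,
      reason = "no reduction preserved both visual score and detectability; reference retained"
    )
  } else {
    best <- cand[which.max(cand$reduction_pct), ]
    out <- tibble::tibble(
      reduction_pct = best$reduction_pct, beta = best$beta,
      reason = sprintf(
        "largest reduction with no significant loss in visual score or detectability (eligible factors: %d)",
        best$n_eligible
      )
    )
  }
  class(out) <- c("dose_recommendation", class(out))
  out
}

#' Synthetic step-1 reader fixture
#'
#' A synthetic single-reader table for five patients over the full
#' reduction x beta grid, constructed so that the per-reduction eligibility
#' pattern matches the study design it emulates: at 17% reduction factors
#' >= 300 are eligible, at 33% factors >= 450, at 50% only factor 600, and at
#' 67% none (detectability below threshold); mean lesion SUVmax decreases
#' with beta so that the SUVmax tie-break selects 450, 450 and 600
#' respectively. Used to exercise [select_optimal_beta()].
#'
#' @return List with elements `scores`, `lesions`, `suvmax`,
#'   `reference_suvmax`.
#' @export
step1_fixture <- function() {
  reductions <- c(0, 17, 33, 50, 67)
  betas <- c(150, 300, 450, 600)
  patients <- paste0("p", 1:5)
  grid <- tidyr::expand_grid(reduction_pct = reductions, beta = betas,
                             patient = patients)
  scores <- grid |>
    dplyr::mutate(
      reader = "A",
      score = dplyr::case_when(
        beta == 150 & patient == "p1" ~ 1,
        reduction_pct == 33 & beta == 300 & patient == "p2" ~ 1,
        reduction_pct == 50 & beta <= 450 & patient == "p2" ~ 1,
        reduction_pct == 67 & patient == "p3" ~ 1,
        reduction_pct >= 33 & patient == "p4" ~ 2,
        TRUE ~ 3
      )
    )
  # reference reader total: 17 lesions over five patients
  lesions <- tidyr::expand_grid(reduction_pct = reductions, beta = betas) |>
    dplyr::mutate(
      reader = "A",
      lesions_detected = dplyr::case_when(
        reduction_pct == 0 ~ 17L,
        reduction_pct == 17 ~ 17L,
        reduction_pct == 33 & beta >= 450 ~ 16L,
        reduction_pct == 33 ~ 14L,
        reduction_pct == 50 & beta == 600 ~ 16L,
        reduction_pct == 50 ~ 15L,
        TRUE ~ 15L  # 67%: 15/17 = 88% < 90%
      )
    )
  suvmax <- tidyr::expand_grid(reduction_pct = reductions, beta = betas) |>
    dplyr::mutate(mean_suvmax = c(`150` = 20.0, `300` = 17.0,
                                  `450` = 15.5, `600` = 14.7)[as.character(.data$beta)])
  list(scores = scores, lesions = lesions, suvmax = suvmax,
       reference_suvmax = 15.4)
}
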