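#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.cohens_kappa <- function(x, ...) {
  tibble::tibble(estimate = x$kappa, p_observed = x$p_observed,
                 p_expected = x$p_expected, n = x$n)
}

#' @export
tidy.icc <- function(x, ...) {
  tibble::tibble(estimate = x$icc, conf.low = x$conf_low,
                 conf.high = x$conf_high, conf.level = x$conf_level)
}

#' @export
glance.icc <- function(x, ...) {
  tibble::tibble(icc = x$icc, MSR = x$MSR, MSC = x$MSC, MSE = x$MSE,
                 n = x$n, k = x$k)
}

#' @export
tidy.ref_comparison <- function(x, ...) x$comparisons

#' @export
glance.ref_comparison <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 p.value = x$p_value, epsilon = x$epsilon,
                 mauchly_p = x$mauchly_p, n = x$n, k = x$k,
                 reference = x$reference)
}

#' @export
tidy.beta_selection <- function(x, ...) x$eligibility

#' @export
glance.beta_selection <- function(x, ...) x$optimal
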