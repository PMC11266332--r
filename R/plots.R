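#' Plot phantom image-quality trends
#'
#' Background variability and mean contrast-to-noise ratio against the
#' penalisation factor, one line per activity-reduction level.
#'
#' @param object A `phantom_grid` from [run_phantom_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phantom_grid <- function(object, ...) {
  summ <- object |>
    dplyr::summarise(BV = .data$bv[1], `mean CNR` = mean(.data$cnr),
                     .by = c("reduction_pct", "beta")) |>
    tidyr::pivot_longer(c("BV", "mean CNR"), names_to = "metric")
  ggplot2::ggplot(summ, ggplot2::aes(
    x = .data$beta, y = .data$value,
    colour = factor(.data$reduction_pct), group = .data$reduction_pct
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = expression(beta), y = NULL,
                  colour = "reduction (%)") +
    ggplot2::theme_minimal()
}

#' Plot patient image-quality metrics
#'
#' Box plots of liver noise, lesion SNR, SBR and SUVmax by condition.
#'
#' @param object A `patient_grid` from [run_patient_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.patient_grid <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(c("liver_noise", "lesion_snr", "lesion_sbr",
                          "lesion_suvmax"),
                        names_to = "metric") |>
    dplyr::filter(is.finite(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$beta), y = .data$value,
    fill = factor(.data$reduction_pct)
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = expression(beta), y = NULL, fill = "reduction (%)") +
    ggplot2::theme_minimal()
}

#' Plot the beta-selection eligibility map
#'
#' Tile map of the reduction x beta grid showing eligibility and the
#' selected factor per reduction.
#'
#' @param object A `beta_selection` from [select_optimal_beta()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.beta_selection <- function(object, ...) {
  el <- object$eligibility
  opt <- dplyr::filter(object$optimal, !is.na(.data$beta))
  ggplot2::ggplot(el, ggplot2::aes(
    x = factor(.data$beta), y = factor(.data$reduction_pct),
    fill = .data$eligible
  )) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_point(data = opt, ggplot2::aes(
      x = factor(.data$beta), y = factor(.data$reduction_pct)
    ), inherit.aes = FALSE, shape = 8, size = 3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8", `FALSE` = "grey85")) +
    ggplot2::labs(x = expression(beta), y = "activity reduction (%)",
                  fill = "eligible") +
    ggplot2::theme_minimal()
}
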