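#' Contrast recovery
#'
#' `CR = (CH/CB - 1) / (aH/aB - 1)`, where `CH` and `CB` are the measured
#' mean values in the sphere and background VOIs and `aH`, `aB` the true
#' filled activities. 1 means perfect recovery; partial-volume effects push
#' small spheres below 1.
#'
#' @param CH,CB Measured sphere and background VOI means (CB > 0).
#' @param aH,aB True sphere and background activities (aB > 0, aH != aB).
#' @return Contrast recovery (dimensionless). Vectorised over `CH`.
#' @export
contrast_recovery <- function(CH, CB, aH, aB) {
  if (any(CB <= 0)) stop("`CB` must be > 0", call. = FALSE)
  if (any(aB <= 0)) stop("`aB` must be > 0", call. = FALSE)
  if (any(aH == aB)) stop("undefined contrast: `aH` equals `aB`", call. = FALSE)
  (CH / CB - 1) / (aH / aB - 1)
}

#' Background variability
#'
#' Noise metric: mean over background VOIs of the per-VOI coefficient of
#' variation (sample SD divided by mean).
#'
#' @param bg_stats Data frame of background [voi_stats()] rows (columns
#'   `mean`, `sd`), one per VOI.
#' @return Background variability (dimensionless).
#' @export
background_variability <- function(bg_stats) {
  bg_stats <- tibble::as_tibble(bg_stats)
  if (nrow(bg_stats) < 1) stop("need at least one background VOI", call. = FALSE)
  if (any(bg_stats$mean <= 0)) stop("background VOI mean must be > 0", call. = FALSE)
  mean(bg_stats$sd / bg_stats$mean)
}

#' Contrast-to-noise ratio
#'
#' @param CR Contrast recovery.
#' @param BV Background variability (> 0).
#' @return `CR / BV`. Vectorised.
#' @export
cnr <- function(CR, BV) {
  if (any(BV <= 0)) stop("CNR undefined: `BV` must be > 0", call. = FALSE)
  CR / BV
}

#' Liver noise
#'
#' Liver SD normalised to liver SUVmean.
#'
#' @param liver_sd SD of the liver VOI.
#' @param liver_suvmean Mean SUV of the liver VOI (> 0).
#' @return Dimensionless noise level.
#' @export
liver_noise <- function(liver_sd, liver_suvmean) {
  if (any(liver_suvmean <= 0)) stop("`liver_suvmean` must be > 0", call. = FALSE)
  liver_sd / liver_suvmean
}

#' Lesion signal-to-noise ratio
#'
#' @param lesion_suvmax Lesion peak SUV.
#' @param liver_noise Liver noise (> 0), see [liver_noise()].
#' @return `lesion_suvmax / liver_noise`.
#' @export
lesion_snr <- function(lesion_suvmax, liver_noise) {
  if (any(liver_noise <= 0)) stop("SNR undefined: `liver_noise` must be > 0", call. = FALSE)
  lesion_suvmax / liver_noise
}

#' Lesion signal-to-background ratio
#'
#' @param lesion_suvmax Lesion peak SUV.
#' @param liver_suvmean Liver mean SUV (> 0).
#' @return `lesion_suvmax / liver_suvmean`.
#' @export
lesion_sbr <- function(lesion_suvmax, liver_suvmean) {
  if (any(liver_suvmean <= 0)) stop("`liver_suvmean` must be > 0", call. = FALSE)
  lesion_suvmax / liver_suvmean
}

#' Standardised uptake value from activity concentration
#'
#' `SUV = concentration [Bq/ml] / (injected activity [Bq] / body weight [g])`,
#' assuming tissue density 1 g/ml. A tracer distributed uniformly through the
#' body would read SUV 1 everywhere.
#'
#' @param conc_kBq_per_ml Activity concentration in kBq/ml.
#' @param injected_MBq Injected activity in MBq (> 0).
#' @param weight_kg Body weight in kg (> 0).
#' @return SUV. Vectorised over `conc_kBq_per_ml`.
#' @export
suv_from_concentration <- function(conc_kBq_per_ml, injected_MBq, weight_kg) {
  if (injected_MBq <= 0 || weight_kg <= 0) {
    stop("injected activity and weight must be > 0", call. = FALSE)
  }
  (conc_kBq_per_ml * 1000) / (injected_MBq * 1e6 / (weight_kg * 1000))
}
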