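#' Acquisition configuration
#'
#' Physical parameters of the simulated PET acquisition. Defaults describe a
#' digital PET/MR-like system: sensitivity 21 cps/kBq, 4.2 mm FWHM point
#' spread, 2.34 x 2.34 x 2.78 mm voxels; `sensitivity_cps_per_kBq = 10` and
#' `voxel_size_mm = c(4.1, 4.1, 3.0)` give a PET/CT-like system.
#'
#' @param time_per_bed_s Acquisition time per bed position, seconds (>= 0).
#' @param sensitivity_cps_per_kBq System sensitivity, counts/s per kBq.
#' @param psf_fwhm_mm Gaussian point-spread FWHM in mm (0 disables blurring).
#' @param voxel_size_mm Reconstruction voxel size, mm.
#' @param matrix In-plane matrix dimensions.
#' @param half_life_min Isotope half-life in minutes (Ga-68: 67.71).
#' @param seed Integer RNG seed for the Poisson draw.
#' @return An `acquisition_config` object.
#' @export
acquisition_config <- function(time_per_bed_s,
                               sensitivity_cps_per_kBq = 21,
                               psf_fwhm_mm = 4.2,
                               voxel_size_mm = c(2.34, 2.34, 2.78),
                               matrix = c(256, 256),
                               half_life_min = 67.71,
                               seed = 1L) {
  if (time_per_bed_s < 0) stop("`time_per_bed_s` must be >= 0", call. = FALSE)
  if (sensitivity_cps_per_kBq <= 0) stop("`sensitivity_cps_per_kBq` must be > 0", call. = FALSE)
  if (psf_fwhm_mm < 0) stop("`psf_fwhm_mm` must be >= 0", call. = FALSE)
  if (any(voxel_size_mm <= 0)) stop("`voxel_size_mm` must be > 0", call. = FALSE)
  if (half_life_min <= 0) stop("`half_life_min` must be > 0", call. = FALSE)
  structure(list(
    time_per_bed_s = time_per_bed_s,
    sensitivity_cps_per_kBq = sensitivity_cps_per_kBq,
    psf_fwhm_mm = psf_fwhm_mm,
    voxel_size_mm = voxel_size_mm,
    matrix = matrix,
    half_life_min = half_life_min,
    seed = as.integer(seed)
  ), class = "acquisition_config")
}

#' Simulate a noisy count acquisition
#'
#' Expected counts per voxel are activity (kBq/ml) x voxel volume (ml) x
#' sensitivity (cps/kBq) x acquisition time (s). The expectation field is
#' blurred with the Gaussian point spread, then one independent Poisson draw
#' per voxel produces the count image. The deterministic scale factor is
#' stored so counts can be converted back to concentration with
#' [counts_to_concentration()].
#'
#' @param truth An `activity_volume` in kBq/ml.
#' @param acq An [acquisition_config()].
#' @return An `activity_volume` of integer counts with attribute
#'   `scale_factor` (counts per kBq/ml).
#' @export
simulate_acquisition <- function(truth, acq) {
  stopifnot(inherits(truth, "activity_volume"), inherits(acq, "acquisition_config"))
  scale <- voxel_volume_ml(truth) * acq$sensitivity_cps_per_kBq * acq$time_per_bed_s
  expected <- truth$data * scale
  if (acq$psf_fwhm_mm > 0) {
    sigma <- acq$psf_fwhm_mm / (2 * sqrt(2 * log(2)))
    expected <- gauss_blur(expected, sigma, truth$spacing)
  }
  counts <- with_seed(acq$seed, rpois(length(expected), lambda = pmax(expected, 0)))
  out <- activity_volume(array(as.double(counts), dim = dim(truth$data)),
                         truth$spacing, truth$origin, units = "counts")
  attr(out, "scale_factor") <- scale
  out
}

#' Convert a count volume back to activity concentration
#'
#' Divides by the deterministic acquisition scale factor recorded by
#' [simulate_acquisition()] (and updated by [thin_counts()] to reflect the
#' reduced injected dose, so concentrations stay calibrated across
#' reductions).
#'
#' @param counts A count `activity_volume` with a `scale_factor` attribute.
#' @param units Unit label for the result.
#' @return An `activity_volume` in concentration units.
#' @export
counts_to_concentration <- function(counts, units = "kBq/ml") {
  scale <- attr(counts, "scale_factor")
  if (is.null(scale) || scale <= 0) {
    stop("`counts` carries no positive scale_factor", call. = FALSE)
  }
  activity_volume(counts$data / scale, counts$spacing, counts$origin, units = units)
}

#' Thin a count volume to emulate reduced injected activity
#'
#' Each voxel count is replaced by a binomial draw with keep-probability
#' `1 - r`: removing a fraction `r` of detected events statistically emulates
#' a scan acquired with `r` less injected activity. By the Poisson thinning
#' property, thinned Poisson counts remain Poisson with mean scaled by
#' `1 - r`. The recorded scale factor is multiplied by `1 - r`, matching the
#' SUV normalisation by the reduced injected dose.
#'
#' @param counts Non-negative integer count `activity_volume`.
#' @param r Reduction fraction in `[0, 1)`.
#' @param seed Integer RNG seed.
#' @return A thinned count `activity_volume`.
#' @export
thin_counts <- function(counts, r, seed = 1L) {
  stopifnot(inherits(counts, "activity_volume"))
  if (length(r) != 1 || !is.finite(r) || r < 0 || r >= 1) {
    stop("`r` must be a single value in [0, 1)", call. = FALSE)
  }
  x <- counts$data
  if (any(x < 0) || any(x != round(x))) {
    stop("`counts` must contain non-negative integers", call. = FALSE)
  }
  if (r == 0) return(counts)
  thinned <- with_seed(seed, rbinom(length(x), size = as.integer(round(x)), prob = 1 - r))
  out <- activity_volume(array(as.double(thinned), dim = dim(x)),
                         counts$spacing, counts$origin, units = "counts")
  sf <- attr(counts, "scale_factor")
  if (!is.null(sf)) attr(out, "scale_factor") <- sf * (1 - r)
  out
}

#' Penalised-reconstruction noise-suppression surrogate
#'
#' Stands in for the noise-penalisation behaviour of a regularised PET
#' reconstruction: Gaussian smoothing whose width grows with the penalisation
#' factor as `sigma(beta) = sigma_ref * sqrt(beta / 300)`, anchored at the
#' clinical reference `beta = 300`. This is a surrogate for the qualitative
#' noise/resolution trade-off only, not a model of any vendor algorithm.
#' `beta = 0` returns the input unchanged; the global mean is preserved.
#'
#' @param image An `activity_volume`.
#' @param beta Penalisation factor, >= 0.
#' @param sigma_ref_mm Smoothing width (mm) at `beta = 300`.
#' @return A smoothed `activity_volume`.
#' @export
beta_smooth <- function(image, beta, sigma_ref_mm = 3) {
  stopifnot(inherits(image, "activity_volume"))
  if (length(beta) != 1 || !is.finite(beta) || beta < 0) {
    stop("`beta` must be a single value >= 0", call. = FALSE)
  }
  if (beta == 0) return(image)
  sigma <- sigma_ref_mm * sqrt(beta / 300)
  out <- image
  out$data <- gauss_blur(image$data, sigma, image$spacing)
  for (a in names(attributes(image))) {
    if (!a %in% c("names", "class")) attr(out, a) <- attr(image, a)
  }
  out
}

#' Decay-compensated acquisition time
#'
#' Time needed after a delay to collect the same number of decays as a
#' reference acquisition at time zero: `t_ref * 2^(delay / half_life)`.
#'
#' @param t_ref_s Reference acquisition time, seconds.
#' @param delay_min Delay since the reference time, minutes (>= 0).
#' @param half_life_min Isotope half-life, minutes (Ga-68: 67.71).
#' @return Compensated time in seconds.
#' @export
decay_compensated_time <- function(t_ref_s, delay_min, half_life_min = 67.71) {
  if (half_life_min <= 0) stop("`half_life_min` must be > 0", call. = FALSE)
  if (delay_min < 0) stop("`delay_min` must be >= 0", call. = FALSE)
  t_ref_s * 2^(delay_min / half_life_min)
}
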