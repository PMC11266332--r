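#' NEMA image-quality phantom specification
#'
#' Describes the digital NEMA IQ phantom: six fillable spheres (10-37 mm
#' diameter) on a 57.2 mm ring in the central plane, an elliptical-cylinder
#' body, a central zero-activity lung insert, and two lateral 500 ml "arm"
#' bottles. Sphere-to-background activity ratios follow the three standard
#' fill sessions; `ratio = "4:1"` is the default used for the
#' activity-reduction experiments.
#'
#' @param ratio One of `"10:1"`, `"4:1"`, `"2:1"`; selects the session's
#'   sphere/background activities (kBq/ml): 38.9/4.0, 22.1/5.2, 12.0/5.4.
#' @param sphere_activity,background_activity Optional explicit activities
#'   (kBq/ml) overriding `ratio`.
#' @param bottle_activity Activity in the arm bottles (kBq/ml).
#' @param sphere_diameters Sphere diameters in mm.
#' @param ring_radius_mm Radius of the sphere ring in the central plane.
#' @param body_semi_axes_mm In-plane semi-axes of the elliptical body.
#' @param body_height_mm Axial extent of the body.
#' @param lung_diameter_mm Diameter of the central zero-activity insert.
#' @param arm_bottles Include the two lateral 500 ml bottles?
#' @return A `phantom_spec` object.
#' @export
nema_phantom_spec <- function(ratio = c("4:1", "10:1", "2:1"),
                              sphere_activity = NULL,
                              background_activity = NULL,
                              bottle_activity = 0.32,
                              sphere_diameters = c(37, 10, 13, 28, 17, 22),
                              ring_radius_mm = 57.2,
                              body_semi_axes_mm = c(150, 110),
                              body_height_mm = 180,
                              lung_diameter_mm = 50,
                              arm_bottles = TRUE) {
  ratio <- match.arg(ratio)
  fills <- list(`10:1` = c(38.9, 4.0), `4:1` = c(22.1, 5.2), `2:1` = c(12.0, 5.4))
  if (is.null(sphere_activity)) sphere_activity <- fills[[ratio]][1]
  if (is.null(background_activity)) background_activity <- fills[[ratio]][2]
  if (any(c(sphere_activity, background_activity, bottle_activity) < 0)) {
    stop("activities must be >= 0", call. = FALSE)
  }
  n <- length(sphere_diameters)
  angles <- 2 * pi * (seq_len(n) - 1) / n
  centers <- cbind(
    x = ring_radius_mm * cos(angles),
    y = ring_radius_mm * sin(angles),
    z = 0
  )
  bottle_r <- 40
  bottle_h <- 500e3 / (pi * bottle_r^2)  # 500 ml
  spec <- structure(list(
    ratio = ratio,
    sphere_diameters = sphere_diameters,
    sphere_centers = centers,
    sphere_angles = angles,
    ring_radius_mm = ring_radius_mm,
    body_semi_axes_mm = body_semi_axes_mm,
    body_height_mm = body_height_mm,
    lung_diameter_mm = lung_diameter_mm,
    arm_bottles = arm_bottles,
    bottle_diameter_mm = 2 * bottle_r,
    bottle_height_mm = bottle_h,
    bottle_centers = cbind(x = c(-1, 1) * (body_semi_axes_mm[1] + bottle_r),
                           y = 0, z = 0),
    activities = list(spheres = rep_len(sphere_activity, n),
                      background = background_activity,
                      bottles = bottle_activity)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  r <- spec$sphere_diameters / 2
  ctr <- spec$sphere_centers
  n <- nrow(ctr)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- sqrt(sum((ctr[i, ] - ctr[j, ])^2))
      if (d <= r[i] + r[j]) {
        stop(sprintf("spheres %d and %d overlap", i, j), call. = FALSE)
      }
    }
  }
  inner <- sqrt(ctr[, 1]^2 + ctr[, 2]^2) - r
  if (any(inner <= spec$lung_diameter_mm / 2)) {
    stop("a sphere overlaps the lung insert", call. = FALSE)
  }
  # conservative body-wall check on the margin-shrunk ellipse
  a <- spec$body_semi_axes_mm[1]; b <- spec$body_semi_axes_mm[2]
  out <- (ctr[, 1] / (a - r))^2 + (ctr[, 2] / (b - r))^2 > 1
  if (any(out)) stop("a sphere crosses the body wall", call. = FALSE)
  invisible(spec)
}

#' Build the ground-truth activity volume for a NEMA phantom
#'
#' Voxelises the phantom onto a regular grid: each voxel carries the activity
#' (kBq/ml) of the compartment containing its centre (background inside the
#' body, zero in the lung insert, sphere activity inside each sphere, bottle
#' activity in the arm bottles, zero elsewhere).
#'
#' @param spec A [nema_phantom_spec()].
#' @param voxel_size Voxel spacing in mm (length 3).
#' @param dim Grid dimensions; the default covers body and arm bottles.
#' @return An `activity_volume` in kBq/ml.
#' @export
build_nema_phantom <- function(spec, voxel_size = c(2.34, 2.34, 2.78),
                               dim = NULL) {
  if (any(voxel_size <= 0)) stop("voxel size must be positive", call. = FALSE)
  validate_phantom_spec(spec)
  if (is.null(dim)) {
    extent_x <- 2 * (spec$body_semi_axes_mm[1] +
                       if (spec$arm_bottles) spec$bottle_diameter_mm else 0) + 20
    extent_y <- 2 * spec$body_semi_axes_mm[2] + 20
    extent_z <- spec$body_height_mm + 20
    dim <- as.integer(ceiling(c(extent_x, extent_y, extent_z) / voxel_size))
  }
  g <- vol_grid(dim, voxel_size)
  arr <- array(0, g$dim)
  body <- elliptical_cylinder_mask(g, c(0, 0, 0), spec$body_semi_axes_mm,
                                   spec$body_height_mm)
  lung <- cylinder_mask(g, c(0, 0, 0), spec$lung_diameter_mm,
                        spec$body_height_mm)
  arr[body & !lung] <- spec$activities$background
  for (i in seq_along(spec$sphere_diameters)) {
    m <- sphere_mask(g, spec$sphere_centers[i, ], spec$sphere_diameters[i])
    arr[m] <- spec$activities$spheres[i]
  }
  if (spec$arm_bottles) {
    for (i in 1:2) {
      m <- cylinder_mask(g, spec$bottle_centers[i, ], spec$bottle_diameter_mm,
                         spec$bottle_height_mm)
      arr[m] <- spec$activities$bottles
    }
  }
  activity_volume(arr, voxel_size, units = "kBq/ml")
}

#' Synthetic patient specification
#'
#' A stylised whole-body section for SUV-valued simulations: uniform body
#' background, a homogeneous ellipsoidal liver, and spherical lesions with
#' target peak SUV. The default lesion set has 10 lesions of diameters
#' 6-37 mm, half of them subcentimeter (volume at or below that of the 10 mm
#' NEMA sphere, 0.52 cm^3), with peak SUV 4-40. The default injected dose
#' follows the 1.5 MBq/kg protocol.
#'
#' @param weight_kg Patient weight.
#' @param injected_MBq Injected activity; default 1.5 MBq/kg.
#' @param liver_suv Uniform liver SUV.
#' @param body_suv Body background SUV.
#' @param liver_center,liver_semi_axes Liver ellipsoid geometry (mm).
#' @param body_semi_axes,body_height Body elliptical-cylinder geometry (mm).
#' @param lesions Tibble with columns `x, y, z, diameter_mm, suvmax`; defaults
#'   to the built-in 10-lesion set.
#' @param liver_voi_center Centre (mm) of the fixed 3 cm liver VOI, at least
#'   1 cm inside the liver boundary and clear of all lesions.
#' @return A `patient_spec` object.
#' @export
patient_spec <- function(weight_kg = 80,
                         injected_MBq = 1.5 * weight_kg,
                         liver_suv = 6,
                         body_suv = 1,
                         liver_center = c(45, 25, 0),
                         liver_semi_axes = c(70, 50, 45),
                         body_semi_axes = c(160, 110),
                         body_height = 200,
                         lesions = default_lesions(),
                         liver_voi_center = c(20, 10, -5)) {
  if (weight_kg <= 0 || injected_MBq <= 0) {
    stop("weight and injected activity must be positive", call. = FALSE)
  }
  lesions <- tibble::as_tibble(lesions)
  need <- c("x", "y", "z", "diameter_mm", "suvmax")
  if (!all(need %in% names(lesions))) {
    stop("`lesions` needs columns x, y, z, diameter_mm, suvmax", call. = FALSE)
  }
  r <- lesions$diameter_mm / 2
  inside <- (lesions$x / (body_semi_axes[1] - r))^2 +
    (lesions$y / (body_semi_axes[2] - r))^2 <= 1 &
    abs(lesions$z) + r <= body_height / 2
  if (!all(inside)) {
    stop(sprintf("lesion(s) %s lie outside the body",
                 paste(which(!inside), collapse = ", ")), call. = FALSE)
  }
  structure(list(
    weight_kg = weight_kg, injected_MBq = injected_MBq,
    liver_suv = liver_suv, body_suv = body_suv,
    liver_center = liver_center, liver_semi_axes = liver_semi_axes,
    body_semi_axes = body_semi_axes, body_height = body_height,
    lesions = lesions, liver_voi_center = liver_voi_center
  ), class = "patient_spec")
}

#' Default synthetic lesion set
#'
#' Ten spherical lesions; the five with diameter at most 10 mm have volume at
#' or below that of the smallest NEMA sphere (0.52 cm^3). Lesions with peak
#' SUV below the liver SUV sit in the body background; the rest in the liver.
#'
#' @return A tibble with columns `x, y, z, diameter_mm, suvmax`.
#' @export
default_lesions <- function() {
  tibble::tribble(
    ~x,   ~y,  ~z,  ~diameter_mm, ~suvmax,
    -90, -45,   0,   6,   4,
    -90,  45,   0,   7,   6,
     15,  55,  18,   8,   8,
     25,  65, -12,   9,  10,
     75,  45,  18,  10,  12,
     95,  30,  10,  12,  14,
     65,  -8,  25,  17,  18,
     25,  18,  30,  22,  24,
     55,  45, -27,  28,  32,
     78,   2, -18,  37,  40
  )
}

#' Fraction of lesions at or below a reference volume
#'
#' @param spec A [patient_spec()].
#' @param reference_volume_ml Reference volume; default the 10 mm sphere
#'   (0.5236 cm^3).
#' @return Fraction in `[0, 1]`.
#' @export
subcentimeter_fraction <- function(spec, reference_volume_ml = 4 / 3 * pi * 0.5^3) {
  v <- 4 / 3 * pi * (spec$lesions$diameter_mm / 20)^3  # cm^3
  mean(v <= reference_volume_ml + 1e-9)
}

#' Build a synthetic patient SUV volume
#'
#' Voxelises a [patient_spec()]: body background, uniform liver, spherical
#' lesions. When a point-spread FWHM is supplied, lesion amplitudes are
#' pre-compensated so that after Gaussian blurring the lesion peak equals the
#' target SUVmax in expectation (within 5% for diameters >= 17 mm; smaller
#' lesions stay partial-volume limited, as on a real scanner).
#'
#' @param spec A [patient_spec()].
#' @param voxel_size Voxel spacing in mm.
#' @param dim Grid dimensions; default covers the body section.
#' @param psf_fwhm_mm FWHM of the Gaussian blur the image chain will apply;
#'   `0` disables amplitude pre-compensation.
#' @return An `activity_volume` in SUV units.
#' @export
build_patient_volume <- function(spec, voxel_size = c(2.34, 2.34, 2.78),
                                 dim = NULL, psf_fwhm_mm = 0) {
  if (is.null(dim)) {
    dim <- as.integer(ceiling(
      (c(2 * spec$body_semi_axes, spec$body_height) + 12) / voxel_size
    ))
  }
  g <- vol_grid(dim, voxel_size)
  arr <- array(0, g$dim)
  body <- elliptical_cylinder_mask(g, c(0, 0, 0), spec$body_semi_axes,
                                   spec$body_height)
  arr[body] <- spec$body_suv
  liver <- ellipsoid_mask(g, spec$liver_center, spec$liver_semi_axes)
  arr[liver] <- spec$liver_suv
  sigma <- psf_fwhm_mm / (2 * sqrt(2 * log(2)))
  les <- spec$lesions
  for (i in seq_len(nrow(les))) {
    ctr <- c(les$x[i], les$y[i], les$z[i])
    in_liver <- sum(((ctr - spec$liver_center) / spec$liver_semi_axes)^2) <= 1
    bg <- if (in_liver) spec$liver_suv else spec$body_suv
    rec <- gaussian_sphere_recovery(les$diameter_mm[i] / 2, sigma)
    amp <- bg + (les$suvmax[i] - bg) / rec
    m <- sphere_mask(g, ctr, les$diameter_mm[i])
    arr[m] <- amp
  }
  activity_volume(arr, voxel_size, units = "SUV")
}
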