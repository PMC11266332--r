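#' Create an activity volume
#'
#' A lightweight container for a 3-D scalar field on a regular grid: a numeric
#' array plus voxel spacing (mm) and the world coordinate (mm) of the centre of
#' the first voxel. By default the grid is centred on the world origin, so the
#' phantom centre sits at (0, 0, 0).
#'
#' @param data Numeric 3-D array (voxel values).
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @param origin Numeric length-3 world coordinate (mm) of the centre of voxel
#'   `[1, 1, 1]`. Defaults to a grid centred on (0, 0, 0).
#' @param units Character unit label, e.g. `"kBq/ml"`, `"SUV"`, `"counts"`.
#' @return An object of class `activity_volume`.
#' @export
activity_volume <- function(data, spacing, origin = NULL, units = "kBq/ml") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-D array", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive voxel sizes in mm", call. = FALSE)
  }
  d <- dim(data)
  if (is.null(origin)) origin <- -(d - 1) / 2 * spacing
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must have length 3", call. = FALSE)
  structure(
    list(data = data, spacing = spacing, origin = origin, units = units),
    class = "activity_volume"
  )
}

#' @export
print.activity_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<activity_volume> %d x %d x %d voxels @ %.3g x %.3g x %.3g mm [%s]\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], x$units
  ))
  cat(sprintf(
    "  range [%.4g, %.4g], voxel volume %.4g ml\n",
    min(x$data), max(x$data), voxel_volume_ml(x)
  ))
  invisible(x)
}

#' @export
as.array.activity_volume <- function(x, ...) x$data

#' @export
dim.activity_volume <- function(x) dim(x$data)

#' Voxel volume in millilitres
#'
#' @param vol An `activity_volume` (or anything with a `spacing` field in mm).
#' @return Voxel volume in ml.
#' @export
voxel_volume_ml <- function(vol) prod(vol$spacing) / 1000

#' World coordinates of voxel centres along each axis
#'
#' @param vol An `activity_volume` or `vol_grid`.
#' @return List of three numeric vectors (mm).
#' @export
axis_coords <- function(vol) {
  d <- dim(vol$data %||% vol$dim)
  if (is.null(d)) d <- vol$dim
  lapply(1:3, function(k) vol$origin[k] + (seq_len(d[k]) - 1) * vol$spacing[k])
}

#' Define a voxel grid without data
#'
#' @param dim Integer length-3 grid dimensions.
#' @param spacing Voxel spacing in mm.
#' @param origin Optional world coordinate of the first voxel centre; defaults
#'   to a centred grid.
#' @return A `vol_grid` object usable wherever a grid is expected.
#' @export
vol_grid <- function(dim, spacing, origin = NULL) {
  dim <- as.integer(dim)
  spacing <- as.numeric(spacing)
  if (length(dim) != 3L || any(dim < 1L)) stop("`dim` must be 3 positive integers", call. = FALSE)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("`spacing` must be 3 positive values", call. = FALSE)
  if (is.null(origin)) origin <- -(dim - 1) / 2 * spacing
  structure(list(dim = dim, spacing = spacing, origin = as.numeric(origin)),
            class = "vol_grid")
}

# Coerce an activity_volume or vol_grid to a plain grid description.
as_grid <- function(x) {
  if (inherits(x, "vol_grid")) return(x)
  if (inherits(x, "activity_volume")) {
    return(vol_grid(dim(x$data), x$spacing, x$origin))
  }
  stop("expected an `activity_volume` or `vol_grid`", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a volume to NIfTI-1 with a JSON sidecar
#'
#' The voxel spacing goes in the NIfTI header; units and world origin go in a
#' JSON sidecar next to the image.
#'
#' @param vol An `activity_volume`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(units = vol$units, origin_mm = vol$origin, spacing_mm = vol$spacing),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' @param path Path to the NIfTI image.
#' @return An `activity_volume`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  spacing <- RNifti::pixdim(img)[1:3]
  activity_volume(
    array(as.numeric(img), dim = dim(img)),
    spacing = spacing,
    origin = meta$origin_mm %||% NULL,
    units = meta$units %||% "kBq/ml"
  )
}

# Evaluate code with a temporary RNG state seeded at `seed`, restoring the
# caller's state afterwards so simulations are reproducible but non-invasive.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  force(code)
}
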