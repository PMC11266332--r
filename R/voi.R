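#' Volumes of interest
#'
#' VOIs are boolean voxel sets on the same grid as the volume they are
#' measured on, built by voxel-centre containment. Constructors return a
#' `voi_mask` carrying the mask, the grid, and a shape descriptor.
#'
#' @name voi
NULL

new_voi_mask <- function(mask, grid, kind, center, dims_mm) {
  if (!any(mask)) stop("degenerate VOI: no voxel centre falls inside the shape",
                       call. = FALSE)
  structure(list(mask = mask, grid = as_grid(grid), kind = kind,
                 center = as.numeric(center), dims_mm = dims_mm),
            class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask> %s at (%s) mm, %d voxels (%.3g ml)\n",
              x$kind, paste(signif(x$center, 4), collapse = ", "),
              sum(x$mask), voi_volume_ml(x)))
  invisible(x)
}

#' VOI volume in ml
#' @param voi A `voi_mask`.
#' @return Volume in ml (voxel count times voxel volume).
#' @export
voi_volume_ml <- function(voi) sum(voi$mask) * prod(voi$grid$spacing) / 1000

#' Spherical VOI
#'
#' @param grid An `activity_volume` or `vol_grid`.
#' @param center Centre in mm.
#' @param diameter Diameter in mm.
#' @return A `voi_mask`.
#' @export
make_sphere_voi <- function(grid, center, diameter) {
  g <- as_grid(grid)
  m <- sphere_mask(g, center, diameter)
  new_voi_mask(m, g, "sphere", center, list(diameter = diameter))
}

#' Cylindrical VOI
#'
#' @inheritParams make_sphere_voi
#' @param height Height in mm.
#' @param axis Direction vector of the cylinder axis (sign-insensitive).
#' @return A `voi_mask`.
#' @export
make_cylinder_voi <- function(grid, center, diameter, height, axis = c(0, 0, 1)) {
  g <- as_grid(grid)
  m <- cylinder_mask(g, center, diameter, height, axis)
  new_voi_mask(m, g, "cylinder", center,
               list(diameter = diameter, height = height, axis = axis))
}

#' Place background cylinders in a phantom
#'
#' Places `n` cylindrical background VOIs (default 27 mm diameter x 70 mm, the
#' standard background noise VOI) at equal angular spacing on an elliptical
#' ring in the background compartment, offset from the sphere angles. Every
#' placement keeps at least `margin` mm clearance from each sphere surface,
#' the lung insert and the body wall; the construction is deterministic given
#' the spec and the constraints are verified, with an error if unsatisfiable.
#'
#' @param spec A [nema_phantom_spec()].
#' @param grid Grid or volume to build masks on.
#' @param n Number of VOIs.
#' @param diameter,height Cylinder dimensions in mm.
#' @param margin Minimum clearance in mm.
#' @return A list of `voi_mask` objects.
#' @export
place_background_vois <- function(spec, grid, n = 6, diameter = 27, height = 70,
                                  margin = 15) {
  g <- as_grid(grid)
  rad <- diameter / 2
  a <- spec$body_semi_axes_mm[1]; b <- spec$body_semi_axes_mm[2]
  ring <- 0.97 * c(a - rad - margin, b - rad - margin)
  if (any(ring <= 0)) stop("background too small for the requested VOIs", call. = FALSE)
  offset <- pi / length(spec$sphere_angles)
  angles <- spec$sphere_angles[1] + offset + 2 * pi * (seq_len(n) - 1) / n
  centers <- cbind(ring[1] * cos(angles), ring[2] * sin(angles), 0)

  sph_r <- spec$sphere_diameters / 2
  for (i in seq_len(n)) {
    dxy <- sqrt((spec$sphere_centers[, 1] - centers[i, 1])^2 +
                  (spec$sphere_centers[, 2] - centers[i, 2])^2)
    clear <- dxy - rad - sph_r  # cylinder spans the sphere plane (z = 0)
    if (any(clear < margin)) {
      stop("background VOI placement violates sphere clearance", call. = FALSE)
    }
    if (sqrt(sum(centers[i, 1:2]^2)) - rad - spec$lung_diameter_mm / 2 < margin) {
      stop("background VOI placement violates lung-insert clearance", call. = FALSE)
    }
    wall <- (centers[i, 1] / (a - rad - margin))^2 +
      (centers[i, 2] / (b - rad - margin))^2
    if (wall > 1) stop("background VOI placement violates body-wall clearance",
                       call. = FALSE)
    if (height / 2 + margin > spec$body_height_mm / 2) {
      stop("background VOI too tall for the body", call. = FALSE)
    }
  }
  lapply(seq_len(n), function(i) {
    make_cylinder_voi(g, centers[i, ], diameter, height)
  })
}

#' Half-maximum lesion VOI
#'
#' Builds the standard lesion VOI: the connected component (6-connectivity)
#' containing the hottest voxel within 15 mm of `seed_point`, thresholded at
#' `fraction` of that maximum. Falls back to a fixed 10 mm sphere at the
#' hottest voxel when the component exceeds `max_volume_ml` or touches the
#' supplied liver VOI (the region has merged into background uptake).
#'
#' @param volume An `activity_volume`.
#' @param seed_point Approximate lesion location in mm.
#' @param fraction Threshold as a fraction of the local maximum.
#' @param liver_voi Optional liver `voi_mask` triggering the fallback.
#' @param max_volume_ml Component volume triggering the fallback.
#' @param background Optional background level; if the local maximum does not
#'   exceed it, a no-lesion error is raised.
#' @param search_radius_mm Radius of the peak search around `seed_point`.
#' @return A `voi_mask` (kind `"threshold"` or `"sphere"` for the fallback).
#' @export
threshold_lesion_voi <- function(volume, seed_point, fraction = 0.5,
                                 liver_voi = NULL, max_volume_ml = 100,
                                 background = NULL, search_radius_mm = 15) {
  g <- as_grid(volume)
  near <- sphere_mask(g, seed_point, 2 * search_radius_mm)
  vals <- volume$data
  if (!any(near)) stop("seed point outside the volume", call. = FALSE)
  peak_val <- max(vals[near])
  if (!is.null(background) && peak_val <= background) {
    stop("no lesion: local maximum does not exceed background", call. = FALSE)
  }
  idx <- which(near & vals == peak_val)[1]
  thr <- fraction * peak_val
  comp <- flood_fill(vals >= thr, idx)
  vol_ml <- sum(comp) * prod(g$spacing) / 1000
  touches_liver <- !is.null(liver_voi) && any(comp & liver_voi$mask)
  if (vol_ml > max_volume_ml || touches_liver) {
    ctr <- vapply(1:3, function(k) {
      g$origin[k] + (arrayInd(idx, g$dim)[k] - 1) * g$spacing[k]
    }, numeric(1))
    return(new_voi_mask(sphere_mask(g, ctr, 10), g, "sphere", ctr,
                        list(diameter = 10, fallback = TRUE)))
  }
  new_voi_mask(comp, g, "threshold", seed_point,
               list(fraction = fraction, peak = peak_val))
}

# 6-connected flood fill over a logical array from a linear start index.
flood_fill <- function(cand, start) {
  d <- dim(cand)
  visited <- array(FALSE, d)
  if (!cand[start]) return(visited)
  visited[start] <- TRUE
  frontier <- start
  n1 <- d[1]; n12 <- d[1] * d[2]
  offs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  while (length(frontier)) {
    ai <- arrayInd(frontier, d)
    nbrs <- integer(0)
    for (off in offs) {
      co <- sweep(ai, 2, off, `+`)
      ok <- co[, 1] >= 1 & co[, 1] <= d[1] &
        co[, 2] >= 1 & co[, 2] <= d[2] &
        co[, 3] >= 1 & co[, 3] <= d[3]
      if (!any(ok)) next
      nbrs <- c(nbrs, co[ok, 1] + (co[ok, 2] - 1) * n1 + (co[ok, 3] - 1) * n12)
    }
    nbrs <- unique(nbrs)
    nbrs <- nbrs[cand[nbrs] & !visited[nbrs]]
    visited[nbrs] <- TRUE
    frontier <- nbrs
  }
  visited
}

#' Per-VOI statistics
#'
#' Mean, sample (n-1) standard deviation, maximum, voxel count and volume of
#' the voxels inside a VOI.
#'
#' @param volume An `activity_volume`.
#' @param voi A `voi_mask` on the same grid.
#' @return A one-row tibble: `mean`, `sd`, `max`, `voxel_count`, `volume_ml`.
#' @export
voi_stats <- function(volume, voi) {
  stopifnot(inherits(volume, "activity_volume"), inherits(voi, "voi_mask"))
  if (!identical(dim(volume$data), voi$grid$dim) ||
      !isTRUE(all.equal(volume$spacing, voi$grid$spacing)) ||
      !isTRUE(all.equal(volume$origin, voi$grid$origin))) {
    stop("volume and VOI are on different grids", call. = FALSE)
  }
  v <- volume$data[voi$mask]
  if (length(v) < 2) {
    stop("single-voxel VOI: sample SD is undefined", call. = FALSE)
  }
  tibble::tibble(
    mean = mean(v), sd = sd(v), max = max(v),
    voxel_count = length(v),
    volume_ml = length(v) * prod(volume$spacing) / 1000
  )
}
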