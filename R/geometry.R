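# Internal geometry helpers. All masks use voxel-centre containment on the
# shared world grid: a voxel belongs to a shape iff its centre does.

# Squared distance of every axis coordinate to a point, per axis.
axis_sqdist <- function(grid, center) {
  cc <- axis_coords(grid)
  lapply(1:3, function(k) (cc[[k]] - center[k])^2)
}

# Logical array: voxel centres within `diameter/2` of `center`.
sphere_mask <- function(grid, center, diameter) {
  g <- as_grid(grid)
  d2 <- axis_sqdist(g, center)
  r2 <- (diameter / 2)^2
  m <- outer(outer(d2[[1]], d2[[2]], `+`), d2[[3]], `+`)
  array(m <= r2, dim = g$dim)
}

# Logical array: cylinder of given diameter/height about `center`, with `axis`
# a direction vector (sign-insensitive).
cylinder_mask <- function(grid, center, diameter, height, axis = c(0, 0, 1)) {
  g <- as_grid(grid)
  a <- axis / sqrt(sum(axis^2))
  cc <- axis_coords(g)
  dx <- cc[[1]] - center[1]; dy <- cc[[2]] - center[2]; dz <- cc[[3]] - center[3]
  # Components of the displacement along the cylinder axis, built separably.
  t_ <- outer(outer(dx * a[1], dy * a[2], `+`), dz * a[3], `+`)
  r2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`) - t_^2
  r2[r2 < 0] <- 0
  array(abs(t_) <= height / 2 & r2 <= (diameter / 2)^2, dim = g$dim)
}

# Elliptical cylinder along z: (x/a)^2 + (y/b)^2 <= 1, |z - cz| <= h/2.
elliptical_cylinder_mask <- function(grid, center, semi_axes, height) {
  g <- as_grid(grid)
  cc <- axis_coords(g)
  ex <- ((cc[[1]] - center[1]) / semi_axes[1])^2
  ey <- ((cc[[2]] - center[2]) / semi_axes[2])^2
  inz <- abs(cc[[3]] - center[3]) <= height / 2
  m <- outer(ex, ey, `+`) <= 1
  array(outer(m, inz, `&`), dim = g$dim)
}

# Ellipsoid with semi-axes (mm).
ellipsoid_mask <- function(grid, center, semi_axes) {
  g <- as_grid(grid)
  cc <- axis_coords(g)
  ex <- ((cc[[1]] - center[1]) / semi_axes[1])^2
  ey <- ((cc[[2]] - center[2]) / semi_axes[2])^2
  ez <- ((cc[[3]] - center[3]) / semi_axes[3])^2
  m <- outer(outer(ex, ey, `+`), ez, `+`)
  array(m <= 1, dim = g$dim)
}

# Separable Gaussian blur of a 3-D array, sigma in mm. The 1-D kernels are
# truncated at 4 sigma and renormalised per output voxel (rows sum to 1), so
# constant fields are preserved exactly everywhere including the boundary; a
# final rescale restores the global sum exactly (the boundary renormalisation
# alone can drift it by a few parts per million on noisy fields).
gauss_blur <- function(arr, sigma_mm, spacing) {
  if (length(sigma_mm) == 1L) sigma_mm <- rep(sigma_mm, 3)
  total_in <- sum(arr)
  for (axis in 1:3) {
    sv <- sigma_mm[axis] / spacing[axis]
    if (sv < 1e-8) next
    n <- dim(arr)[axis]
    h <- min(n - 1L, as.integer(ceiling(4 * sv)))
    off <- -h:h
    K <- matrix(0, n, n)
    w <- exp(-off^2 / (2 * sv^2))
    for (i in seq_len(n)) {
      jj <- i + off
      ok <- jj >= 1L & jj <= n
      K[i, jj[ok]] <- w[ok] / sum(w[ok])
    }
    arr <- apply_along_axis(arr, K, axis)
  }
  total_out <- sum(arr)
  if (is.finite(total_in) && total_out != 0) arr <- arr * (total_in / total_out)
  arr
}

# Multiply K (n_axis x n_axis) along one axis of a 3-D array.
apply_along_axis <- function(a, K, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- K %*% matrix(ap, nrow = d[axis])
  dim(m) <- d[perm]
  aperm(m, order(perm))
}

# Fraction of a 3-D isotropic Gaussian's mass within radius R of its centre;
# equals the blurred centre value of a unit sphere of radius R. Used to
# pre-compensate lesion amplitudes for PSF blurring.
gaussian_sphere_recovery <- function(R, sigma) {
  if (sigma <= 0) return(1)
  z <- R / sigma
  pchisq(z^2, df = 3)
}
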