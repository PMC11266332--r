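test_that("sphere VOIs match analytic volumes by voxel-centre containment", {
  g <- vol_grid(c(41, 41, 41), c(2.34, 2.34, 2.78))
  # sub-voxel sphere centred on a voxel centre -> exactly one voxel
  tiny <- make_sphere_voi(g, c(0, 0, 0), 2)
  expect_equal(sum(tiny$mask), 1L)
  # 37 mm sphere: 26 522 mm^3 / 15.22 mm^3 = 1743 voxels, within 3%
  voi <- make_sphere_voi(g, c(0, 0, 0), 37)
  expect_equal(sum(voi$mask), 26522 / prod(g$spacing), tolerance = 0.03)
  # 30 mm liver VOI: analytic 14.14 ml
  liver <- make_sphere_voi(g, c(0, 0, 0), 30)
  expect_equal(voi_volume_ml(liver), 4 / 3 * pi * 1.5^3, tolerance = 0.08)
  expect_error(make_sphere_voi(g, c(500, 0, 0), 10), "degenerate")
})

test_that("cylinder VOIs have the right volume and are axis-sign invariant", {
  g <- vol_grid(c(41, 41, 61), c(2, 2, 2))
  voi <- make_cylinder_voi(g, c(0, 0, 0), 27, 70)
  expect_equal(voi_volume_ml(voi), pi * 1.35^2 * 7, tolerance = 0.03)
  flipped <- make_cylinder_voi(g, c(0, 0, 0), 27, 70, axis = c(0, 0, -1))
  expect_identical(voi$mask, flipped$mask)
  # height below the axial pitch centred on a slice -> single-slice disk
  disk <- make_cylinder_voi(g, c(0, 0, 0), 27, 1.5)
  expect_equal(length(unique(which(disk$mask, arr.ind = TRUE)[, 3])), 1L)
})

test_that("background VOIs sit in clean background with 15 mm clearance", {
  ph <- coarse_phantom("4:1")
  bg <- place_background_vois(ph$spec, ph$truth)
  expect_length(bg, 6)
  combined <- Reduce(`+`, lapply(bg, function(v) v$mask))
  expect_true(all(combined <= 1))  # pairwise disjoint
  for (v in bg) {
    expect_true(all(ph$truth$data[v$mask] == ph$spec$activities$background))
  }
  # distance scan: every mask voxel >= sphere radius + 15 mm from centres
  cc <- axis_coords(ph$truth)
  for (v in bg) {
    ai <- which(v$mask, arr.ind = TRUE)
    pts <- cbind(cc[[1]][ai[, 1]], cc[[2]][ai[, 2]], cc[[3]][ai[, 3]])
    for (i in seq_along(ph$spec$sphere_diameters)) {
      d <- sqrt(rowSums(sweep(pts, 2, ph$spec$sphere_centers[i, ])^2))
      expect_gte(min(d), ph$spec$sphere_diameters[i] / 2 + 15)
    }
  }
  expect_error(place_background_vois(ph$spec, ph$truth, margin = 60),
               "clearance|too small")
})

test_that("threshold lesion VOIs follow the half-maximum isocontour", {
  g <- vol_grid(c(61, 61, 41), c(2, 2, 2))
  arr <- array(1, g$dim)
  vol <- activity_volume(arr, g$spacing, units = "SUV")
  vol$data[sphere_mask(g <- as_grid(vol), c(-30, 0, 0), 22)] <- 10
  vol$data[sphere_mask(g, c(40, 20, 0), 16)] <- 8
  # isolated hot sphere, no blur: mask is exactly the voxels > 50% of max
  voi <- threshold_lesion_voi(vol, c(-30, 0, 0))
  expect_true(all(vol$data[voi$mask] >= 5))
  # two disjoint hot spots: only the seeded component is returned
  cc <- axis_coords(vol)
  expect_true(all(cc[[1]][which(voi$mask, arr.ind = TRUE)[, 1]] < 0))
  voi2 <- threshold_lesion_voi(vol, c(40, 20, 0))
  expect_false(any(voi$mask & voi2$mask))
  expect_error(threshold_lesion_voi(vol, c(0, -50, 0), background = 1),
               "no lesion")
})

test_that("the blurred half-maximum contour stays within one FWHM of the true diameter", {
  # 22 mm lesion blurred at 4.2 mm FWHM: 50% isocontour diameter in
  # [22, 22 + 4.2] mm (radial-profile oracle: blurring a step edge moves the
  # half level outward by less than the kernel FWHM)
  g <- vol_grid(c(61, 61, 61), c(1.5, 1.5, 1.5))
  arr <- array(0, g$dim)
  vol <- activity_volume(arr, g$spacing)
  vol$data[sphere_mask(as_grid(vol), c(0, 0, 0), 22)] <- 10
  blurred <- beta_smooth(vol, 300, sigma_ref_mm = 4.2 / (2 * sqrt(2 * log(2))))
  voi <- threshold_lesion_voi(blurred, c(0, 0, 0))
  ai <- which(voi$mask, arr.ind = TRUE)
  cc <- axis_coords(blurred)
  xs <- cc[[1]][ai[ai[, 2] == 31 & ai[, 3] == 31, 1]]
  width <- diff(range(xs)) + g$spacing[1]  # voxel-centre span -> extent
  expect_gte(width, 22 - g$spacing[1])
  expect_lte(width, 22 + 4.2 + g$spacing[1])
})

test_that("oversized or liver-merged components fall back to a 10 mm sphere", {
  g <- vol_grid(c(41, 41, 41), c(3, 3, 3))
  vol <- activity_volume(array(10, g$dim), g$spacing)  # everything "hot"
  voi <- threshold_lesion_voi(vol, c(0, 0, 0), max_volume_ml = 100)
  expect_equal(voi$kind, "sphere")
  expect_true(voi$dims_mm$fallback)
  expect_equal(voi_volume_ml(voi), 4 / 3 * pi * 0.5^3, tolerance = 0.25)
})

test_that("voi_stats computes sample statistics and guards its contract", {
  g <- vol_grid(c(11, 11, 11), c(2, 2, 2))
  arr <- array(0, g$dim)
  arr[1:3, 1, 1] <- c(8, 10, 12)
  vol <- activity_volume(arr, g$spacing)
  voi <- structure(list(mask = array(FALSE, g$dim), grid = g, kind = "test",
                        center = c(0, 0, 0), dims_mm = list()),
                   class = "voi_mask")
  voi$mask[1:3, 1, 1] <- TRUE
  st <- voi_stats(vol, voi)
  expect_equal(st$mean, 10)
  expect_equal(st$sd, 2)
  expect_equal(st$max, 12)
  expect_equal(st$volume_ml, 3 * 8 / 1000)
  # constant region
  vol2 <- activity_volume(array(7, g$dim), g$spacing)
  st2 <- voi_stats(vol2, voi)
  expect_equal(unlist(st2[c("mean", "sd", "max")]),
               c(mean = 7, sd = 0, max = 7))
  # single voxel: SD undefined
  one <- voi; one$mask[] <- FALSE; one$mask[1] <- TRUE
  expect_error(voi_stats(vol, one), "single-voxel")
  # different grid
  other <- activity_volume(array(1, g$dim), c(3, 3, 3))
  expect_error(voi_stats(other, voi), "different grids")
})

test_that("voi_stats is affine-equivariant", {
  set.seed(8)
  g <- vol_grid(c(9, 9, 9), c(2, 2, 2))
  vol <- activity_volume(array(rnorm(729), g$dim), g$spacing)
  voi <- make_sphere_voi(g, c(0, 0, 0), 10)
  st <- voi_stats(vol, voi)
  scaled <- activity_volume(3 * vol$data + 2, g$spacing)
  st2 <- voi_stats(scaled, voi)
  expect_equal(st2$mean, 3 * st$mean + 2)
  expect_equal(st2$max, 3 * st$max + 2)
  expect_equal(st2$sd, 3 * st$sd)
})
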