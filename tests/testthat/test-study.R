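test_that("the step-1 fixture selects factors 450, 450 and 600", {
  fx <- step1_fixture()
  sel <- select_optimal_beta(fx$scores, fx$lesions, fx$suvmax,
                             fx$reference_suvmax)
  opt <- sel$optimal
  expect_equal(opt$beta[opt$reduction_pct == 17], 450)
  expect_equal(opt$beta[opt$reduction_pct == 33], 450)
  expect_equal(opt$beta[opt$reduction_pct == 50], 600)
  expect_true(is.na(opt$beta[opt$reduction_pct == 67]))
  # eligibility pattern behind the selection
  el <- sel$eligibility
  expect_setequal(el$beta[el$reduction_pct == 17 & el$eligible], c(300, 450, 600))
  expect_setequal(el$beta[el$reduction_pct == 33 & el$eligible], c(450, 600))
  expect_setequal(el$beta[el$reduction_pct == 50 & el$eligible], 600)
})

test_that("selection respects single-eligible and empty eligible sets", {
  fx <- step1_fixture()
  # single eligible factor is returned regardless of the SUVmax tie-break
  fx50 <- dplyr::filter(fx$suvmax, TRUE)
  fx50$mean_suvmax[fx50$beta == 600] <- 99  # terrible SUVmax match
  sel <- select_optimal_beta(fx$scores, fx$lesions, fx50, fx$reference_suvmax)
  expect_equal(sel$optimal$beta[sel$optimal$reduction_pct == 50], 600)
  # no factor with all scores >= threshold -> no eligible factor
  bad <- dplyr::mutate(fx$scores, score = pmin(score, 1))
  sel2 <- select_optimal_beta(bad, fx$lesions, fx$suvmax, fx$reference_suvmax)
  expect_true(all(is.na(sel2$optimal$beta)))
  # missing condition is a fixture error
  expect_error(
    select_optimal_beta(dplyr::filter(fx$scores, !(reduction_pct == 17 & beta == 450)),
                        fx$lesions, fx$suvmax, fx$reference_suvmax),
    "missing conditions"
  )
})

test_that("raising the detectability threshold never enlarges eligibility", {
  fx <- step1_fixture()
  sizes <- vapply(c(80, 90, 94, 99), function(thr) {
    sel <- select_optimal_beta(fx$scores, fx$lesions, fx$suvmax,
                               fx$reference_suvmax,
                               detectability_threshold = thr)
    sum(sel$eligibility$eligible)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("the final recommendation weighs step-2 significance per reduction", {
  fx <- step1_fixture()
  sel <- select_optimal_beta(fx$scores, fx$lesions, fx$suvmax,
                             fx$reference_suvmax)
  worse_at_50 <- tibble::tibble(reduction_pct = c(17, 33, 50),
                                significant = c(FALSE, FALSE, TRUE))
  det_worse_33 <- tibble::tibble(reduction_pct = c(17, 33, 50),
                                 significant = c(FALSE, TRUE, TRUE))
  rec <- final_recommendation(sel, worse_at_50, det_worse_33)
  expect_equal(rec$reduction_pct, 17)
  expect_equal(rec$beta, 450)
  # nothing significantly worse -> the largest reduction with an eligible beta
  none <- tibble::tibble(reduction_pct = c(17, 33, 50),
                         significant = FALSE)
  rec2 <- final_recommendation(sel, none, none)
  expect_equal(rec2$reduction_pct, 50)
  expect_equal(rec2$beta, 600)
  # everything significantly worse -> fall back to the reference condition
  all_bad <- dplyr::mutate(none, significant = TRUE)
  rec3 <- final_recommendation(sel, all_bad, all_bad)
  expect_equal(rec3$reduction_pct, 0)
  expect_equal(rec3$beta, 300)
})

test_that("the Friedman statistic matches the closed form and friedman.test", {
  # rank sums {3, 6, 9} at n = 3, k = 3 -> 12/(3*3*4)*(9+36+81) - 36 = 6
  m <- matrix(c(1, 1, 1, 2, 2, 2, 3, 3, 3), nrow = 3)
  expect_equal(friedman_statistic(m)$statistic, 6)
  set.seed(5)
  for (i in 1:5) {
    x <- matrix(rnorm(8 * 4), 8, 4)  # continuous -> tie-free
    expect_equal(friedman_statistic(x)$statistic,
                 unname(stats::friedman.test(x)$statistic),
                 tolerance = 1e-10)
  }
})

test_that("identical conditions are never flagged against the reference", {
  d <- tidyr::expand_grid(subj = 1:10, cond = c("ref", "a", "b"))
  set.seed(6)
  base <- rnorm(10)
  d$val <- rep(base, each = 3)
  r <- compare_to_reference(d, val, subj, cond, "ref")
  expect_false(any(r$comparisons$significant))
})

test_that("the normality gate routes to the parametric and rank branches", {
  set.seed(1)
  d <- tidyr::expand_grid(subj = 1:20, cond = c("ref", "a"))
  d$val <- rnorm(40)
  expect_equal(compare_to_reference(d, val, subj, cond, "ref")$method, "rm_anova")
  d$val <- rexp(40)^3
  expect_equal(compare_to_reference(d, val, subj, cond, "ref")$method, "friedman")
  expect_error(compare_to_reference(d[d$subj < 3, ], val, subj, cond, "ref"),
               "insufficient")
})

test_that("a strong shift is detected with high power", {
  hits <- 0
  set.seed(31)
  for (rep in 1:100) {
    d <- tidyr::expand_grid(subj = 1:25, cond = c("ref", "a", "b"))
    d$val <- rexp(75) + ifelse(d$cond == "b", 4, 0)  # effect >> noise
    r <- compare_to_reference(d, val, subj, cond, "ref")
    cmp <- r$comparisons
    if (cmp$significant[cmp$condition == "b"] && !cmp$significant[cmp$condition == "a"]) {
      hits <- hits + 1
    }
  }
  expect_gt(hits / 100, 0.9)
})

test_that("phantom grids are deterministic and follow the expected trends", {
  spec <- nema_phantom_spec("4:1")
  acq <- acquisition_config(60, seed = 2)
  g1 <- run_phantom_grid(spec, acq, betas = c(150, 600), reductions = c(0, 0.67),
                         seed = 2, voxel_size = c(4, 4, 4))
  g2 <- run_phantom_grid(spec, acq, betas = c(150, 600), reductions = c(0, 0.67),
                         seed = 2, voxel_size = c(4, 4, 4))
  expect_identical(as.data.frame(g1), as.data.frame(g2))
  bv <- g1 |> dplyr::summarise(bv = bv[1], .by = c(reduction_pct, beta))
  expect_lt(bv$bv[bv$reduction_pct == 0 & bv$beta == 600],
            bv$bv[bv$reduction_pct == 0 & bv$beta == 150])
  expect_gt(bv$bv[bv$reduction_pct == 67 & bv$beta == 150],
            bv$bv[bv$reduction_pct == 0 & bv$beta == 150])
})

test_that("patient grids freeze VOIs and respond to smoothing as expected", {
  spec <- patient_spec()
  acq <- acquisition_config(120, seed = 4)
  pg <- run_patient_grid(spec, acq, betas = c(150, 300, 450, 600),
                         reductions = 0, seed = 4, voxel_size = c(4, 4, 4))
  # lesion SUVmax non-increasing in beta for every lesion
  by_lesion <- pg |>
    dplyr::arrange(beta) |>
    dplyr::summarise(mono = all(diff(lesion_suvmax) <= 1e-9), .by = lesion_id)
  expect_true(all(by_lesion$mono))
  # SBR is invariant to a global intensity rescale by construction
  expect_equal(pg$lesion_sbr, pg$lesion_suvmax / pg$liver_suvmean)
})

test_that("the zero-noise limit flags SNR as undefined", {
  spec <- patient_spec(lesions = default_lesions()[10, ])
  truth <- build_patient_volume(spec, voxel_size = c(4, 4, 4))
  liver <- make_sphere_voi(truth, spec$liver_voi_center, 30)
  st <- voi_stats(truth, liver)
  expect_equal(liver_noise(st$sd, st$mean), 0)
  expect_error(lesion_snr(10, liver_noise(st$sd, st$mean)), "> 0")
})
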