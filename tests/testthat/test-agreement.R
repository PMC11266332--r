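test_that("mean visual scores reproduce the transcribed reader table", {
  scores <- reader_scores_fixture()
  means <- mean_visual_score(scores, n_patients = 25)
  expect_equal(means$mean_score[means$condition == "0%-b300"], 2.60)
  expect_equal(means$mean_score[means$condition == "17%-b450"], 2.72)
  expect_equal(means$mean_score[means$condition == "33%-b450"], 2.40)
  expect_equal(means$mean_score[means$condition == "50%-b600"], 2.20)
})

test_that("mean visual score is bounded, reader-symmetric, and validated", {
  all3 <- tibble::tibble(reader = rep(1:2, each = 1), score = 3, count = 25)
  expect_equal(mean_visual_score(all3)$mean_score, 3)
  m <- tibble::tibble(reader = c(1, 1, 2, 2), score = c(2, 3, 2, 3),
                      count = c(17, 8, 3, 22))
  swapped <- dplyr::mutate(m, reader = 3 - reader)
  expect_equal(mean_visual_score(m), mean_visual_score(swapped))
  expect_gte(mean_visual_score(m)$mean_score, 0)
  expect_lte(mean_visual_score(m)$mean_score, 3)
  expect_error(mean_visual_score(m, n_patients = 10), "inconsistent")
  expect_error(mean_visual_score(dplyr::mutate(m, score = score + 2)), "0..3")
})

test_that("Cohen's kappa matches a brute-force oracle and its fixed points", {
  expect_equal(cohens_kappa(diag(c(5, 9, 3)))$kappa, 1)
  k <- cohens_kappa(matrix(c(20, 10, 5, 15), 2))
  expect_equal(k$kappa, 0.4, tolerance = 1e-12)
  expect_equal(k$p_observed, 0.7)
  expect_equal(k$p_expected, 0.5)
  # independence: table equal to the outer product of its margins
  indep <- outer(c(10, 30), c(5, 15)) / 10
  expect_equal(cohens_kappa(indep)$kappa, 0, tolerance = 1e-12)
  # random confusion-matrix readers vs the explicit-loop oracle
  for (seed in 1:5) {
    tab <- simulate_reader_pair(seed = seed, agreement = 0.5 + seed / 10)
    expect_equal(cohens_kappa(tab)$kappa, kappa_oracle(tab), tolerance = 1e-12)
  }
  expect_error(cohens_kappa(matrix(1, 2, 3)), "square")
  expect_error(cohens_kappa(diag(c(10, 0))), "degenerate")
})

test_that("kappa is invariant under simultaneous category permutation", {
  tab <- simulate_reader_pair(seed = 7)
  p <- c(3, 1, 4, 2)
  expect_equal(cohens_kappa(tab[p, p])$kappa, cohens_kappa(tab)$kappa)
})

test_that("ICC(A,1) matches the two-way ANOVA oracle to 1e-10", {
  cases <- list(
    matrix(c(1, 3, 5, 7, 2, 4, 6, 8), ncol = 2),
    matrix(c(9, 2, 5, 8, 2, 7, 8, 3, 6, 9, 2, 7), ncol = 2),
    cbind(c(1, 2, 3, 4, 5), c(1.2, 2.1, 3.3, 3.9, 5.2), c(0.8, 2.2, 2.9, 4.1, 4.8))
  )
  for (x in cases) {
    expect_equal(icc_absolute_single(x)$icc, icc_oracle(x), tolerance = 1e-10)
  }
})

test_that("ICC edge behaviour: perfect agreement, bounds, and the interval", {
  x <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  fit <- icc_absolute_single(x)
  expect_equal(fit$icc, 1)
  set.seed(2)
  for (i in 1:10) {
    y <- matrix(rnorm(12), ncol = 2)
    f <- icc_absolute_single(y)
    expect_lte(f$icc, 1)
    expect_lte(f$conf_low, f$icc + 1e-9)
    expect_gte(f$conf_high, f$icc - 1e-9)
  }
  expect_error(icc_absolute_single(matrix(1, 1, 2)), ">= 2")
  expect_error(icc_absolute_single(matrix(5, 4, 2)), "zero total variance")
})

test_that("lesion detectability fractions reproduce the transcribed counts", {
  counts <- lesion_counts_fixture()
  det <- detectability_fraction(counts, "17%-b450", "0%-b300")
  expect_equal(det$detectability_pct[det$reader == "1"], 100 * 74 / 76)
  expect_equal(det$detectability_pct[det$reader == "1"], 97.37, tolerance = 1e-3)
  pooled <- det$detectability_pct[det$reader == "pooled"]
  expect_equal(pooled, 100 * 147 / 153)
  expect_equal(pooled, 96.08, tolerance = 1e-3)
  same <- detectability_fraction(counts, "0%-b300", "0%-b300")
  expect_true(all(same$detectability_pct == 100))
  expect_error(detectability_fraction(counts, "17%-b450", "nope"), "reference")
})

test_that("published inter-rater statistics are consistent with their inputs", {
  # the transcribed lesion counts support an excellent-agreement ICC when
  # plausible per-patient splits are drawn; sanity check orders of magnitude
  counts <- lesion_counts_fixture()
  wide <- tidyr::pivot_wider(counts[, c("condition", "reader", "lesions_detected")],
                             names_from = "reader", values_from = "lesions_detected")
  fit <- icc_absolute_single(as.matrix(wide[, c("1", "2")]))
  expect_gt(fit$icc, 0.5)
})
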