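# Shared builders and independent oracles for the test suite.

# Coarse grid keeps most tests fast; geometry tests refine where needed.
coarse_phantom <- function(ratio = "4:1", voxel = 4) {
  spec <- nema_phantom_spec(ratio)
  list(spec = spec, truth = build_nema_phantom(spec, voxel_size = rep(voxel, 3)))
}

# Independent two-way ANOVA mean-squares oracle for ICC(A,1), via aov().
icc_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  df <- data.frame(
    y = as.vector(x),
    subj = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  a <- suppressWarnings(anova(aov(y ~ subj + rater, data = df)))
  MSR <- a["subj", "Mean Sq"]
  MSC <- a["rater", "Mean Sq"]
  MSE <- a["Residuals", "Mean Sq"]
  (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}

# Brute-force kappa: explicit observed/expected agreement sums.
kappa_oracle <- function(m) {
  n <- sum(m)
  po <- 0; pe <- 0
  for (i in seq_len(nrow(m))) {
    po <- po + m[i, i] / n
    pe <- pe + sum(m[i, ]) / n * sum(m[, i]) / n
  }
  (po - pe) / (1 - pe)
}

# Simulate two readers scoring the same latent truth through confusion
# matrices; returns a joint contingency table for kappa tests.
simulate_reader_pair <- function(n = 200, agreement = 0.8, levels = 4,
                                 seed = 42) {
  set.seed(seed)
  truth <- sample.int(levels, n, replace = TRUE)
  flip <- function(s) {
    ifelse(runif(n) < agreement, s, sample.int(levels, n, replace = TRUE))
  }
  r1 <- flip(truth); r2 <- flip(truth)
  table(factor(r1, 1:levels), factor(r2, 1:levels))
}
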