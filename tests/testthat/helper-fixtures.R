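# Shared fixtures, all generated in code.

# Two well-separated Gaussian clouds, n per class, p features (all informative).
toy_separable <- function(n = 40, p = 5, delta = 1.5, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n * p, -delta), n),
               matrix(rnorm(n * p, delta), n))
    colnames(x) <- paste0("f", seq_len(p))
    rownames(x) <- paste0("s", seq_len(2 * n))
    list(x = x, y = rep(c("CTRL", "EC"), each = n))
  })
}

# Pure-noise matrix with balanced labels independent of the features.
toy_null <- function(n = 40, p = 10, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n)
    colnames(x) <- paste0("f", seq_len(p))
    rownames(x) <- paste0("s", seq_len(n))
    list(x = x, y = rep(c("CTRL", "EC"), length.out = n)[sample(n)])
  })
}

# A small clean cohort with batches for QC tests.
qc_fixture <- function(n = 75, p = 40, seed = 5) {
  pt <- generate_cohort(cohort_config(
    n_ctrl = ceiling(n / 2), n_ec = floor(n / 2), n_features = p,
    effect_features = default_effects()[0, ], missing_rate = 0, seed = seed))
  list(table = pt, batches = generate_batches(pt, seed = seed + 1))
}
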