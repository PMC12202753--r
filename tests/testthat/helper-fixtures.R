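# Shared fixture builders; everything is generated in code at test time.

# small complete dataset for structural checks
small_dataset <- function(n = 300, M = 10, J = 3, rho = 0.5, seed = 11,
                          gamma = c(0.5, 0.8), beta = numeric(0), ...) {
  cfg <- sim_config(n = n, M = M, J = J, rho = rho, gamma = gamma,
                    beta = beta, seed = seed, ...)
  sim_dataset(cfg)
}

# intercept-only null fit with prescribed category counts
counts_fit <- function(counts) {
  y <- rep(seq_along(counts) - 1L, counts)
  fit_null(y, NULL)
}

expect_prob_matrix <- function(P) {
  expect_true(all(P > 0 & P < 1))
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-12)
}
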