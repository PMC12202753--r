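test_that("beta weights match the closed-form squared Beta(1/2,1/2) density", {
  expect_equal(beta_weights(0.5)$weights, (2 / pi)^2, tolerance = 1e-9)
  expect_equal(beta_weights(0.1)$weights, (1 / (0.3 * pi))^2, tolerance = 1e-9)
  expect_equal(beta_weights(0.25)$weights, 1 / (pi^2 * 0.1875), tolerance = 1e-9)
  # folding: f and 1-f give the same weight
  expect_equal(beta_weights(0.9)$weights, beta_weights(0.1)$weights)
  expect_error(beta_weights(0), "monomorphic")
  expect_error(beta_weights(1), "monomorphic")
})

test_that("residualization centers and orthogonalizes genotypes", {
  expect_equal(drop(residualize_genotypes(matrix(c(0, 1, 2, 1), 4), NULL)),
               c(-1, 0, 1, 0), ignore_attr = TRUE)
  d <- small_dataset(n = 200, M = 8, seed = 71)
  Gt <- residualize_genotypes(d$genotypes, d$X)
  expect_lt(max(abs(crossprod(cbind(1, d$X), Gt))), 1e-8)
  # column lying in the covariate span has zero residual and is flagged
  Gbad <- cbind(d$genotypes$dosages[, 1:2], lin = round((d$X[, 1] > 0)) * 0 + 1)
  Gt2 <- residualize_genotypes(Gbad, d$X)
  expect_true(attr(Gt2, "zero_cols")[["lin"]])
})

test_that("score statistic evaluates the weighted quadratic form", {
  expect_equal(skat_statistic(c(0.5, -0.5, 0.5, -0.5), rep(0, 4),
                              matrix(c(1, -1, 1, -1), 4), 1), 2)
  d <- small_dataset(n = 100, M = 5, seed = 81)
  fit <- fit_null(d$y, d$X)
  Gt <- residualize_genotypes(d$genotypes, d$X)
  w <- beta_weights(d$genotypes$maf)$weights
  T1 <- skat_statistic(d$y, fit$mu_hat, Gt, w)
  expect_gte(T1, 0)
  expect_equal(skat_statistic(d$y, d$y, Gt, w), 0)        # y = mu exactly
  expect_equal(skat_statistic(d$y, fit$mu_hat, Gt, 2 * w), 2 * T1)
})

test_that("mixture spectrum has the rank-1 closed form and stated moments", {
  lam <- mixture_eigenvalues(matrix(c(1, -1), 2), 1, c(0.25, 0.25))
  expect_equal(lam$lambdas, 0.25, tolerance = 1e-12)
  sp <- mixture_spectrum(c(2, 1))
  expect_equal(sp$ET, 3)
  expect_equal(sp$VarT, 10)
  expect_equal(sp$M3, 72)
  expect_equal(sp$xi, 72 / 10^1.5, tolerance = 1e-12)
  expect_true(all(diff(sp$lambdas) <= 0))
})

test_that("M x M and n x n eigen routes agree on the nonzero spectrum", {
  for (s in 1:3) {
    d <- small_dataset(n = 40, M = 6, seed = 100 + s)
    fit <- fit_null(d$y, d$X)
    Gt <- residualize_genotypes(d$genotypes, d$X)
    w <- beta_weights(d$genotypes$maf)$weights
    sp <- mixture_eigenvalues(Gt, w, fit$var_hat)
    # brute-force n x n route: 1/2 V^{1/2} Gt W Gt' V^{1/2}
    Vh <- sqrt(fit$var_hat)
    A <- 0.5 * (Vh * (Gt %*% (w * t(Gt)))) * rep(Vh, each = length(Vh))
    lam_n <- eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values
    lam_n <- lam_n[lam_n > 1e-10 * max(lam_n)]
    expect_equal(sp$lambdas, lam_n, tolerance = 1e-8)
  }
})

test_that("Pearson III parameters satisfy the moment-matching constraints", {
  par <- pearson3_params(2 * sqrt(2))
  expect_equal(par$scale_a, sqrt(2), tolerance = 1e-12)
  expect_equal(par$shape_b, 0.5, tolerance = 1e-12)
  expect_equal(par$location_c, -1 / sqrt(2), tolerance = 1e-12)
  for (xi in c(0.1, 1, 3, 10)) {
    pp <- pearson3_params(xi)
    expect_equal(pp$shape_b * pp$scale_a^2, 1, tolerance = 1e-12)
    expect_equal(pp$location_c + pp$shape_b * pp$scale_a, 0, tolerance = 1e-12)
  }
  expect_error(pearson3_params(0), "positive")
})

test_that("vanishing skewness recovers the normal tail", {
  sp <- mixture_spectrum(rep(1, 40000))   # xi -> 0: gamma -> normal
  T_at <- sp$ET + 1.96 * sqrt(sp$VarT)
  expect_lt(abs(pearson3_pvalue(T_at, sp)$p - 0.025), 1e-3)
})

test_that("single-eigenvalue Pearson III equals the scaled chi-square tail", {
  for (lam in c(1, 0.37, 12)) {
    sp <- mixture_spectrum(lam)
    expect_equal(pearson3_pvalue(lam * 3.8415, sp)$p,
                 pchisq(3.8415, 1, lower.tail = FALSE), tolerance = 1e-9)
  }
})

test_that("Pearson III matches a Monte-Carlo mixture tail", {
  set.seed(202)
  lam <- sort(rexp(10, rate = 2), decreasing = TRUE)
  sp <- mixture_spectrum(lam)
  draws <- numeric(2e5)
  for (l in lam) draws <- draws + l * rchisq(2e5, 1)
  for (q in c(0.6, 0.8, 0.95)) {
    T_at <- quantile(draws, q, names = FALSE)
    expect_lt(abs(pearson3_pvalue(T_at, sp)$p - mean(draws >= T_at)), 0.006)
  }
})

test_that("the end-to-end test is invariant to weight rescaling", {
  d <- small_dataset(n = 400, M = 12, seed = 301)
  w <- beta_weights(d$genotypes$maf)$weights
  p1 <- pom_skat_test(d$y, d$X, d$genotypes, weights = w)$p_value
  p7 <- pom_skat_test(d$y, d$X, d$genotypes, weights = 7 * w)$p_value
  expect_equal(p1, p7, tolerance = 1e-10)
  expect_equal(pom_skat_test(d$y, d$X, d$genotypes)$p_value, p1,
               tolerance = 1e-12)
})

test_that("the test is invariant to SNP order and joint subject permutation", {
  d <- small_dataset(n = 350, M = 9, seed = 302)
  p0 <- pom_skat_test(d$y, d$X, d$genotypes)$p_value
  set.seed(4)
  cols <- sample(9)
  p_cols <- pom_skat_test(d$y, d$X, d$genotypes$dosages[, cols])$p_value
  expect_equal(p_cols, p0, tolerance = 1e-10)
  rows <- sample(350)
  p_rows <- pom_skat_test(d$y[rows], d$X[rows, ],
                          d$genotypes$dosages[rows, ])$p_value
  expect_equal(p_rows, p0, tolerance = 1e-10)
})

test_that("monomorphic SNPs are dropped with a warning", {
  d <- small_dataset(n = 200, M = 5, seed = 303)
  Gm <- cbind(d$genotypes$dosages, mono = 0L)
  expect_warning(res <- pom_skat_test(d$y, d$X, Gm), "monomorphic")
  expect_equal(res$M_used, 5)
  expect_equal(res$M_dropped, 1)
  expect_equal(res$p_value, pom_skat_test(d$y, d$X, d$genotypes)$p_value,
               tolerance = 1e-12)
})

test_that("J = 2 runs through the identical machinery as a logistic model", {
  d <- small_dataset(n = 500, M = 8, J = 2, D = 0.4, seed = 304)
  res <- pom_skat_test(d$y, d$X, d$genotypes)
  expect_true(res$p_value > 0 && res$p_value < 1)
  ref <- glm(d$y ~ d$X, family = binomial)
  # same residuals y - mu as the logistic fit feed the statistic
  Gt <- residualize_genotypes(d$genotypes, d$X)
  w <- beta_weights(d$genotypes$maf)$weights
  T_log <- skat_statistic(d$y, fitted(ref), Gt, w)
  expect_equal(res$statistic_T, T_log, tolerance = 1e-6)
})

test_that("permutation p-value uses the add-one estimator and its bounds", {
  d <- small_dataset(n = 150, M = 4, seed = 305, gamma = c(0, 0))
  pp <- permutation_pvalue(d$y, d$X, d$genotypes, H = 199, seed = 9)
  expect_equal(pp$p, (1 + sum(pp$T_perm >= pp$T_obs)) / 200)
  expect_gte(pp$p, 1 / 200)
  expect_lte(pp$p, 1)
  expect_error(permutation_pvalue(rep(1L, 150), d$X, d$genotypes, H = 10),
               "constant")
})
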