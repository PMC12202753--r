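test_that("intercept-only cutpoints have their closed forms", {
  expect_equal(counts_fit(c(50, 50))$cutpoints, 0, tolerance = 1e-8)
  f3 <- counts_fit(c(30, 30, 30))
  expect_equal(f3$cutpoints, qlogis(c(1 / 3, 2 / 3)), tolerance = 1e-8)
  expect_true(f3$converged)
})

test_that("missing categories and bad designs raise explicit errors", {
  expect_error(fit_null(c(0, 0, 2, 2), NULL), "not observed: 1")
  X <- cbind(rnorm(60), rnorm(60))
  expect_error(fit_null(rep(0:2, 20), cbind(X, X[, 1] * 2)), "rank deficient")
})

test_that("fit agrees with MASS::polr (J >= 3) and glm (J = 2)", {
  skip_if_not_installed("MASS")
  d <- small_dataset(n = 800, J = 4, D = c(0.2, 0.5, 0.8), seed = 21)
  mine <- fit_null(d$y, d$X, se = TRUE)
  ref <- MASS::polr(factor(d$y) ~ d$X, Hess = TRUE)
  expect_equal(mine$loglik, as.numeric(logLik(ref)), tolerance = 1e-7)
  expect_equal(mine$gamma_hat, unname(coef(ref)), tolerance = 1e-4)
  expect_equal(mine$cutpoints, unname(ref$zeta), tolerance = 1e-4)

  d2 <- small_dataset(n = 800, J = 2, D = 0.5, seed = 22)
  mine2 <- fit_null(d2$y, d2$X, se = TRUE)
  ref2 <- glm(d2$y ~ d2$X, family = binomial)
  expect_equal(mine2$loglik, as.numeric(logLik(ref2)), tolerance = 1e-8)
  expect_equal(mine2$gamma_hat, unname(coef(ref2))[-1], tolerance = 1e-6)
  expect_equal(mine2$gamma_se,
               unname(summary(ref2)$coefficients[2:3, 2]), tolerance = 1e-5)
  # J=2 mean/variance are the Bernoulli moments of the logistic fit
  phat <- fitted(ref2)
  expect_equal(mine2$mu_hat, unname(phat), tolerance = 1e-6)
  expect_equal(mine2$var_hat, unname(phat * (1 - phat)), tolerance = 1e-6)
})

test_that("log-likelihood is a local maximum", {
  d <- small_dataset(n = 400, J = 3, seed = 31)
  fit <- pom_fit(d$y, d$X)
  set.seed(1)
  for (k in 1:20) {
    pert <- fit$theta + rnorm(length(fit$theta), sd = 0.05)
    if (any(diff(pert[seq_len(fit$J - 1)]) <= 0)) next
    ll <- pomskat:::.pom_core(pert, d$y, d$X, fit$J, ncol(d$X))$loglik
    expect_lte(ll, fit$loglik)
  }
})

test_that("category probabilities are a proper distribution", {
  d <- small_dataset(n = 500, J = 4, D = c(0.25, 0.5, 0.75), seed = 41)
  fit <- fit_null(d$y, d$X)
  P <- category_probs(fit)
  expect_prob_matrix(P)
  expect_equal(category_probs(counts_fit(c(20, 20, 20)))[1, ],
               rep(1 / 3, 3), tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("mean and variance match their definitional sums exactly", {
  d <- small_dataset(n = 500, J = 5, D = c(0.1, 0.35, 0.7, 0.9), seed = 51)
  fit <- fit_null(d$y, d$X)
  P <- category_probs(fit)
  j <- 0:(fit$J - 1)
  mu_def <- drop(P %*% j)
  var_def <- drop(P %*% j^2) - mu_def^2
  expect_equal(mean_response(fit), mu_def, tolerance = 1e-12)
  expect_equal(var_response(fit), var_def, tolerance = 1e-12)
  expect_equal(fit$mu_hat, mu_def, tolerance = 1e-12)
  expect_equal(fit$var_hat, var_def, tolerance = 1e-12)
  expect_true(all(fit$var_hat > 0))
  expect_true(all(fit$mu_hat > 0 & fit$mu_hat < fit$J - 1))
})

test_that("closed-form moments for simple fits", {
  fit <- counts_fit(c(70, 30))             # P(y=1)=0.3
  expect_equal(fit$mu_hat[1], 0.3, tolerance = 1e-7)
  expect_equal(fit$var_hat[1], 0.21, tolerance = 1e-7)
  f3 <- counts_fit(c(40, 40, 40))          # equal thirds: mu=1, var=2/3
  expect_equal(f3$mu_hat[1], 1, tolerance = 1e-7)
  expect_equal(f3$var_hat[1], 2 / 3, tolerance = 1e-7)
})

test_that("model moments match Monte-Carlo draws from the fitted law", {
  d <- small_dataset(n = 50, J = 4, D = c(0.3, 0.6, 0.85), seed = 61)
  fit <- fit_null(d$y, d$X)
  P <- category_probs(fit)
  set.seed(99)
  ndraw <- 1e6
  for (i in c(1, 25)) {
    draws <- sample(0:3, ndraw, replace = TRUE, prob = P[i, ])
    se_mu <- sqrt(fit$var_hat[i] / ndraw)
    expect_equal(mean(draws), fit$mu_hat[i], tolerance = 4 * se_mu / fit$mu_hat[i])
    expect_equal(var(draws), fit$var_hat[i], tolerance = 0.01)
  }
})

test_that("labeled categories remap by explicit level order", {
  lv <- c("none", "low", "moderate", "high")
  expect_identical(remap_ordinal(c("moderate", "none", "high"), lv),
                   c(2L, 0L, 3L))
  expect_error(remap_ordinal(c("none", "unknown"), lv), "unknown")
})
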