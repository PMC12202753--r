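## Null proportional odds model (covariates only) and the implied first two
## moments of the ordinal response, which feed the score statistic.

#' Fit the null proportional odds model (no SNP effects)
#'
#' Fits \eqn{logit P(y_i \le j) = \zeta_j - x_i^\top \gamma} by maximum
#' likelihood and stores, for every subject, the fitted category
#' probabilities' first two moments: \eqn{\hat\mu_i = \sum_{j=0}^{J-2}
#' P(y_i > j)} and \eqn{Var(y_i) = \hat\mu_i - \hat\mu_i^2 +
#' 2\sum_{j=1}^{J-2} j P(y_i > j)}.  These are the exceedance-sum identities
#' for the mean and variance of a score `0..J-1` random variable.
#'
#' @param y integer ordinal phenotype coded `0..J-1`, all categories observed.
#' @param X covariate matrix (no intercept), or `NULL` for an intercept-only
#'   fit.
#' @param se also compute standard errors for `gamma_hat`.
#' @return an object of class `pom_null_fit`: `cutpoints` (ascending
#'   \eqn{\zeta}), `gamma_hat`, `linear_predictor`, `mu_hat`, `var_hat`,
#'   `loglik`, `converged`, `J`, `n`, plus `gamma_se` when `se = TRUE`.
#' @examples
#' y <- rep(0:2, each = 30)
#' fit <- fit_null(y, NULL)
#' fit$cutpoints  # logit(1/3), logit(2/3)
#' @export
fit_null <- function(y, X = NULL, se = FALSE) {
  fit <- pom_fit(y, X, se = se)
  eta <- if (length(fit$coef)) drop(as.matrix(X) %*% fit$coef) else rep(0, fit$n)
  exc <- .exceedance_probs(fit$zeta, eta)    # n x (J-1), P(y > j)
  out <- list(
    cutpoints = fit$zeta,
    gamma_hat = fit$coef,
    linear_predictor = eta,
    mu_hat = rowSums(exc),
    var_hat = .var_from_exceedance(exc),
    loglik = fit$loglik,
    converged = fit$converged,
    theta = fit$theta,
    J = fit$J,
    n = fit$n
  )
  if (se && length(fit$coef)) {
    out$gamma_se <- fit$coef_se
    out$vcov_gamma <- fit$vcov_coef
  }
  class(out) <- "pom_null_fit"
  out
}

# P(y > j) for j = 0..J-2 given ascending cutpoints and linear predictor
.exceedance_probs <- function(zeta, eta) {
  n <- length(eta)
  J1 <- length(zeta)
  exc <- matrix(0, n, J1)
  for (j in seq_len(J1)) exc[, j] <- stats::plogis(eta - zeta[j])
  exc
}

.var_from_exceedance <- function(exc) {
  mu <- rowSums(exc)
  J1 <- ncol(exc)
  extra <- if (J1 >= 2L) {
    drop(exc[, 2:J1, drop = FALSE] %*% (2 * seq_len(J1 - 1L)))
  } else 0
  mu - mu^2 + extra
}

#' Fitted category probabilities under a null proportional odds fit
#'
#' @param fit a `pom_null_fit`.
#' @param X covariate matrix on the same columns as the fit; defaults to the
#'   linear predictor stored in the fit.
#' @return n x J matrix of \eqn{P(y_i = j)}; rows sum to one.
#' @export
category_probs <- function(fit, X = NULL) {
  eta <- if (is.null(X)) fit$linear_predictor
         else if (length(fit$gamma_hat)) drop(as.matrix(X) %*% fit$gamma_hat)
         else rep(0, nrow(as.matrix(X)))
  J <- fit$J
  cum <- vapply(fit$cutpoints, function(z) stats::plogis(z - eta), numeric(length(eta)))
  cum <- cbind(matrix(cum, ncol = J - 1L), 1)
  probs <- cum - cbind(0, cum[, -J, drop = FALSE])
  colnames(probs) <- paste0("P", 0:(J - 1L))
  probs
}

#' Null mean of the ordinal response
#'
#' \eqn{\hat\mu_i = \sum_{j=0}^{J-2} P(y_i > j)}, identical to
#' \eqn{\sum_j j P(y_i = j)}.
#'
#' @inheritParams category_probs
#' @return numeric vector of length n.
#' @export
mean_response <- function(fit, X = NULL) {
  eta <- if (is.null(X)) fit$linear_predictor
         else if (length(fit$gamma_hat)) drop(as.matrix(X) %*% fit$gamma_hat)
         else rep(0, nrow(as.matrix(X)))
  rowSums(.exceedance_probs(fit$cutpoints, eta))
}

#' Null variance of the ordinal response
#'
#' \eqn{Var(y_i) = \hat\mu_i - \hat\mu_i^2 + 2\sum_{j=1}^{J-2} j P(y_i > j)},
#' identical to \eqn{\sum_j j^2 P(y_i = j) - \hat\mu_i^2}.
#'
#' @inheritParams category_probs
#' @return positive numeric vector of length n.
#' @export
var_response <- function(fit, X = NULL) {
  eta <- if (is.null(X)) fit$linear_predictor
         else if (length(fit$gamma_hat)) drop(as.matrix(X) %*% fit$gamma_hat)
         else rep(0, nrow(as.matrix(X)))
  .var_from_exceedance(.exceedance_probs(fit$cutpoints, eta))
}

#' Map labeled ordered categories to consecutive integer scores
#'
#' The test statistic scores the phenotype as consecutive integers
#' `0..J-1`; labeled data must declare the category order explicitly.
#'
#' @param values vector of category labels.
#' @param level_order character vector giving the levels from lowest to
#'   highest; every observed value must appear in it.
#' @return integer vector in `0..J-1`.
#' @export
remap_ordinal <- function(values, level_order) {
  idx <- match(as.character(values), as.character(level_order))
  if (anyNA(idx)) {
    bad <- unique(values[is.na(idx)])
    stop("phenotype value(s) not in level_order: ", paste(bad, collapse = ", "))
  }
  as.integer(idx - 1L)
}

#' @export
print.pom_null_fit <- function(x, ...) {
  cat("Null proportional odds fit:", x$n, "subjects,", x$J, "categories\n")
  cat("  cutpoints:", paste(sprintf("%.4f", x$cutpoints), collapse = ", "), "\n")
  if (length(x$gamma_hat)) {
    cat("  gamma_hat:", paste(sprintf("%.4f", x$gamma_hat), collapse = ", "), "\n")
  }
  cat(sprintf("  loglik: %.4f  converged: %s\n", x$loglik, x$converged))
  invisible(x)
}
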