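## POM-SKAT: variance-component score test for a SNP set under the
## proportional odds model.  Statistic
##   T = 1/2 (y - mu)' Gt W Gt' (y - mu),
## null law sum_m lambda_m chi^2_1 with lambda the eigenvalues of
## 1/2 V^{1/2} Gt W Gt' V^{1/2}; p-value from a Pearson Type III (shifted
## gamma) matched to the mixture's first three moments.

#' Beta-density kernel weights from minor allele frequencies
#'
#' Weight for SNP `m` is the squared Beta(1/2, 1/2) density at its minor
#' allele frequency: \eqn{w_m = [1/(\pi\sqrt{f_m(1-f_m)})]^2} for the default
#' shape parameters.  Frequencies are folded to the minor allele internally.
#'
#' @param maf allele frequencies in `(0,1)`; monomorphic SNPs (0 or 1) are an
#'   error — drop them before weighting.
#' @param a,b Beta density shape parameters (defaults 0.5, 0.5).
#' @return a `kernel_weights` list: `weights`, `maf_used` (folded), `spec`.
#' @examples
#' beta_weights(0.5)$weights  # (2/pi)^2 = 0.405285
#' @export
beta_weights <- function(maf, a = 0.5, b = 0.5) {
  if (any(!is.finite(maf)) || any(maf <= 0) || any(maf >= 1)) {
    stop("monomorphic or invalid MAF (must lie strictly in (0,1)); ",
         "drop monomorphic SNPs before weighting")
  }
  f <- pmin(maf, 1 - maf)
  w <- stats::dbeta(f, a, b)^2
  structure(list(weights = w, maf_used = f, spec = c(beta_a = a, beta_b = b)),
            class = "kernel_weights")
}

#' Residualize genotypes on covariates
#'
#' Removes from each dosage column its least-squares projection onto
#' `[1, X]`, centering out covariate-genotype confounding; every returned
#' column is orthogonal to the intercept and to each covariate.
#'
#' @param G `genotype_matrix` or numeric dosage matrix.
#' @param X covariate matrix or `NULL` (intercept-only: plain centering).
#' @return n x M residual matrix; attribute `zero_cols` flags columns whose
#'   residual is numerically zero (genotype in the span of the covariates).
#' @export
residualize_genotypes <- function(G, X = NULL) {
  Gd <- .dosage_matrix(G)
  n <- nrow(Gd)
  B <- if (is.null(X) || NCOL(X) == 0L) matrix(1, n, 1L) else cbind(1, as.matrix(X))
  qr_ <- qr(B)
  if (qr_$rank < ncol(B)) stop("covariate matrix is rank deficient")
  Gt <- qr.resid(qr_, Gd)
  zero <- colSums(Gt^2) < 1e-12 * n
  structure(Gt, zero_cols = zero)
}

#' Score statistic for the weighted linear kernel
#'
#' \eqn{T = \frac12 \sum_m w_m (\tilde g_m^\top (y - \hat\mu))^2}, evaluated
#' column-wise without forming the n x n kernel.
#'
#' @param y integer phenotype scores; `mu_hat` fitted null means;
#'   `G_tilde` residualized genotypes; `weights` per-SNP weights (vector or
#'   `kernel_weights`).
#' @param mu_hat,G_tilde,weights see above.
#' @return nonnegative scalar.
#' @export
skat_statistic <- function(y, mu_hat, G_tilde, weights) {
  w <- if (inherits(weights, "kernel_weights")) weights$weights else weights
  s <- drop(crossprod(G_tilde, y - mu_hat))
  0.5 * sum(w * s^2)
}

#' Eigenvalue spectrum of the null mixture of chi-squares
#'
#' The statistic's null law is \eqn{\sum_m \lambda_m \chi^2_1} with
#' \eqn{\lambda} the nonzero eigenvalues of
#' \eqn{\frac12 V^{1/2} \tilde G W \tilde G^\top V^{1/2}}; these are computed
#' from the spectrally equivalent M x M form
#' \eqn{\frac12 W^{1/2} \tilde G^\top V \tilde G W^{1/2}}.  Eigenvalues below
#' `1e-10 * max(lambda)` are treated as numerical rank deficiency and
#' discarded.
#'
#' @param G_tilde residualized genotype matrix; `weights` per-SNP weights;
#'   `var_hat` per-subject null variances (positive).
#' @param weights,var_hat see above.
#' @return a `mixture_spectrum`: descending `lambdas` and the moments
#'   `ET` \eqn{= \sum\lambda}, `VarT` \eqn{= 2\sum\lambda^2},
#'   `M3` \eqn{= 8\sum\lambda^3}, skewness `xi` \eqn{= M3 / VarT^{3/2}}.
#' @export
mixture_eigenvalues <- function(G_tilde, weights, var_hat) {
  w <- if (inherits(weights, "kernel_weights")) weights$weights else weights
  if (any(var_hat <= 0)) stop("null variances must be positive")
  sw <- sqrt(w)
  K <- crossprod(G_tilde, G_tilde * var_hat)       # M x M, Gt' V Gt
  A <- 0.5 * (sw %o% sw) * K
  lam <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > 1e-10 * max(lam, 0)]
  if (!length(lam)) stop("empty mixture spectrum: all SNP columns degenerate")
  mixture_spectrum(lam)
}

#' Assemble a mixture spectrum from eigenvalues
#'
#' @param lambdas positive mixture coefficients.
#' @return `mixture_spectrum` with moments and skewness.
#' @export
mixture_spectrum <- function(lambdas) {
  lam <- sort(lambdas, decreasing = TRUE)
  VarT <- 2 * sum(lam^2)
  M3 <- 8 * sum(lam^3)
  structure(list(lambdas = lam, ET = sum(lam), VarT = VarT, M3 = M3,
                 xi = M3 / VarT^1.5),
            class = "mixture_spectrum")
}

#' Pearson Type III parameters matched to (0, 1, xi)
#'
#' The standardized statistic is approximated by the shifted gamma with zero
#' mean, unit variance and skewness `xi`: scale \eqn{a = \xi/2}, shape
#' \eqn{b = 4/\xi^2}, location \eqn{c = -2/\xi}; these satisfy
#' \eqn{b a^2 = 1} and \eqn{c + b a = 0}.
#'
#' @param xi positive skewness.
#' @return list with `scale_a`, `shape_b`, `location_c`.
#' @export
pearson3_params <- function(xi) {
  if (!is.finite(xi) || xi <= 0) stop("skewness must be positive")
  list(scale_a = xi / 2, shape_b = 4 / xi^2, location_c = -2 / xi)
}

#' Upper-tail Pearson Type III p-value for the score statistic
#'
#' Standardizes `T` by the mixture moments and evaluates the upper tail of
#' the moment-matched shifted gamma.  For a single eigenvalue the
#' approximation is exact: it reduces to the \eqn{\lambda\chi^2_1} tail.
#'
#' @param T observed statistic; `spectrum` a `mixture_spectrum`.
#' @param spectrum see above.
#' @return list with `p`, `T_star` and the Pearson III `params`.
#' @export
pearson3_pvalue <- function(T, spectrum) {
  T_star <- (T - spectrum$ET) / sqrt(spectrum$VarT)
  par <- pearson3_params(spectrum$xi)
  q <- (T_star - par$location_c) / par$scale_a
  p <- if (q <= 0) 1 else stats::pgamma(q, shape = par$shape_b, lower.tail = FALSE)
  list(p = p, T_star = T_star, params = par)
}

# shared validation + preprocessing for the set test
.prepare_set <- function(y, X, G, a = 0.5, b = 0.5, set = "set1") {
  y <- as.integer(y)
  if (any(y < 0)) stop("phenotype must be coded 0..J-1")
  Gd <- .dosage_matrix(G)
  if (nrow(Gd) != length(y)) stop("genotypes and phenotype have different lengths")
  M_all <- ncol(Gd)
  keep <- seq_len(M_all)
  p_hat <- colMeans(Gd) / 2
  maf <- pmin(p_hat, 1 - p_hat)
  mono <- maf <= 0
  if (any(mono)) {
    warning(sprintf("[%s] dropping %d monomorphic SNP(s): %s", set, sum(mono),
                    paste(colnames(Gd)[mono], collapse = ", ")))
    Gd <- Gd[, !mono, drop = FALSE]
    maf <- maf[!mono]
    keep <- keep[!mono]
  }
  if (!ncol(Gd)) stop(sprintf("[%s] no polymorphic SNPs left to test", set))
  Gt <- residualize_genotypes(Gd, X)
  zero <- attr(Gt, "zero_cols")
  if (any(zero)) {
    warning(sprintf("[%s] dropping %d SNP(s) with zero residual variance: %s",
                    set, sum(zero), paste(colnames(Gd)[zero], collapse = ", ")))
    Gt <- Gt[, !zero, drop = FALSE]
    maf <- maf[!zero]
    keep <- keep[!zero]
  }
  if (!ncol(Gt)) stop(sprintf("[%s] all SNPs collinear with covariates", set))
  list(y = y, Gt = Gt, maf = maf, keep = keep,
       M_used = ncol(Gt), M_dropped = M_all - ncol(Gt))
}

#' POM-SKAT: kernel association test of a SNP set with an ordinal phenotype
#'
#' End-to-end test: fits the null proportional odds model on the covariates,
#' residualizes the genotypes, applies squared Beta(a,b)-density MAF weights,
#' computes the score statistic and its mixture-of-chi-squares spectrum, and
#' returns the Pearson Type III p-value.  Monomorphic SNPs and SNPs collinear
#' with the covariates are dropped with a warning.
#'
#' @param y ordinal phenotype coded `0..J-1` (consecutive integers, all
#'   observed); use [remap_ordinal()] for labeled categories.
#' @param X covariate matrix or `NULL`.
#' @param G `genotype_matrix` or n x M dosage matrix.
#' @param weights `NULL` for the default squared Beta(0.5, 0.5) density
#'   weights computed from the sample MAF, or a numeric vector of length M.
#' @param a,b Beta weight shape parameters when `weights` is `NULL`.
#' @param set label for reporting.
#' @return a `pomskat_result`: `statistic_T`, `T_star`, `p_value`,
#'   `spectrum`, `null_fit`, `method`, `set`, `n`, `M_used`, `M_dropped`, `J`.
#' @examples
#' cfg <- sim_config(n = 300, M = 10, J = 3, rho = 0.5, seed = 7)
#' d <- sim_dataset(cfg)
#' pom_skat_test(d$y, d$X, d$genotypes)$p_value
#' @export
pom_skat_test <- function(y, X, G, weights = NULL, a = 0.5, b = 0.5,
                          set = "set1") {
  prep <- .prepare_set(y, X, G, a, b, set = set)
  w <- if (is.null(weights)) {
    beta_weights(prep$maf, a, b)$weights
  } else {
    wfull <- if (inherits(weights, "kernel_weights")) weights$weights else weights
    if (length(wfull) == ncol(.dosage_matrix(G))) wfull[prep$keep] else wfull
  }
  fit <- fit_null(prep$y, X)
  T_obs <- skat_statistic(prep$y, fit$mu_hat, prep$Gt, w)
  spec <- mixture_eigenvalues(prep$Gt, w, fit$var_hat)
  pv <- pearson3_pvalue(T_obs, spec)
  structure(list(statistic_T = T_obs, T_star = pv$T_star, p_value = pv$p,
                 spectrum = spec, null_fit = fit, method = "POM-SKAT",
                 set = set, n = length(prep$y), M_used = prep$M_used,
                 M_dropped = prep$M_dropped, J = fit$J,
                 weight_spec = if (is.null(weights)) sprintf("beta:%g,%g", a, b)
                               else "user"),
            class = "pomskat_result")
}

#' @export
print.pomskat_result <- function(x, ...) {
  cat(sprintf("%s  set=%s  n=%d  J=%d  M=%d (%d dropped)\n",
              x$method, x$set, x$n, x$J, x$M_used, x$M_dropped))
  cat(sprintf("  T = %.4f   T* = %.4f   xi = %.4f   p = %.4g\n",
              x$statistic_T, x$T_star, x$spectrum$xi, x$p_value))
  invisible(x)
}

#' Permutation p-value for the score statistic
#'
#' Re-sampling reference for the Pearson Type III approximation: the
#' phenotype vector is permuted `H` times; for each permutation the null
#' model is refit and the statistic recomputed (the residualized genotypes
#' depend only on `G` and `X` and are unchanged by phenotype permutation).
#' Permutations that leave a phenotype category empty cannot occur for a
#' permutation of a complete vector; a degenerate constant phenotype is an
#' error.
#'
#' @param y,X,G as in [pom_skat_test()].
#' @param weights optional per-SNP weights (default squared Beta(0.5,0.5)
#'   density at the sample MAF).
#' @param H number of permutations.
#' @param seed optional RNG seed.
#' @return list with the add-one permutation `p`, the observed statistic
#'   `T_obs`, and `T_perm`.
#' @export
permutation_pvalue <- function(y, X, G, weights = NULL, H = 1000L,
                               seed = NULL) {
  if (H < 1) stop("H must be at least 1")
  if (length(unique(y)) < 2L) stop("phenotype is constant; test is degenerate")
  if (!is.null(seed)) set.seed(seed)
  prep <- .prepare_set(y, X, G)
  w <- if (is.null(weights)) beta_weights(prep$maf)$weights
       else if (inherits(weights, "kernel_weights")) weights$weights else weights
  fit0 <- fit_null(prep$y, X)
  T_obs <- skat_statistic(prep$y, fit0$mu_hat, prep$Gt, w)
  T_perm <- numeric(H)
  for (h in seq_len(H)) {
    yp <- sample(prep$y)
    fit_p <- pom_fit(yp, X, start = fit0$theta)
    eta <- if (length(fit_p$coef)) drop(as.matrix(X) %*% fit_p$coef)
           else rep(0, length(yp))
    mu_p <- rowSums(.exceedance_probs(fit_p$zeta, eta))
    T_perm[h] <- skat_statistic(yp, mu_p, prep$Gt, w)
  }
  list(p = (1 + sum(T_perm >= T_obs)) / (H + 1), T_obs = T_obs,
       T_perm = T_perm)
}
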