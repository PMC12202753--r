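## Baseline set tests: PCA + likelihood ratio, per-SNP minimum p with
## permutation, Bonferroni, and the joint "quadratic" likelihood-ratio test.

#' Principal component reduction of a genotype matrix
#'
#' PCA on the column correlation matrix (columns standardized); retains the
#' smallest number of leading components whose cumulative eigenvalue
#' proportion reaches `threshold`.
#'
#' @param G `genotype_matrix` or dosage matrix; every column must vary.
#' @param threshold cumulative variance proportion to capture (default 0.80).
#' @return a `pca_reduction`: `scores` (n x L), `loadings` (M x L, unit
#'   norm), `explained` (first L eigenvalue proportions), `L`.
#' @export
pca_reduce <- function(G, threshold = 0.80) {
  Gd <- .dosage_matrix(G)
  sds <- apply(Gd, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant genotype column(s): ",
         paste(colnames(Gd)[sds == 0], collapse = ", "))
  }
  Z <- scale(Gd)
  eg <- eigen(stats::cor(Gd), symmetric = TRUE)
  prop <- eg$values / ncol(Gd)
  L <- which(cumsum(prop) >= threshold - 1e-12)[1L]
  loadings <- eg$vectors[, seq_len(L), drop = FALSE]
  structure(list(scores = Z %*% loadings, loadings = loadings,
                 explained = prop[seq_len(L)], L = L),
            class = "pca_reduction")
}

#' Likelihood ratio test on leading principal components
#'
#' Fits the proportional odds model with covariates plus the first L
#' principal component scores of the SNP set against the covariates-only
#' model; twice the log-likelihood gap is referred to \eqn{\chi^2_L}.
#'
#' @param y,X,G as in [pom_skat_test()].
#' @param threshold variance proportion defining L.
#' @return p-value with attributes `L` and `statistic`.
#' @export
pca_lrt_test <- function(y, X, G, threshold = 0.80) {
  red <- pca_reduce(G, threshold)
  X0 <- if (is.null(X)) NULL else as.matrix(X)
  fit0 <- pom_fit(y, X0)
  fit1 <- pom_fit(y, if (is.null(X0)) red$scores else cbind(X0, red$scores))
  stat <- max(0, 2 * (fit1$loglik - fit0$loglik))
  p <- stats::pchisq(stat, df = red$L, lower.tail = FALSE)
  structure(p, L = red$L, statistic = stat)
}

#' Per-SNP Wald p-values under the proportional odds model
#'
#' Each SNP is tested one at a time in a proportional odds model with the
#' covariates; the Wald statistic \eqn{\hat\beta_m / SE(\hat\beta_m)} is
#' referred to the standard normal (the asymptotic reference for the POM
#' coefficient).  SNPs whose fit fails are returned as `NA` with a warning.
#'
#' @param y,X,G as in [pom_skat_test()].
#' @return numeric vector of M p-values (named by SNP id).
#' @export
single_snp_pvalues <- function(y, X, G) {
  Gd <- .dosage_matrix(G)
  X0 <- if (is.null(X)) NULL else as.matrix(X)
  p <- rep(NA_real_, ncol(Gd))
  names(p) <- colnames(Gd)
  for (m in seq_len(ncol(Gd))) {
    fit <- tryCatch(
      pom_fit(y, if (is.null(X0)) Gd[, m, drop = FALSE]
                 else cbind(X0, Gd[, m]), se = TRUE),
      error = function(e) NULL)
    if (is.null(fit)) next
    k <- length(fit$coef)
    z <- fit$coef[k] / fit$coef_se[k]
    p[m] <- 2 * stats::pnorm(-abs(z))
  }
  if (anyNA(p)) {
    warning("single-SNP fit failed for: ",
            paste(names(p)[is.na(p)], collapse = ", "))
  }
  p
}

#' Minimum-p permutation test over a SNP set
#'
#' The observed statistic is the smallest per-SNP p-value; its reference
#' distribution comes from `R` random permutations of the phenotype vector
#' (covariates left in place), with the add-one estimator
#' \eqn{(1 + \#\{minp_r \le minp\}) / (R + 1)}.
#'
#' @param y,X,G as in [pom_skat_test()].
#' @param R permutation count; `seed` optional RNG seed.
#' @param seed see above.
#' @return list with `p`, the observed `minp`, and the permuted minima.
#' @export
minp_permutation_test <- function(y, X, G, R = 1000L, seed = NULL) {
  if (R < 1) stop("R must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  obs <- min(single_snp_pvalues(y, X, G), na.rm = TRUE)
  minp_r <- numeric(R)
  for (r in seq_len(R)) {
    minp_r[r] <- suppressWarnings(
      min(single_snp_pvalues(sample(y), X, G), na.rm = TRUE))
  }
  list(p = (1 + sum(minp_r <= obs)) / (R + 1), minp = obs, minp_perm = minp_r)
}

#' Bonferroni-adjusted minimum p-value
#'
#' @param pvalues per-SNP p-values (NAs ignored).
#' @return `min(1, M * min(p))` with `M` the number of non-missing tests.
#' @export
bonferroni_test <- function(pvalues) {
  p <- pvalues[!is.na(pvalues)]
  if (!length(p)) stop("no p-values to adjust")
  min(1, length(p) * min(p))
}

#' Joint likelihood-ratio ("quadratic") test of all SNPs
#'
#' Fits the proportional odds model with all M SNP dosages jointly (plus
#' covariates) against the covariates-only model; the deviance is referred
#' to \eqn{\chi^2_M}.  Fails explicitly when the joint design is collinear
#' or M is too large to estimate — the classical method's known failure mode
#' for large SNP sets.
#'
#' @param y,X,G as in [pom_skat_test()].
#' @return p-value with attributes `df` and `statistic`.
#' @export
qt_test <- function(y, X, G) {
  Gd <- .dosage_matrix(G)
  X0 <- if (is.null(X)) NULL else as.matrix(X)
  M <- ncol(Gd)
  full <- if (is.null(X0)) Gd else cbind(X0, Gd)
  if (qr(cbind(1, full))$rank < ncol(full) + 1L) {
    stop("joint SNP design is collinear; the quadratic test is not estimable ",
         "for this set (M = ", M, ")")
  }
  fit0 <- pom_fit(y, X0)
  fit1 <- pom_fit(y, full)
  stat <- max(0, 2 * (fit1$loglik - fit0$loglik))
  p <- stats::pchisq(stat, df = M, lower.tail = FALSE)
  structure(p, df = M, statistic = stat)
}
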