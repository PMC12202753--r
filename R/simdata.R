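## Simulator for the study conditions: AR(1) Gaussian-copula genotypes with
## Hardy-Weinberg thresholding, bivariate normal covariates, and ordinal
## phenotypes obtained by truncating a logistic-error latent trait at
## empirical quantiles.

#' Equally spaced minor allele frequency grid
#'
#' @param M number of SNPs.
#' @param lo,hi endpoints of the frequency range (defaults 0.1 and 0.45).
#' @return numeric vector of `M` frequencies; `lo` alone when `M = 1`.
#' @examples
#' maf_grid(3)  # 0.100 0.275 0.450
#' @export
maf_grid <- function(M, lo = 0.1, hi = 0.45) {
  if (length(M) != 1L || is.na(M) || M < 1) stop("M must be a positive integer")
  if (lo <= 0 || hi < lo || hi > 0.5) stop("need 0 < lo <= hi <= 0.5")
  if (M == 1) return(lo)
  seq(lo, hi, length.out = M)
}

#' Simulation configuration
#'
#' Bundles the parameters of one simulation scenario: subject count `n`, SNP
#' count `M`, category count `J`, AR(1) latent genotype correlation `rho`,
#' per-SNP minor allele frequencies `maf`, covariate effects `gamma`, causal
#' SNP effects `beta` (applied to the first `length(beta)` SNPs), pairwise
#' interaction effect `phi` between the first two SNPs, quantile truncation
#' probabilities `D` (length `J-1`, strictly increasing in (0,1)), and the
#' master RNG `seed`.
#'
#' @param n,M,J,rho,maf,gamma,beta,phi,D,seed see description.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n, M, J, rho, maf = maf_grid(M),
                       gamma = c(0.5, 0.8), beta = numeric(0), phi = 0,
                       D = NULL, seed = 1L) {
  if (is.null(D)) {
    D <- if (J == 3) c(0.16, 0.84) else seq_len(J - 1L) / J
  }
  if (J < 2) stop("J must be at least 2")
  if (length(D) != J - 1L) stop("D must have length J-1")
  if (any(D <= 0) || any(D >= 1) || any(diff(D) <= 0)) {
    stop("D must be strictly increasing within (0,1)")
  }
  if (rho < 0 || rho >= 1) stop("rho must lie in [0,1)")
  if (any(maf <= 0) || any(maf > 0.5)) stop("maf values must lie in (0, 0.5]")
  if (length(maf) != M) stop("maf must have length M")
  if (length(beta) > M) stop("more SNP effects than SNPs")
  structure(list(n = n, M = M, J = J, rho = rho, maf = maf, gamma = gamma,
                 beta = beta, phi = phi, D = D, seed = seed),
            class = "sim_config")
}

#' Replicate-specific RNG seed
#'
#' Pure affine mixing of (master seed, replicate index) modulo the prime
#' 2^31 - 1, so each replicate gets its own reproducible stream.
#'
#' @param master master seed (integer).
#' @param r replicate index (1-based).
#' @return integer seed.
#' @export
rep_seed <- function(master, r) {
  m <- 2147483647
  x <- ((as.numeric(master) %% m) * 48271 + as.numeric(r) * 1664525 + 1013904223) %% m
  as.integer(x)
}

#' Simulate genotype dosages with AR(1) linkage disequilibrium
#'
#' Each subject's latent vector is multivariate normal with covariance
#' \eqn{\rho^{|j-k|}}; SNP `m` with minor allele frequency `f` is thresholded
#' at the standard normal quantiles of \eqn{(1-f)^2} and \eqn{1-f^2}, so the
#' marginal dosage distribution is the Hardy-Weinberg
#' \eqn{((1-f)^2, 2f(1-f), f^2)}.
#'
#' @param n subjects; `M` SNPs; `rho` AR(1) latent correlation in `[0,1)`;
#'   `maf` vector of `M` frequencies in `(0,1)`; `seed` optional RNG seed
#'   (`NULL` uses the current RNG state).
#' @param M,rho,maf,seed see above.
#' @return a `genotype_matrix`: list with integer `dosages` (n x M, values
#'   0/1/2, SNP ids as column names), `snp_ids`, and the observed folded
#'   sample `maf`.
#' @export
gen_genotypes <- function(n, M, rho, maf = maf_grid(M), seed = NULL) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0,1)")
  if (any(maf <= 0) || any(maf >= 1)) stop("allele frequencies must lie in (0,1)")
  if (length(maf) == 1L) maf <- rep(maf, M)
  if (length(maf) != M) stop("maf must have length M")
  if (!is.null(seed)) set.seed(seed)
  Z <- matrix(stats::rnorm(n * M), n, M)
  if (rho > 0 && M > 1) {
    Sigma <- rho^abs(outer(seq_len(M), seq_len(M), "-"))
    Z <- Z %*% chol(Sigma)
  }
  q1 <- rep(stats::qnorm((1 - maf)^2), each = n)
  q2 <- rep(stats::qnorm(1 - maf^2), each = n)
  G <- matrix((Z > q1) + (Z > q2), n, M)
  storage.mode(G) <- "integer"
  colnames(G) <- paste0("snp", seq_len(M))
  .genotype_matrix_unchecked(G)
}

#' Construct a genotype matrix container
#'
#' @param dosages n x M matrix of 0/1/2 dosages.
#' @param snp_ids SNP identifiers (default: column names, else `snp1..M`).
#' @return `genotype_matrix` with folded sample minor allele frequencies.
#' @export
genotype_matrix <- function(dosages, snp_ids = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  rng <- range(dosages)
  if (rng[1L] < 0 || rng[2L] > 2 || any(dosages != round(dosages))) {
    stop("dosages must be 0, 1 or 2")
  }
  if (!is.null(snp_ids)) colnames(dosages) <- snp_ids
  .genotype_matrix_unchecked(dosages)
}

.genotype_matrix_unchecked <- function(dosages) {
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- paste0("snp", seq_len(ncol(dosages)))
  }
  p <- colMeans(dosages) / 2
  structure(list(dosages = dosages, snp_ids = colnames(dosages),
                 maf = pmin(p, 1 - p)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "subjects x", ncol(x$dosages),
      "SNPs; sample MAF range",
      sprintf("[%.3f, %.3f]\n", min(x$maf), max(x$maf)))
  invisible(x)
}

# accept either a genotype_matrix or a plain dosage matrix
.dosage_matrix <- function(G) {
  if (inherits(G, "genotype_matrix")) G$dosages else as.matrix(G)
}

#' Simulate bivariate normal covariates
#'
#' Rows i.i.d. \eqn{N_2(0, [[1, 0.5], [0.5, 1]])}.
#'
#' @param n subjects; `seed` optional RNG seed.
#' @param seed see above.
#' @return n x 2 matrix with columns `x1`, `x2`.
#' @export
gen_covariates <- function(n, seed = NULL) {
  if (n < 1) stop("n must be positive")
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(stats::rnorm(2 * n), n, 2) %*% chol(matrix(c(1, 0.5, 0.5, 1), 2))
  colnames(X) <- c("x1", "x2")
  X
}

#' Simulate an ordinal phenotype by quantile truncation
#'
#' The latent trait is \eqn{y_i = x_i^\top\gamma + g_i^\top\beta +
#' \phi g_{i1} g_{i2} + \epsilon_i} with standard logistic errors; the ordinal
#' phenotype cuts the realized latent vector at its own empirical quantiles at
#' probabilities `D` (linear-interpolation quantiles), so category
#' proportions equal `diff(c(0, D, 1))` up to rounding for every replicate.
#'
#' @param G `genotype_matrix` or dosage matrix; the first `length(beta)`
#'   columns carry the SNP effects.
#' @param X covariate matrix.
#' @param config a [sim_config()]; fields `gamma`, `beta`, `phi`, `D` used.
#' @return list with integer `y` in `0..J-1`, the continuous `latent`
#'   trait, and the `cutpoints` used.
#' @export
gen_ordinal_phenotype <- function(G, X, config) {
  D <- config$D
  if (config$J < 2) stop("J must be at least 2")
  if (any(D <= 0) || any(D >= 1)) stop("D must lie strictly within (0,1)")
  Gd <- .dosage_matrix(G)
  n <- nrow(Gd)
  eta <- drop(as.matrix(X) %*% config$gamma)
  B <- length(config$beta)
  if (B > 0) eta <- eta + drop(Gd[, seq_len(B), drop = FALSE] %*% config$beta)
  if (config$phi != 0) eta <- eta + config$phi * Gd[, 1L] * Gd[, 2L]
  latent <- eta + stats::rlogis(n)
  cuts <- stats::quantile(latent, probs = D, names = FALSE)
  y <- as.integer(cut(latent, c(-Inf, cuts, Inf), labels = FALSE, right = TRUE)) - 1L
  list(y = y, latent = latent, cutpoints = cuts)
}

#' Simulate one complete dataset for a scenario replicate
#'
#' Seeds the RNG with [rep_seed()] of the config's master seed and the
#' replicate index, then draws genotypes, covariates and the phenotype.
#'
#' @param config a [sim_config()].
#' @param rep replicate index (default 1).
#' @return list with `genotypes` (`genotype_matrix`), `X`, `y`, `latent`,
#'   `seed` (the replicate seed used) and the `config`.
#' @export
sim_dataset <- function(config, rep = 1L) {
  s <- rep_seed(config$seed, rep)
  set.seed(s)
  G <- gen_genotypes(config$n, config$M, config$rho, config$maf)
  X <- gen_covariates(config$n)
  ph <- gen_ordinal_phenotype(G, X, config)
  list(genotypes = G, X = X, y = ph$y, latent = ph$latent, seed = s,
       config = config)
}

#' Null-simulation scenario configuration
#'
#' Convenience constructor for the type I error scenarios: `J = 3` uses
#' `n = 2000`, `D = (0.16, 0.84)`; `J = 5` uses `n = 3000`,
#' `D = (0.2, 0.4, 0.6, 0.8)`; MAFs equally spaced in `[0.1, 0.45]`,
#' covariate effects `gamma = (0.5, 0.8)`, no SNP effects.
#'
#' @param J categories (3 or 5); `M` SNPs; `rho` AR(1) correlation;
#'   `seed` master seed.
#' @param M,rho,seed see above.
#' @return a [sim_config()].
#' @export
null_scenario_config <- function(J, M, rho, seed = 1L) {
  n <- if (J == 3) 2000L else if (J == 5) 3000L else
    stop("null scenarios are defined for J = 3 or 5")
  D <- if (J == 3) c(0.16, 0.84) else c(0.2, 0.4, 0.6, 0.8)
  sim_config(n = n, M = M, J = J, rho = rho, maf = maf_grid(M),
             gamma = c(0.5, 0.8), beta = numeric(0), phi = 0, D = D,
             seed = seed)
}
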