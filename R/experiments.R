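## Simulation harness: type I error, power (with comparators), and Q-Q data.

.experiment_result <- function(config, method, pvalues, alpha, n_failed = 0L) {
  rate <- mean(pvalues <= alpha)
  structure(list(config = config, method = method, reps = length(pvalues),
                 pvalues = pvalues, rejection_rate = rate, alpha = alpha,
                 mc_se = sqrt(rate * (1 - rate) / length(pvalues)),
                 n_failed = n_failed),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("%s: %d reps, rejection rate %.4f (MC SE %.4f) at alpha=%g\n",
              x$method, x$reps, x$rejection_rate, x$mc_se, x$alpha))
  invisible(x)
}

#' Empirical type I error of POM-SKAT for one null scenario
#'
#' Runs `reps` independent replicates of the null simulation (fresh
#' genotypes, covariates and phenotype per replicate, each on its own seed
#' stream) and records the POM-SKAT p-value; reports the rejection rate at
#' `alpha`.  Replicates whose null fit fails are redrawn (counted in
#' `n_failed`).
#'
#' @param config a [sim_config()] with `beta` empty.
#' @param reps replicate count (default 500).
#' @param alpha nominal level (default 0.05).
#' @return an `experiment_result` with the per-replicate p-values.
#' @export
type1_experiment <- function(config, reps = 500L, alpha = 0.05) {
  if (length(config$beta)) stop("type I error scenario requires beta to be empty")
  pvals <- numeric(reps)
  n_failed <- 0L
  r <- 0L
  draw <- 0L
  while (r < reps) {
    draw <- draw + 1L
    res <- tryCatch({
      d <- sim_dataset(config, rep = draw)
      pom_skat_test(d$y, d$X, d$genotypes)$p_value
    }, error = function(e) NA_real_)
    if (is.na(res)) { n_failed <- n_failed + 1L; next }
    r <- r + 1L
    pvals[r] <- res
  }
  .experiment_result(config, "POM-SKAT", pvals, alpha, n_failed)
}

#' Power comparison of POM-SKAT against PCA, Bonferroni and QT
#'
#' Simulates under the alternative encoded in `config` (its `beta`/`phi`) and
#' records each requested method's p-value per replicate.
#'
#' @param config a [sim_config()].
#' @param reps,alpha as in [type1_experiment()].
#' @param methods subset of `c("pomskat", "pca", "bc", "qt")`.
#' @return named list of `experiment_result`, one per method.
#' @export
power_experiment <- function(config, reps = 500L, alpha = 0.05,
                             methods = c("pomskat", "pca", "bc", "qt")) {
  methods <- match.arg(methods, several.ok = TRUE)
  pv <- matrix(NA_real_, reps, length(methods),
               dimnames = list(NULL, methods))
  n_failed <- 0L
  r <- 0L
  draw <- 0L
  while (r < reps) {
    draw <- draw + 1L
    row <- tryCatch({
      d <- sim_dataset(config, rep = draw)
      snp_p <- if ("bc" %in% methods) {
        suppressWarnings(single_snp_pvalues(d$y, d$X, d$genotypes))
      }
      vapply(methods, function(m) {
        switch(m,
               pomskat = pom_skat_test(d$y, d$X, d$genotypes)$p_value,
               pca = as.numeric(pca_lrt_test(d$y, d$X, d$genotypes)),
               bc = bonferroni_test(snp_p),
               qt = as.numeric(qt_test(d$y, d$X, d$genotypes)))
      }, numeric(1))
    }, error = function(e) NULL)
    if (is.null(row)) { n_failed <- n_failed + 1L; next }
    r <- r + 1L
    pv[r, ] <- row
  }
  labels <- c(pomskat = "POM-SKAT", pca = "PCA", bc = "BC", qt = "QT")
  out <- lapply(methods, function(m) {
    .experiment_result(config, labels[[m]], pv[, m], alpha, n_failed)
  })
  names(out) <- methods
  out
}

#' Q-Q data for null p-values on the -log10 scale
#'
#' Pairs the sorted observed p-values with uniform plotting positions
#' `i/(n+1)`, both -log10 transformed.
#'
#' @param pvalues p-values in `[0,1]`.
#' @return data frame with `theoretical` and `observed` columns, ascending in
#'   significance.
#' @export
qq_data <- function(pvalues) {
  if (!length(pvalues)) stop("no p-values supplied")
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0,1]")
  if (length(unique(pvalues)) == 1L) {
    warning("degenerate p-value vector (all values identical)")
  }
  n <- length(pvalues)
  data.frame(theoretical = -log10(seq_len(n) / (n + 1)),
             observed = -log10(sort(pvalues)))
}
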