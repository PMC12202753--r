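## Core cumulative-logit (proportional odds) likelihood machinery.
##
## Parameterization: logit P(y <= j | x) = zeta_j - eta,  eta = X %*% coef,
## with strictly ascending cutpoints zeta_0 < ... < zeta_{J-2}.  The primary
## optimizer is a damped Newton on the raw (zeta, coef) vector with the
## analytic gradient and Hessian (step halving keeps the cutpoints ordered:
## a disordered proposal makes a category probability nonpositive, which the
## likelihood penalizes hard).  A quasi-Newton fallback on the transformed
## (zeta_0, log-gaps, coef) scale handles the rare case where Newton stalls.

# map internal transformed parameter vector to (zeta, coef)
.pom_unpack <- function(theta, J, p) {
  zeta <- theta[1L]
  if (J > 2L) zeta <- zeta + c(0, cumsum(exp(theta[2:(J - 1L)])))
  coef <- if (p > 0L) theta[J:(J + p - 1L)] else numeric(0)
  list(zeta = zeta, coef = coef)
}

.pom_pack <- function(zeta, coef) {
  J <- length(zeta) + 1L
  c(zeta[1L], if (J > 2L) log(pmax(diff(zeta), 1e-10)), coef)
}

# log-likelihood, gradient and (optionally) Hessian at raw par = c(zeta, coef);
# gidx is the list of per-category subject index vectors (fixed across
# evaluations within one fit, so it is computed once by the caller)
.pom_core <- function(par, y, X, J, p, hessian = FALSE,
                      gidx = lapply(0:(J - 1L), function(j) which(y == j))) {
  zeta <- par[seq_len(J - 1L)]
  coef <- if (p > 0L) par[J:(J + p - 1L)] else numeric(0)
  eta <- if (p > 0L) drop(X %*% coef) else 0
  zpad <- c(-Inf, zeta, Inf)        # category j spans (zpad[j+1], zpad[j+2]]
  zu <- zpad[y + 2L] - eta
  zl <- zpad[y + 1L] - eta
  Fu <- stats::plogis(zu)
  Fl <- stats::plogis(zl)
  P <- pmax(Fu - Fl, 1e-300)
  ll <- sum(log(P))

  # dlogis(+-Inf) = 0: boundary categories drop out automatically
  fu <- stats::dlogis(zu)
  fl <- stats::dlogis(zl)
  r_up <- fu / P
  r_lo <- fl / P
  gsum <- function(v) vapply(gidx, function(ii) sum(v[ii]), 0)
  su <- gsum(r_up)
  sl <- gsum(r_lo)
  gz <- su[seq_len(J - 1L)] - sl[2:J]
  g <- c(gz, if (p > 0L) drop(crossprod(X, r_lo - r_up)))

  out <- list(loglik = ll, grad = g)
  if (hessian) {
    # second derivatives of log P in (zeta_upper, zeta_lower, eta)
    fpu <- fu * (1 - 2 * Fu)
    fpl <- fl * (1 - 2 * Fl)
    huu <- fpu / P - r_up^2
    hll <- -fpl / P - r_lo^2
    hul <- r_up * r_lo
    hue <- -fpu / P + r_up * (r_up - r_lo)
    hle <- fpl / P - r_lo * (r_up - r_lo)
    hee <- (fpu - fpl) / P - (r_up - r_lo)^2

    K1 <- J - 1L
    Hzz <- matrix(0, K1, K1)
    s_uu <- gsum(huu)
    s_ll <- gsum(hll)
    s_ul <- gsum(hul)
    for (j in 0:(J - 1L)) {
      if (j <= J - 2L) Hzz[j + 1L, j + 1L] <- Hzz[j + 1L, j + 1L] + s_uu[j + 1L]
      if (j >= 1L)     Hzz[j, j]           <- Hzz[j, j] + s_ll[j + 1L]
      if (j >= 1L && j <= J - 2L) {                # middle categories couple
        Hzz[j, j + 1L] <- Hzz[j, j + 1L] + s_ul[j + 1L]
        Hzz[j + 1L, j] <- Hzz[j + 1L, j] + s_ul[j + 1L]
      }
    }
    if (p > 0L) {
      gsumX <- function(v) t(vapply(gidx, function(ii)
        colSums(X[ii, , drop = FALSE] * v[ii]), numeric(p)))
      Su <- gsumX(hue)                            # J x p
      Sl <- gsumX(hle)
      Hzg <- matrix(0, K1, p)
      for (j in 0:(J - 1L)) {
        if (j <= J - 2L) Hzg[j + 1L, ] <- Hzg[j + 1L, ] + Su[j + 1L, ]
        if (j >= 1L)     Hzg[j, ]      <- Hzg[j, ] + Sl[j + 1L, ]
      }
      Hgg <- crossprod(X, X * hee)
      out$hessian <- rbind(cbind(Hzz, Hzg), cbind(t(Hzg), Hgg))
    } else {
      out$hessian <- Hzz
    }
  }
  out
}

.pom_start <- function(y, J, p) {
  prop <- tabulate(y + 1L, nbins = J) / length(y)
  zeta <- stats::qlogis(pmin(pmax(cumsum(prop)[seq_len(J - 1L)], 1e-6), 1 - 1e-6))
  zeta <- zeta + cumsum(c(0, pmax(0, 1e-6 - diff(zeta))))  # enforce ascent
  c(zeta, rep(0, p))
}

# damped Newton; returns NULL if it fails to make progress
.pom_newton <- function(par, y, X, J, p, tol, max_iter, gidx) {
  core <- .pom_core(par, y, X, J, p, hessian = TRUE, gidx = gidx)
  for (it in seq_len(max_iter)) {
    if (max(abs(core$grad)) <= tol) break
    step <- tryCatch(solve(core$hessian, core$grad),
                     error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    repeat {
      cand <- par - lam * step                 # Hessian is negative definite
      ordered <- J == 2L || all(diff(cand[seq_len(J - 1L)]) > 0)
      if (ordered) {
        cc <- .pom_core(cand, y, X, J, p, hessian = TRUE, gidx = gidx)
        if (is.finite(cc$loglik) && cc$loglik >= core$loglik - 1e-10) {
          par <- cand
          core <- cc
          break
        }
      }
      lam <- lam / 2
      if (lam < 1e-8) return(NULL)
    }
  }
  list(par = par, core = core, iterations = it)
}

#' Fit a proportional odds model by maximum likelihood
#'
#' Maximizes the cumulative-logit multinomial likelihood
#' \eqn{logit P(y \le j) = \zeta_j - x^\top \gamma} over strictly ordered
#' cutpoints \eqn{\zeta} and regression coefficients.  A damped Newton
#' iteration with the analytic gradient and Hessian is tried first; if it
#' stalls, a quasi-Newton pass on \eqn{(\zeta_0, \log\Delta\zeta, \gamma)}
#' (which enforces the cutpoint ordering unconditionally) restarts it.
#' Convergence requires gradient max-norm below `tol`.
#'
#' @param y integer phenotype in `0:(J-1)`; every category must be observed.
#' @param X numeric design matrix (no intercept column), or `NULL`.
#' @param tol gradient max-norm convergence tolerance.
#' @param max_iter Newton iteration cap.
#' @param start optional warm start `c(zeta, coef)`.
#' @param se compute standard errors of the regression coefficients from the
#'   analytic observed information.
#' @return list with `zeta` (ascending cutpoints), `coef`, `loglik`, `grad`,
#'   `converged`, `theta` (= `c(zeta, coef)`), `J`, `n`, and if `se = TRUE`
#'   also `coef_se` and `vcov_coef`.
#' @export
pom_fit <- function(y, X = NULL, tol = 1e-8, max_iter = 100L,
                    start = NULL, se = FALSE) {
  y <- as.integer(y)
  J <- max(y) + 1L
  if (J < 2L) stop("phenotype must have at least 2 categories")
  if (min(y) < 0L) stop("phenotype must be coded 0..J-1")
  counts <- tabulate(y + 1L, nbins = J)
  if (any(counts == 0L)) {
    stop("phenotype category level(s) not observed: ",
         paste(which(counts == 0L) - 1L, collapse = ", "))
  }
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (ncol(X) == 0L) X <- NULL
  }
  p <- if (is.null(X)) 0L else ncol(X)
  if (p > 0L) {
    if (nrow(X) != length(y)) stop("X and y have different lengths")
    if (qr(cbind(1, X))$rank < p + 1L) {
      stop("design matrix is rank deficient (after adding an intercept)")
    }
  }

  gidx <- lapply(0:(J - 1L), function(j) which(y == j))
  par <- if (is.null(start)) .pom_start(y, J, p) else start
  res <- .pom_newton(par, y, X, J, p, tol, max_iter, gidx)
  if (is.null(res) || max(abs(res$core$grad)) > tol) {
    res <- .pom_fallback(if (is.null(res)) par else res$par, y, X, J, p, tol, gidx)
  }
  par <- res$par
  core <- res$core
  converged <- max(abs(core$grad)) <= tol
  if (!converged && max(abs(core$grad)) > 1e-3) {
    stop(sprintf(
      "proportional odds fit did not converge (gradient max-norm %.3g after %d iterations)",
      max(abs(core$grad)), res$iterations))
  }

  out <- list(zeta = unname(par[seq_len(J - 1L)]),
              coef = if (p > 0L) unname(par[J:(J + p - 1L)]) else numeric(0),
              loglik = core$loglik, grad = core$grad, converged = converged,
              theta = par, J = J, n = length(y))
  if (se && p > 0L) {
    H <- if (!is.null(core$hessian)) core$hessian
         else .pom_core(par, y, X, J, p, hessian = TRUE, gidx = gidx)$hessian
    V <- tryCatch(solve(-H), error = function(e)
      matrix(NA_real_, length(par), length(par)))
    idx <- J:(J + p - 1L)
    out$vcov_coef <- unname(V[idx, idx, drop = FALSE])
    out$coef_se <- unname(sqrt(pmax(diag(out$vcov_coef), 0)))
  }
  out
}

# quasi-Newton on the transformed scale, then one Newton polish pass
.pom_fallback <- function(par, y, X, J, p, tol, gidx) {
  theta <- .pom_pack(par[seq_len(J - 1L)],
                     if (p > 0L) par[J:(J + p - 1L)] else numeric(0))
  cache <- new.env(parent = emptyenv())
  core_at <- function(th) {
    if (!is.null(cache$th) && identical(th, cache$th)) return(cache$core)
    up <- .pom_unpack(th, J, p)
    core <- .pom_core(c(up$zeta, up$coef), y, X, J, p, gidx = gidx)
    cache$th <- th
    cache$core <- core
    core
  }
  grad_at <- function(th) {
    gz <- core_at(th)$grad[seq_len(J - 1L)]
    g <- numeric(length(th))
    csum <- rev(cumsum(rev(gz)))
    g[1L] <- csum[1L]
    if (J > 2L) g[2:(J - 1L)] <- exp(th[2:(J - 1L)]) * csum[-1L]
    if (p > 0L) g[J:(J + p - 1L)] <- core_at(th)$grad[J:(J + p - 1L)]
    -g
  }
  opt <- stats::nlminb(theta, function(th) -core_at(th)$loglik, grad_at,
                       control = list(iter.max = 300L, rel.tol = 1e-13))
  up <- .pom_unpack(opt$par, J, p)
  par <- c(up$zeta, up$coef)
  res <- .pom_newton(par, y, X, J, p, tol, 20L, gidx)
  if (is.null(res)) {
    res <- list(par = par,
                core = .pom_core(par, y, X, J, p, hessian = TRUE, gidx = gidx),
                iterations = opt$iterations)
  }
  res
}
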