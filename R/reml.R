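## Kernel mixed-model machinery shared by snp_heritability(), gblup(),
## multikernel_gblup() and mlma_loco().

#' Single-kernel REML by eigendecomposition
#'
#' Fits \eqn{y = X\beta + g + e} with \eqn{g \sim N(0, \sigma^2_g K)} and
#' \eqn{e \sim N(0, \sigma^2_e I)} by profiling the restricted likelihood
#' over the variance ratio \eqn{\delta = \sigma^2_e / \sigma^2_g} on the
#' eigenbasis of \code{K} (the EMMA device), so each candidate ratio costs
#' O(n) after a single O(n^3) decomposition.
#'
#' @param y numeric response vector (no NAs).
#' @param K symmetric positive semi-definite kernel matrix, \code{n x n}.
#'   Negative eigenvalues beyond numerical noise are clipped to zero with a
#'   warning (bending).
#' @param X fixed-effects design matrix; defaults to an intercept.
#' @param interval search interval for \code{log(delta)}.
#' @return list with \code{varcomps} (named \code{c(g, e)}), \code{h2},
#'   \code{beta}, \code{loglik} (restricted), \code{blup} (kernel effects for
#'   the fitted individuals), and the rotated quantities needed by callers
#'   (\code{U}, \code{eigenvalues}, \code{delta}, \code{Py}).
#' @export
emma_reml <- function(y, K, X = NULL, interval = c(-12, 12)) {
  n <- length(y)
  stopifnot(is.matrix(K), nrow(K) == n, ncol(K) == n)
  if (anyNA(y) || anyNA(K)) stop("emma_reml: NA in y or K")
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  p <- ncol(X)

  eig <- eigen(K, symmetric = TRUE)
  if (min(eig$values) < -1e-6 * max(abs(eig$values))) {
    warning("kernel not PSD; clipping negative eigenvalues (bending)")
  }
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)

  restricted_ll <- function(logdelta) {
    delta <- exp(logdelta)
    w <- 1 / (d + delta)
    XtWX <- crossprod(Xs, w * Xs)
    XtWy <- crossprod(Xs, w * ys)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
    r <- ys - Xs %*% beta
    ss <- sum(w * r^2)
    s2 <- ss / (n - p)
    -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + sum(log(d + delta)) +
              2 * sum(log(diag(ch))))
  }

  ## coarse grid then local refinement: the profile can be multimodal at the
  ## boundaries, and optimize() alone can miss the interior optimum
  grid <- seq(interval[1], interval[2], length.out = 25)
  ll_grid <- vapply(grid, restricted_ll, numeric(1))
  i0 <- which.max(ll_grid)
  lo <- grid[max(1, i0 - 1)]
  hi <- grid[min(length(grid), i0 + 1)]
  opt <- stats::optimize(restricted_ll, lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-8)
  logdelta <- if (opt$objective >= ll_grid[i0]) opt$maximum else grid[i0]
  delta <- exp(logdelta)

  w <- 1 / (d + delta)
  XtWX <- crossprod(Xs, w * Xs)
  beta <- solve(XtWX, crossprod(Xs, w * ys))
  r <- ys - Xs %*% beta
  s2g <- sum(w * r^2) / (n - p)
  s2e <- delta * s2g
  ## V^{-1}(y - X beta) on the original scale, for BLUP/prediction
  Py <- U %*% (w * r) / s2g
  blup <- as.numeric(s2g * K %*% Py)
  names(blup) <- rownames(K)

  list(varcomps = c(g = s2g, e = s2e), h2 = s2g / (s2g + s2e),
       beta = as.numeric(beta), loglik = restricted_ll(logdelta),
       blup = blup, U = U, eigenvalues = d, delta = delta, Py = Py, X = X)
}

#' Multi-kernel REML by average information with EM safeguards
#'
#' Fits \eqn{y = X\beta + \sum_k g_k + e}, one variance component per kernel
#' plus a residual, by AI-REML updates; any step that would leave the
#' parameter space or decrease the restricted likelihood falls back to the
#' (monotone) EM-REML update. This is the engine behind multi-kernel GBLUP
#' and multi-kernel RKHS, where REML weights the kernels.
#'
#' @param y numeric response.
#' @param kernels named list of \code{n x n} PSD matrices.
#' @param X fixed-effects design; default intercept.
#' @param maxit,tol iteration cap and convergence tolerance on the change in
#'   restricted log-likelihood.
#' @return list with \code{varcomps} (one per kernel plus \code{e}),
#'   \code{weights} (variance shares among kernels), \code{beta},
#'   \code{loglik}, per-kernel BLUPs (\code{blups}, an n x K matrix), and
#'   \code{Py} for out-of-sample prediction.
#' @export
aireml_multi <- function(y, kernels, X = NULL, maxit = 200, tol = 1e-6) {
  n <- length(y)
  stopifnot(is.list(kernels), length(kernels) >= 1)
  if (is.null(names(kernels)) || any(!nzchar(names(kernels))))
    names(kernels) <- paste0("K", seq_along(kernels))
  for (K in kernels) stopifnot(is.matrix(K), nrow(K) == n, ncol(K) == n)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  p <- ncol(X)
  m <- length(kernels)
  vy <- stats::var(y)
  if (vy == 0) {
    s2 <- stats::setNames(rep(0, m + 1), c(names(kernels), "e"))
    return(list(varcomps = s2, weights = rep(NA_real_, m), beta = mean(y),
                loglik = NA_real_, blups = matrix(0, n, m), Py = rep(0, n)))
  }
  floor_v <- 1e-8 * vy
  ## degenerate (all-zero) kernels are unidentifiable: fix their variance
  ## at zero and estimate the rest; with one active kernel left the fit
  ## collapses exactly to the single-kernel eigen-profile path
  active <- vapply(kernels, function(K) sum(abs(K)) > 0, logical(1))
  if (sum(active) == 0) stop("all kernels are zero matrices")
  if (sum(active) == 1) {
    k1 <- which(active)
    f <- emma_reml(y, kernels[[k1]], X = X)
    s2 <- stats::setNames(rep(0, m + 1), c(names(kernels), "e"))
    s2[k1] <- f$varcomps["g"]; s2[m + 1] <- f$varcomps["e"]
    blups <- matrix(0, n, m, dimnames = list(rownames(kernels[[1]]),
                                             names(kernels)))
    blups[, k1] <- f$blup
    w <- rep(0, m); w[k1] <- 1
    return(list(varcomps = s2, weights = w, beta = f$beta,
                loglik = f$loglik, blups = blups, Py = as.numeric(f$Py),
                iterations = 0L))
  }
  if (any(!active)) {
    sub <- aireml_multi(y, kernels[active], X = X, maxit = maxit, tol = tol)
    s2 <- stats::setNames(rep(0, m + 1), c(names(kernels), "e"))
    s2[names(kernels)[active]] <- sub$varcomps[seq_len(sum(active))]
    s2["e"] <- sub$varcomps[["e"]]
    blups <- matrix(0, n, m, dimnames = list(rownames(kernels[[1]]),
                                             names(kernels)))
    blups[, active] <- sub$blups
    w <- rep(0, m); w[active] <- sub$weights
    return(list(varcomps = s2, weights = w, beta = sub$beta,
                loglik = sub$loglik, blups = blups, Py = sub$Py,
                iterations = sub$iterations))
  }
  s2 <- rep(vy / (m + 1), m + 1)  # kernels then residual

  eval_fit <- function(s2) {
    V <- diag(s2[m + 1], n)
    for (k in seq_len(m)) V <- V + s2[k] * kernels[[k]]
    ch <- chol(V)
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    chx <- chol(XtViX)
    beta <- backsolve(chx, forwardsolve(t(chx), crossprod(ViX, y)))
    P <- Vi - ViX %*% backsolve(chx, forwardsolve(t(chx), t(ViX)))
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                    sum(y * Py))
    list(P = P, Py = Py, beta = beta, loglik = ll)
  }

  fit <- eval_fit(s2)
  for (it in seq_len(maxit)) {
    P <- fit$P; Py <- fit$Py
    KPy <- vector("list", m + 1)
    trPK <- numeric(m + 1)
    for (k in seq_len(m)) {
      KPy[[k]] <- kernels[[k]] %*% Py
      trPK[k] <- sum(P * kernels[[k]])
    }
    KPy[[m + 1]] <- Py
    trPK[m + 1] <- sum(diag(P))
    score <- vapply(seq_len(m + 1), function(k)
      -0.5 * (trPK[k] - sum(Py * KPy[[k]])), numeric(1))
    AI <- matrix(0, m + 1, m + 1)
    PKPy <- lapply(KPy, function(v) P %*% v)
    for (k in seq_len(m + 1)) for (l in k:(m + 1)) {
      AI[k, l] <- AI[l, k] <- 0.5 * sum(KPy[[k]] * PKPy[[l]])
    }
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(step)) {
      ## dampened AI step, reject if it leaves the cone or drops the ll
      for (damp in c(1, 0.5, 0.1)) {
        cand <- s2 + damp * step
        if (any(!is.finite(cand)) || any(cand < -floor_v)) next
        cand <- pmax(cand, floor_v)
        f2 <- tryCatch(eval_fit(cand), error = function(e) NULL)
        if (!is.null(f2) && is.finite(f2$loglik) &&
            f2$loglik >= fit$loglik - 1e-10) {
          accepted <- TRUE; s2_new <- cand; fit_new <- f2; break
        }
      }
    }
    if (!accepted) {
      ## EM-REML update (Harville): monotone but slow
      cand <- vapply(seq_len(m + 1), function(k)
        s2[k] + s2[k]^2 * (sum(Py * KPy[[k]]) - trPK[k]) / n, numeric(1))
      cand <- pmax(cand, floor_v)
      f2 <- eval_fit(cand)
      s2_new <- cand; fit_new <- f2
    }
    dll <- abs(fit_new$loglik - fit$loglik)
    s2 <- s2_new; fit <- fit_new
    if (dll < tol * (1 + abs(fit$loglik))) break
  }
  if (it == maxit && dll >= 1000 * tol * (1 + abs(fit$loglik)))
    warning("aireml_multi: not fully converged after ", maxit, " iterations")

  blups <- matrix(0, n, m, dimnames = list(rownames(kernels[[1]]),
                                           names(kernels)))
  for (k in seq_len(m)) blups[, k] <- s2[k] * (kernels[[k]] %*% fit$Py)
  varcomps <- stats::setNames(s2, c(names(kernels), "e"))
  list(varcomps = varcomps,
       weights = s2[seq_len(m)] / sum(s2[seq_len(m)]),
       beta = as.numeric(fit$beta), loglik = fit$loglik,
       blups = blups, Py = as.numeric(fit$Py), iterations = it)
}
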