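# Relaxed LASSO: stage-1 LASSO selects a support at penalty lambda,
# stage-2 refits the LASSO restricted to that support at the weaker
# penalty phi * lambda (phi = 0 is the unpenalized least-squares refit).
# (lambda, phi) are tuned jointly by K-fold CV.  Linear family only.

# Stage-2 coefficients of the restricted LASSO at each penalty in
# `lambdas` (decreasing).  Returns a matrix with one row per penalty,
# columns (intercept, coefs).  Exact OLS is used for a zero penalty.
relaxed_stage2 <- function(Xs, y, lambdas, thresh = 1e-9) {
  k <- ncol(Xs)
  out <- matrix(0, length(lambdas), k + 1L)
  ols <- NULL
  if (any(lambdas == 0)) {
    fit <- stats::lm.fit(cbind(1, Xs), y)
    ols <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  }
  pos <- lambdas > 0
  if (any(pos)) {
    if (k >= 2L) {
      want <- lambdas[pos]
      path <- sort(unique(c(max(want) * c(8, 4, 2), want)),
                   decreasing = TRUE)
      gf <- glmnet::glmnet(Xs, y, family = "gaussian", lambda = path,
                           standardize = FALSE, thresh = thresh)
      cols <- match(want, gf$lambda)
      co <- rbind(gf$a0[cols], as.matrix(gf$beta)[, cols, drop = FALSE])
      out[pos, ] <- t(co)
    } else {
      xb <- mean(Xs[, 1L]); yb <- mean(y)
      xc <- Xs[, 1L] - xb; yc <- y - yb
      n <- length(y)
      z <- sum(xc * yc) / n; v <- sum(xc * xc) / n
      b <- vapply(lambdas[pos], function(l)
        sign(z) * max(abs(z) - l, 0) / v, 0)
      out[pos, 2L] <- b
      out[pos, 1L] <- yb - b * xb
    }
  }
  if (!is.null(ols)) out[lambdas == 0, ] <- rep(ols, each = sum(lambdas == 0))
  out
}

#' Relaxed LASSO with cross-validated penalty and relaxation
#'
#' Two-stage estimator: the LASSO at penalty `lambda` fixes the support,
#' then the LASSO restricted to that support is solved at penalty
#' `phi * lambda`, `phi` in `[0, 1]`.  `phi = 1` recovers the ordinary
#' LASSO; `phi = 0` is the unpenalized refit on the selected support.
#' `(lambda, phi)` are chosen jointly by K-fold cross-validated squared
#' error on shared folds.
#'
#' @param X predictor matrix.
#' @param y continuous outcome.
#' @param grid a [tuning_grid()]; `grid$phi` is the relaxation grid.
#' @return a [penalized_fit()] with `tuning$lambda` and `tuning$phi`.
#' @export
fit_relaxed_lasso <- function(X, y, grid = tuning_grid()) {
  n <- nrow(X); p <- ncol(X)
  foldid <- grid_folds(grid, n)
  lam <- lambda_grid(X, y, grid$nlambda, grid$lambda_min_ratio)
  phis <- sort(unique(grid$phi), decreasing = TRUE)
  K <- grid$cv_folds
  err <- array(0, dim = c(length(lam), length(phis)))
  for (f in seq_len(K)) {
    tr <- foldid != f
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    Xva <- X[!tr, , drop = FALSE]; yva <- y[!tr]
    path <- glmnet::glmnet(Xtr, ytr, family = "gaussian", lambda = lam,
                           standardize = FALSE, thresh = 1e-9)
    B <- as.matrix(path$beta)
    # the solver can drop path points it fails to converge on; map each
    # requested penalty to the nearest computed column
    cols <- vapply(lam, function(l) which.min(abs(path$lambda - l)), 0L)
    for (i in seq_along(lam)) {
      S <- which(abs(B[, cols[i]]) > grid$zero_tol)
      if (!length(S)) {
        err[i, ] <- err[i, ] + mean((yva - mean(ytr))^2)
        next
      }
      co <- relaxed_stage2(Xtr[, S, drop = FALSE], ytr, phis * lam[i],
                           thresh = 1e-7)
      pred <- cbind(1, Xva[, S, drop = FALSE]) %*% t(co)
      err[i, ] <- err[i, ] + colMeans((yva - pred)^2)
    }
  }
  pick <- arrayInd(which.min(err), dim(err))
  lambda <- lam[pick[1L]]; phi <- phis[pick[2L]]
  full <- glmnet::glmnet(X, y, family = "gaussian", lambda = lam,
                         standardize = FALSE, thresh = 1e-9)
  b1 <- as.numeric(full$beta[, which.min(abs(full$lambda - lambda))])
  S <- which(abs(b1) > grid$zero_tol)
  beta <- numeric(p)
  empty <- !length(S)
  if (empty) {
    b0 <- mean(y)
  } else {
    co <- relaxed_stage2(X[, S, drop = FALSE], y, c(phi * lambda, 0))[1L, ]
    b0 <- co[1L]
    beta[S] <- co[-1L]
  }
  penalized_fit("relaxo", "linear", b0, beta,
                tuning = list(lambda = lambda, phi = phi),
                zero_tol = grid$zero_tol,
                diagnostics = list(empty_stage1 = empty))
}
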