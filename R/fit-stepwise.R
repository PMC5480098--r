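# Forward stepwise selection over ridge-penalized logistic regressions
# ("adaptive logistic regression").  At each step every remaining
# predictor is tried inside an L2-penalized logistic model; the best
# addition is accepted only if it lowers a BIC-type score
# (deviance + log(n) * df).  The ridge level is chosen by K-fold CV over
# a small grid, re-running the selection at each candidate level.

# Ridge-penalized logistic regression by Newton/IRLS.  X holds the
# slopes; the intercept is unpenalized.  Warm starts keep the stepwise
# search cheap.
ridge_logistic <- function(X, y, lambda, start = NULL, maxit = 50L,
                           tol = 1e-8) {
  n <- length(y)
  X1 <- cbind(1, X)
  k <- ncol(X1)
  pen <- c(0, rep(lambda, k - 1L))
  b <- if (is.null(start)) numeric(k) else start
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% b)
    p <- logistic(eta)
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    g <- drop(crossprod(X1, y - p)) - pen * b
    W <- p * (1 - p)
    H <- crossprod(X1 * W, X1)
    diag(H) <- diag(H) + pen
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    # damped Newton: halve until the penalized deviance does not increase
    dev_pen <- function(bb) {
      pp <- pmin(pmax(logistic(drop(X1 %*% bb)), 1e-10), 1 - 1e-10)
      -2 * sum(y * log(pp) + (1 - y) * log(1 - pp)) + sum(pen * bb^2)
    }
    d0 <- dev_pen(b)
    s <- 1
    repeat {
      bnew <- b + s * step
      if (dev_pen(bnew) <= d0 + 1e-10 || s < 1e-4) break
      s <- s / 2
    }
    b <- bnew
    dev <- dev_pen(b)
    if (abs(dev_old - dev) < tol * (abs(dev) + 1)) { converged <- TRUE; break }
    dev_old <- dev
  }
  p <- pmin(pmax(logistic(drop(X1 %*% b)), 1e-10), 1 - 1e-10)
  dev <- -2 * sum(y * log(p) + (1 - y) * log(1 - p))
  list(coef = b, deviance = dev, converged = converged)
}

# forward stepwise at a fixed ridge level; returns selected indices,
# final ridge fit and the trace of accepted scores
stepwise_once <- function(X, y, lambda, max_terms = NULL) {
  n <- length(y)
  p <- ncol(X)
  if (is.null(max_terms)) max_terms <- min(p, n - 2L)
  S <- integer(0)
  cur <- ridge_logistic(X[, S, drop = FALSE], y, lambda)
  score <- cur$deviance + log(n) * (1 + length(S))
  trace <- score
  while (length(S) < max_terms) {
    cand <- setdiff(seq_len(p), S)
    if (!length(cand)) break
    # rank candidates by the Rao score statistic at the current fit (one
    # vectorized pass), then refit the winner to convergence so the
    # accept/stop decision uses the exact penalized deviance
    X1 <- cbind(1, X[, S, drop = FALSE])
    eta <- drop(X1 %*% cur$coef)
    pr <- pmin(pmax(logistic(eta), 1e-10), 1 - 1e-10)
    W <- pr * (1 - pr)
    r <- y - pr
    Xc <- X[, cand, drop = FALSE]
    H <- crossprod(X1 * W, X1)
    diag(H) <- diag(H) + c(0, rep(lambda, length(S)))
    M <- crossprod(X1 * W, Xc)
    HM <- solve(H, M)
    u <- drop(crossprod(Xc, r))
    denom <- colSums(Xc * (W * Xc)) + lambda - colSums(M * HM)
    stat <- u^2 / pmax(denom, 1e-12)
    j <- cand[which.max(stat)]
    fit <- ridge_logistic(X[, c(S, j), drop = FALSE], y, lambda,
                          start = c(cur$coef, 0))
    new_score <- fit$deviance + log(n) * (2 + length(S))
    if (new_score < score - 1e-8) {
      S <- c(S, j)
      cur <- fit
      score <- new_score
      trace <- c(trace, score)
    } else break
  }
  list(support = S, fit = cur, score = score, trace = trace)
}

#' Forward stepwise ridge logistic regression
#'
#' Builds a logistic model by forward selection over L2-penalized
#' logistic fits.  At each step candidates are ranked by the Rao score
#' statistic at the current fit; the best candidate is refit to
#' convergence and accepted only if it lowers the BIC-type score
#' `deviance + log(n) * df`.  Selection stops when no addition lowers
#' the score.  The ridge level is chosen from `grid$ridge_lambda` by
#' K-fold cross-validated deviance of the selected model.
#'
#' @param X predictor matrix.
#' @param y binary outcome.
#' @param grid a [tuning_grid()]; `grid$ridge_lambda` is the ridge grid.
#' @param max_terms optional cap on the number of selected predictors.
#' @return a [penalized_fit()]; `diagnostics$score_trace` holds the
#'   monotone sequence of accepted scores.
#' @export
fit_stepwise_ridge_logistic <- function(X, y, grid = tuning_grid(),
                                        max_terms = NULL) {
  n <- length(y)
  foldid <- grid_folds(grid, n)
  best <- NULL
  for (lambda in grid$ridge_lambda) {
    sel <- stepwise_once(X, y, lambda, max_terms)
    cv <- 0
    for (f in seq_len(grid$cv_folds)) {
      tr <- foldid != f
      fit <- ridge_logistic(X[tr, sel$support, drop = FALSE], y[tr], lambda)
      eta <- drop(cbind(1, X[!tr, sel$support, drop = FALSE]) %*% fit$coef)
      cv <- cv + binomial_deviance(y[!tr], logistic(eta))
    }
    if (is.null(best) || cv < best$cv)
      best <- list(cv = cv, lambda = lambda, sel = sel)
  }
  sel <- best$sel
  beta <- numeric(ncol(X))
  beta[sel$support] <- sel$fit$coef[-1L]
  penalized_fit("stepplr", "logistic", sel$fit$coef[1L], beta,
                tuning = list(ridge_lambda = best$lambda),
                zero_tol = grid$zero_tol,
                diagnostics = list(score_trace = sel$trace,
                                   entry_order = sel$support,
                                   converged = sel$fit$converged))
}
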