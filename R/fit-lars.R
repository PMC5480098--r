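# Least angle regression, implemented from the equiangular-direction
# recursion.  Pure LAR: variables enter the active set and never leave
# (no LASSO modification).  Linear family only.

# Full LAR path on centered data.  Returns the coefficient matrix at the
# path breakpoints (rows = steps 0..K) plus the entry order.
lar_path <- function(X, y, max_steps = NULL) {
  n <- nrow(X); p <- ncol(X)
  xbar <- colMeans(X); ybar <- mean(y)
  Xc <- sweep(X, 2L, xbar)
  yc <- y - ybar
  K <- min(p, n - 1L)
  if (!is.null(max_steps)) K <- min(K, max_steps)
  beta <- numeric(p)
  mu <- numeric(n)
  active <- integer(0)
  signs <- numeric(0)
  path <- matrix(0, nrow = K + 1L, ncol = p)
  truncated <- FALSE
  for (k in seq_len(K)) {
    cvec <- drop(crossprod(Xc, yc - mu))
    inactive <- setdiff(seq_len(p), active)
    if (!length(inactive)) break
    jstar <- inactive[which.max(abs(cvec[inactive]))]
    active <- c(active, jstar)
    signs <- c(signs, sign(cvec[jstar]))
    XA <- Xc[, active, drop = FALSE] *
      rep(signs, each = n)
    G <- crossprod(XA)
    w1 <- tryCatch(solve(G, rep(1, length(active))), error = function(e) NULL)
    if (is.null(w1) || any(!is.finite(w1)) || sum(w1) <= 0) {
      active <- active[-length(active)]
      signs <- signs[-length(signs)]
      truncated <- TRUE
      path <- path[seq_len(k), , drop = FALSE]
      break
    }
    AA <- 1 / sqrt(sum(w1))
    w <- AA * w1
    u <- drop(XA %*% w)
    Cmax <- max(abs(cvec[active]))
    rest <- setdiff(seq_len(p), active)
    if (length(rest)) {
      a <- drop(crossprod(Xc[, rest, drop = FALSE], u))
      cr <- cvec[rest]
      cand <- c((Cmax - cr) / (AA - a), (Cmax + cr) / (AA + a))
      cand <- cand[is.finite(cand) & cand > 1e-12]
      gamma <- if (length(cand)) min(cand, Cmax / AA) else Cmax / AA
    } else {
      gamma <- Cmax / AA
    }
    beta[active] <- beta[active] + gamma * signs * w
    mu <- mu + gamma * u
    path[k + 1L, ] <- beta
  }
  list(path = path, active = active, xbar = xbar, ybar = ybar,
       truncated = truncated, steps = nrow(path) - 1L)
}

#' Least angle regression with cross-validated stopping step
#'
#' Computes the LAR path (equiangular directions, no LASSO modification)
#' and selects the number of steps by K-fold cross-validated squared
#' error; the support is the active set at the chosen step.  The first
#' variable to enter is always the one most correlated with the outcome.
#'
#' @param X predictor matrix.
#' @param y continuous outcome.
#' @param grid a [tuning_grid()] (supplies folds and `zero_tol`).
#' @param max_steps optional cap on the number of path steps.
#' @return a [penalized_fit()] with `tuning$step` set.
#' @export
fit_lars <- function(X, y, grid = tuning_grid(), max_steps = NULL) {
  n <- nrow(X)
  foldid <- grid_folds(grid, n)
  K <- grid$cv_folds
  fold_paths <- lapply(seq_len(K), function(f) {
    lar_path(X[foldid != f, , drop = FALSE], y[foldid != f], max_steps)
  })
  nsteps <- min(vapply(fold_paths, function(z) z$steps, 0L))
  cv_err <- vapply(0:nsteps, function(s) {
    errs <- vapply(seq_len(K), function(f) {
      pp <- fold_paths[[f]]
      b <- pp$path[s + 1L, ]
      b0 <- pp$ybar - sum(pp$xbar * b)
      pred <- b0 + drop(X[foldid == f, , drop = FALSE] %*% b)
      mean((y[foldid == f] - pred)^2)
    }, 0)
    mean(errs)
  }, 0)
  step <- which.min(cv_err) - 1L
  full <- lar_path(X, y, max_steps)
  step <- min(step, full$steps)
  b <- full$path[step + 1L, ]
  b0 <- full$ybar - sum(full$xbar * b)
  penalized_fit("lars", "linear", b0, b,
                tuning = list(step = step),
                zero_tol = grid$zero_tol,
                diagnostics = list(truncated = full$truncated))
}
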