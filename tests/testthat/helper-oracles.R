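# Independent oracles used to verify the implementation.  Everything here
# deliberately takes a different computational route from the package
# (grid search, QR least squares, numeric differentiation, direct
# counting) so agreement is evidence, not tautology.

# Monte-Carlo tolerance for a binomial rate v estimated from R replicates
mc_tol <- function(v, R, widen = 0) {
  3 * sqrt(v * (1 - v) / R) + widen
}

# least squares via QR (the package uses Cholesky / lm.fit)
ols_oracle <- function(X1, y) {
  qr.solve(qr(X1), y)
}

# ridge closed form on centered data
ridge_oracle <- function(X, y, lambda_prime) {
  xb <- colMeans(X); yb <- mean(y)
  Xc <- sweep(X, 2, xb); yc <- y - yb
  b <- solve(crossprod(Xc) + diag(lambda_prime, ncol(X)), crossprod(Xc, yc))
  list(intercept = yb - sum(xb * b), beta = drop(b))
}

# objective of the elastic-net-penalized problem (gaussian / binomial),
# matching the scaling used by the fits: nll/n + lambda * penalty
penalized_objective <- function(X, y, family, b0, beta, lambda, alpha) {
  eta <- b0 + drop(X %*% beta)
  nll <- if (family == "linear") sum((y - eta)^2) / 2
         else -sum(y * eta - log1p(exp(eta)))
  nll / length(y) +
    lambda * (alpha * sum(abs(beta)) +
                (1 - alpha) / 2 * sum(beta^2))
}

# brute-force grid minimizer of the same objective over the slopes
# (intercept held at b0); returns the minimum objective value
grid_min_objective <- function(X, y, family, b0, center, lambda, alpha,
                               half_width = 0.5, m = 101) {
  g1 <- seq(center[1] - half_width, center[1] + half_width, length.out = m)
  g2 <- seq(center[2] - half_width, center[2] + half_width, length.out = m)
  best <- Inf
  for (b1 in g1) for (b2 in g2) {
    v <- penalized_objective(X, y, family, b0, c(b1, b2), lambda, alpha)
    if (v < best) best <- v
  }
  best
}

# scalar weighted-L1 grid minimizer for one coordinate of an orthonormal
# design: min_b  (b - z)^2 / 2 + w * |b|
scalar_l1_grid <- function(z, w, m = 40001, span = 3) {
  g <- seq(-span, span, length.out = m)
  g[which.min((g - z)^2 / 2 + w * abs(g))]
}

# numeric Hessian of the logistic negative log-likelihood at beta
logistic_hessian_oracle <- function(X1, beta, h = 1e-5) {
  gfun <- function(b) {
    p <- plogis(drop(X1 %*% b))
    -drop(crossprod(X1, numeric(nrow(X1)) - p))  # gradient of nll minus y-part
  }
  # full gradient of nll: -X'(y - p); the y part is linear so it drops out
  # of the Hessian -> differentiate -X'(-p) = X'p
  k <- length(beta)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    e <- numeric(k); e[j] <- h
    H[, j] <- (gfun(beta + e) - gfun(beta - e)) / (2 * h)
  }
  (H + t(H)) / 2
}

# plain undamped Newton-Raphson logistic MLE, independent of glm.fit
irls_oracle <- function(X1, y, maxit = 50, tol = 1e-12) {
  b <- numeric(ncol(X1))
  for (i in seq_len(maxit)) {
    p <- plogis(drop(X1 %*% b))
    W <- p * (1 - p)
    step <- solve(crossprod(X1 * W, X1), crossprod(X1, y - p))
    b <- b + drop(step)
    if (max(abs(step)) < tol) break
  }
  b
}

# direct two-variable LAR breakpoint computation (Efron et al. geometry),
# written without the package's loop structure
lar2_oracle <- function(X, y) {
  Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
  c0 <- drop(crossprod(Xc, yc))
  j1 <- which.max(abs(c0))
  s1 <- sign(c0[j1])
  x1 <- s1 * Xc[, j1]
  # one active variable: u = x1/||x1||, A = ||x1||... with G = x1'x1
  G <- sum(x1 * x1)
  A1 <- sqrt(G)          # (1' G^-1 1)^(-1/2) for scalar G
  u <- x1 / A1
  a <- drop(crossprod(Xc, u))
  Cmax <- abs(c0[j1])
  j2 <- setdiff(1:2, j1)
  cand <- c((Cmax - c0[j2]) / (A1 - a[j2]), (Cmax + c0[j2]) / (A1 + a[j2]))
  cand <- cand[is.finite(cand) & cand > 1e-12]
  gamma1 <- min(cand)
  beta_step1 <- numeric(2)
  beta_step1[j1] <- gamma1 * s1 / A1
  # step 2 reaches the full OLS solution
  beta_ols <- drop(qr.solve(qr(Xc), yc))
  list(order = c(j1, j2), beta_step1 = beta_step1, beta_final = beta_ols)
}

# independent recount of every metric from the long audit log, using
# data-frame aggregation rather than the package's outcome-list loops
recount_from_log <- function(log) {
  per_coef <- function(sub, f) mean(vapply(split(sub, sub$coefficient), f, 0))
  zeros <- log[log$beta_true == 0, ]
  sigs <- log[log$beta_true != 0, ]
  covz <- function(sub, alg) {
    lo <- sub[[paste0(alg, "_lower")]]; hi <- sub[[paste0(alg, "_upper")]]
    dg <- sub[[paste0(alg, "_degenerate")]]
    keep <- !sub$selected | (!dg & !is.na(lo))
    sub <- sub[keep, ]; lo <- lo[keep]; hi <- hi[keep]
    ok <- !sub$selected | (lo <= 0 & 0 <= hi)
    mean(vapply(split(ok, sub$coefficient), mean, 0))
  }
  covt <- function(sub, alg) {
    lo <- sub[[paste0(alg, "_lower")]]; hi <- sub[[paste0(alg, "_upper")]]
    dg <- sub[[paste0(alg, "_degenerate")]]
    keep <- sub$selected & !dg & !is.na(lo)
    sub <- sub[keep, ]; lo <- lo[keep]; hi <- hi[keep]
    ok <- lo <= sub$beta_true & sub$beta_true <= hi
    mean(vapply(split(ok, sub$coefficient), mean, 0))
  }
  list(
    fp = per_coef(zeros, function(s) mean(s$selected)),
    fn = per_coef(sigs, function(s) mean(!s$selected)),
    cz_null_adapt = covz(zeros, "adapt"),
    cz_null_oracle = covz(zeros, "oracle"),
    cz_sig_adapt = covz(sigs, "adapt"),
    cz_sig_oracle = covz(sigs, "oracle"),
    ct_adapt = covt(sigs, "adapt"),
    ct_oracle = covt(sigs, "oracle"))
}

# orthonormal-in-the-penalized-sense design: centered columns with
# X'X = n I (so the soft-threshold closed form applies exactly)
orthonormal_design <- function(n, p, seed = 1) {
  set.seed(seed)
  Z <- matrix(rnorm(n * p), n, p)
  Z <- sweep(Z, 2, colMeans(Z))
  Q <- qr.Q(qr(Z))
  sweep(Q, 2, sqrt(colSums(Q^2) / n), "/")
}
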