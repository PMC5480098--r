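# Internal numerical and seeding helpers shared across modules.

logistic <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

#' Deterministic per-replicate child seed
#'
#' Derives a 32-bit-safe child seed from a master seed and a replicate
#' index, so that any single replicate of a simulation cell can be
#' reproduced in isolation.
#'
#' @param master integer master seed of the cell.
#' @param r replicate index (1-based).  `r = 0` is reserved for cell-level
#'   draws.
#' @return an integer in `[0, 2^31)` usable with [set.seed()].
#' @export
child_seed <- function(master, r) {
  stopifnot(is.numeric(master), length(master) == 1L, is.numeric(r))
  # keep all intermediate products < 2^53 so double arithmetic is exact
  m <- as.double(master) %% 94906249
  as.integer((m * 1103515 + as.double(r) * 12820163 + 7) %% 2147483629)
}

# seed used for CV fold assignment inside replicate r; offset keeps it
# distinct from the data-generating stream
fold_seed <- function(master, r) {
  as.integer((as.double(child_seed(master, r)) + 1013904223) %% 2147483629)
}

#' Cross-validation fold assignment
#'
#' Fold labels depend only on `(n, k, seed)`, so every estimator fitted to
#' the same replicate sees identical folds.  The global RNG state is left
#' untouched.
#'
#' @param n number of observations.
#' @param k number of folds.
#' @param seed integer seed governing the random assignment.
#' @return integer vector of length `n` with values in `1..k`.
#' @export
make_folds <- function(n, k = 5L, seed = 1L) {
  stopifnot(n >= k, k >= 2)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

# Symmetric solve with a condition-number guard.  Returns NULL when the
# matrix is numerically singular (rcond below 1/tol); callers translate
# that into a degenerate flag.
safe_inverse <- function(A, tol = 1e12) {
  A <- (A + t(A)) / 2
  rc <- tryCatch(rcond(A), error = function(e) 0)
  if (!is.finite(rc) || rc < 1 / tol) return(NULL)
  inv <- tryCatch(chol2inv(chol(A)), error = function(e) NULL)
  if (is.null(inv)) inv <- tryCatch(solve(A), error = function(e) NULL)
  inv
}

# smallest eigenvalue of a symmetric matrix
min_eigen <- function(A) {
  min(eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

#' Geometric penalty grid
#'
#' Builds the default tuning-parameter path: `nlambda` geometrically spaced
#' values from the smallest penalty that zeroes every slope down to
#' `ratio` times that value.  The entry point of the path uses the null
#' model gradient `max_j |x_j'(y - mean(y))| / n`, which is exact for
#' squared-error loss and the standard choice for binomial deviance.
#'
#' @param X predictor matrix.
#' @param y outcome vector.
#' @param nlambda number of grid points.
#' @param ratio smallest penalty as a fraction of the largest.
#' @return decreasing numeric vector of length `nlambda`.
#' @export
lambda_grid <- function(X, y, nlambda = 50L, ratio = 1e-3) {
  r <- y - mean(y)
  lmax <- max(abs(crossprod(X, r))) / nrow(X)
  if (lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax * ratio), length.out = nlambda))
}
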