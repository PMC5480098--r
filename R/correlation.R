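# Predictor correlation structures for the multivariate-normal design.

#' Correlation structure specification
#'
#' Describes the correlation matrix of the multivariate-normal predictors.
#' Three structures are supported: `identity` (independent predictors),
#' `block` (disjoint consecutive blocks of size `block_size` with constant
#' off-diagonal correlation `rho`), and `ar` (autoregressive decay
#' `rho^|i-j|`, truncated to zero beyond `max_lag`).
#'
#' @param kind one of `"identity"`, `"block"`, `"ar"`.
#' @param p number of predictors.
#' @param rho correlation scalar in `[0, 1)`; ignored for `identity`.
#' @param block_size block dimension for the block structure.
#' @param max_lag truncation lag for the AR structure.
#' @return an object of class `correlation_spec`.
#' @examples
#' correlation_spec("block", p = 50)
#' @export
correlation_spec <- function(kind = c("identity", "block", "ar"), p,
                             rho = 0.5, block_size = 5L, max_lag = 10L) {
  kind <- match.arg(kind)
  stopifnot(p >= 1, rho >= 0, rho < 1, block_size >= 1, max_lag >= 1)
  structure(
    list(kind = kind, p = as.integer(p), rho = rho,
         block_size = as.integer(block_size), max_lag = as.integer(max_lag)),
    class = "correlation_spec")
}

#' @export
print.correlation_spec <- function(x, ...) {
  cat(sprintf("<correlation_spec> kind=%s p=%d rho=%g\n", x$kind, x$p, x$rho))
  invisible(x)
}

#' Build the correlation matrix of a specification
#'
#' Materializes the `p x p` correlation matrix and verifies numerically
#' that it is symmetric, unit-diagonal and positive definite.  The AR
#' structure is truncated at `max_lag`, which can in principle destroy
#' positive definiteness; by default this is an error, optionally repaired
#' by shifting the spectrum just above zero.
#'
#' @param spec a [correlation_spec()].
#' @param repair_pd if `TRUE`, a non-positive-definite truncated matrix is
#'   repaired by an eigenvalue floor instead of raising an error.
#' @return a `p x p` correlation matrix.
#' @export
build_correlation <- function(spec, repair_pd = FALSE) {
  stopifnot(inherits(spec, "correlation_spec"))
  p <- spec$p
  S <- switch(spec$kind,
    identity = diag(p),
    block = {
      S <- diag(p)
      b <- spec$block_size
      for (start in seq(1L, p, by = b)) {
        idx <- start:min(start + b - 1L, p)
        S[idx, idx] <- spec$rho
      }
      diag(S) <- 1
      S
    },
    ar = {
      d <- abs(outer(seq_len(p), seq_len(p), "-"))
      S <- spec$rho^d
      S[d > spec$max_lag] <- 0
      S
    })
  ev <- min_eigen(S)
  if (ev <= 0) {
    if (!repair_pd)
      stop("correlation matrix is not positive definite (min eigenvalue ",
           signif(ev, 3), "); set repair_pd = TRUE to shift the spectrum")
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    vals <- pmax(e$values, 1e-8)
    S <- e$vectors %*% (vals * t(e$vectors))
    D <- 1 / sqrt(diag(S))
    S <- S * tcrossprod(D)
  }
  S <- (S + t(S)) / 2
  dimnames(S) <- NULL
  S
}
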