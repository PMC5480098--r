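# The generating truth: sparse signed coefficient vectors and model family.

#' Signed sparse coefficient vector
#'
#' Builds the length-`p` truth used throughout the simulations: the first
#' `p_star` predictors carry the signal at a common magnitude, with the
#' first half positive and the second half negative; the remaining
#' `p - p_star` coefficients are exactly zero.
#'
#' @param p number of predictors.
#' @param p_star number of truly associated predictors (must be even).
#' @param magnitude common absolute effect size (> 0).
#' @return numeric vector of length `p`.
#' @examples
#' build_coefficients(p = 50, p_star = 10, magnitude = 0.5)
#' @export
build_coefficients <- function(p, p_star, magnitude) {
  stopifnot(p >= 1, p_star >= 0, p_star <= p, magnitude > 0)
  if (p_star %% 2L != 0L)
    stop("p_star must be even so that signs can be split half and half")
  beta <- numeric(p)
  if (p_star > 0) {
    half <- p_star / 2L
    beta[seq_len(half)] <- magnitude
    beta[(half + 1L):p_star] <- -magnitude
  }
  beta
}

#' Generating truth for one simulation design
#'
#' Bundles everything that defines the data-generating process: the model
#' family, the sparse signed coefficient vector, the intercept, the error
#' law (linear family) and the marginal law of the predictors.
#'
#' @param family `"linear"` or `"logistic"`.
#' @param p,p_star dimensions of the full and truly-associated predictor
#'   sets.
#' @param magnitude common absolute value of the nonzero coefficients.
#' @param beta0_star intercept of the generating model; defaults to 0 for
#'   the linear family and -1 for the logistic (case-control) family.
#' @param error_kind linear-family error law: `"normal"` (variance 1) or a
#'   Student t with 2 or 15 degrees of freedom, used unscaled.
#' @param predictor_kind `"mvnormal"` or iid `"binary"` with success
#'   probability 1/2.
#' @return an object of class `true_model`.
#' @export
true_model <- function(family = c("linear", "logistic"), p = 50L,
                       p_star = 10L, magnitude = 0.5, beta0_star = NULL,
                       error_kind = c("normal", "t2", "t15"),
                       predictor_kind = c("mvnormal", "binary")) {
  family <- match.arg(family)
  error_kind <- match.arg(error_kind)
  predictor_kind <- match.arg(predictor_kind)
  if (is.null(beta0_star))
    beta0_star <- if (family == "logistic") -1 else 0
  beta <- build_coefficients(p, p_star, magnitude)
  structure(
    list(family = family, p = as.integer(p), p_star = as.integer(p_star),
         magnitude = magnitude, beta0_star = beta0_star,
         beta_star = beta[seq_len(p_star)], beta_full = beta,
         support = seq_len(p_star), sigma2_star = 1,
         error_kind = error_kind, predictor_kind = predictor_kind),
    class = "true_model")
}

#' @export
print.true_model <- function(x, ...) {
  cat(sprintf(
    "<true_model> %s p=%d p*=%d |beta*|=%g intercept=%g errors=%s X=%s\n",
    x$family, x$p, x$p_star, x$magnitude, x$beta0_star, x$error_kind,
    x$predictor_kind))
  invisible(x)
}
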