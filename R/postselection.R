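# Post-selection inference: adaptive (plug-in) and oracle (refit)
# covariance estimates on the selected design, for linear and logistic
# models, with normal-approximation confidence intervals.

new_inference <- function(algorithm, family, support, estimates, covariance,
                          sigma2 = NA_real_, degenerate = FALSE,
                          reason = NA_character_) {
  p_adapt <- 1L + length(support)
  structure(
    list(algorithm = algorithm, family = family,
         support = as.integer(support), p_adapt = p_adapt,
         estimates = as.numeric(estimates), sigma2_hat = sigma2,
         covariance = covariance, degenerate = degenerate, reason = reason,
         level = NA_real_, lower = NULL, upper = NULL),
    class = "sel_inference")
}

#' @export
print.sel_inference <- function(x, ...) {
  cat(sprintf("<sel_inference> %s %s p_adapt=%d%s\n", x$algorithm, x$family,
              x$p_adapt, if (x$degenerate) paste0(" DEGENERATE (", x$reason, ")")
              else ""))
  invisible(x)
}

#' Selected design matrix
#'
#' Builds the design on which both inference algorithms operate: an
#' all-ones intercept column followed by the selected predictors in index
#' order.
#'
#' @param X full predictor matrix.
#' @param fit a [penalized_fit()] obtained from the same `X` (or an
#'   integer vector of selected indices).
#' @return a list with `XS` (`n x p_adapt` matrix), `support`, and
#'   `degenerate` (`TRUE` when `p_adapt >= n`, in which case no covariance
#'   with positive residual degrees of freedom exists).
#' @export
select_design <- function(X, fit) {
  support <- if (inherits(fit, "penalized_fit")) fit$support
             else sort(as.integer(fit))
  stopifnot(all(support >= 1), all(support <= ncol(X)))
  XS <- cbind(1, X[, support, drop = FALSE])
  colnames(XS) <- c("(Intercept)",
                    if (length(support)) paste0("x", support))
  list(XS = XS, support = support, degenerate = ncol(XS) >= nrow(XS))
}

# shared guard: NULL covariance -> degenerate result
finish_inference <- function(algorithm, family, support, estimates, XtX_inv,
                             scale = 1, sigma2 = NA_real_, degenerate = FALSE,
                             reason = NA_character_) {
  if (is.null(XtX_inv)) {
    degenerate <- TRUE
    if (is.na(reason)) reason <- "singular_design"
    cov <- NULL
  } else {
    cov <- scale * XtX_inv
    cov <- (cov + t(cov)) / 2
  }
  new_inference(algorithm, family, support, estimates, cov, sigma2,
                degenerate, reason)
}

#' Adaptive (plug-in) inference for linear models
#'
#' Algorithm 1 for the linear family: the penalized estimates themselves
#' define the residuals.  With `XS` the selected design (intercept first)
#' and `beta_adapt` the intercept plus nonzero penalized coefficients,
#' `sigma2_adapt = ||y - XS beta_adapt||^2 / (n - p_adapt)` and the
#' covariance is `sigma2_adapt * (XS' XS)^{-1}`.
#'
#' @param XS selected design from [select_design()] (matrix, intercept
#'   column first) or the list returned by `select_design()`.
#' @param y outcome vector.
#' @param beta_adapt numeric vector of length `ncol(XS)`: the penalized
#'   intercept followed by the selected penalized coefficients.
#' @return a `sel_inference` object (`algorithm = "adapt"`).
#' @export
adaptive_inference_linear <- function(XS, y, beta_adapt) {
  sel <- normalize_design(XS)
  n <- nrow(sel$XS); p_adapt <- ncol(sel$XS)
  stopifnot(length(beta_adapt) == p_adapt, length(y) == n)
  if (p_adapt >= n)
    return(new_inference("adapt", "linear", sel$support, beta_adapt, NULL,
                         degenerate = TRUE, reason = "p_adapt_ge_n"))
  res <- y - drop(sel$XS %*% beta_adapt)
  sigma2 <- sum(res^2) / (n - p_adapt)
  finish_inference("adapt", "linear", sel$support, beta_adapt,
                   safe_inverse(crossprod(sel$XS)), scale = sigma2,
                   sigma2 = sigma2)
}

#' Oracle (refit) inference for linear models
#'
#' Algorithm 2 for the linear family: ordinary least squares of `y` on
#' the selected design; `sigma2_oracle = RSS / (n - p_adapt)`; covariance
#' `sigma2_oracle * (XS' XS)^{-1}`.  The point estimates depend on the
#' selected support only, not on the stage-1 coefficient values.
#'
#' @inheritParams adaptive_inference_linear
#' @return a `sel_inference` object (`algorithm = "oracle"`).
#' @export
oracle_inference_linear <- function(XS, y) {
  sel <- normalize_design(XS)
  n <- nrow(sel$XS); p_adapt <- ncol(sel$XS)
  if (p_adapt >= n)
    return(new_inference("oracle", "linear", sel$support,
                         rep(NA_real_, p_adapt), NULL,
                         degenerate = TRUE, reason = "p_adapt_ge_n"))
  inv <- safe_inverse(crossprod(sel$XS))
  if (is.null(inv))
    return(new_inference("oracle", "linear", sel$support,
                         rep(NA_real_, p_adapt), NULL,
                         degenerate = TRUE, reason = "singular_design"))
  beta <- drop(inv %*% crossprod(sel$XS, y))
  res <- y - drop(sel$XS %*% beta)
  sigma2 <- sum(res^2) / (n - p_adapt)
  finish_inference("oracle", "linear", sel$support, beta, inv,
                   scale = sigma2, sigma2 = sigma2)
}

#' Adaptive (plug-in) inference for logistic models
#'
#' Algorithm 1 for the logistic family: fitted probabilities are computed
#' at the penalized estimates, `V = diag(p_i (1 - p_i))`, and the
#' covariance is `(XS' V XS)^{-1}`.  Probabilities are clipped at 1e-10
#' from both ends; clipping is flagged.
#'
#' @inheritParams adaptive_inference_linear
#' @return a `sel_inference` object.
#' @export
adaptive_inference_logistic <- function(XS, y, beta_adapt) {
  sel <- normalize_design(XS)
  n <- nrow(sel$XS); p_adapt <- ncol(sel$XS)
  stopifnot(length(beta_adapt) == p_adapt)
  if (p_adapt >= n)
    return(new_inference("adapt", "logistic", sel$support, beta_adapt, NULL,
                         degenerate = TRUE, reason = "p_adapt_ge_n"))
  pr <- logistic(drop(sel$XS %*% beta_adapt))
  clipped <- any(pr < 1e-10 | pr > 1 - 1e-10)
  pr <- pmin(pmax(pr, 1e-10), 1 - 1e-10)
  v <- pr * (1 - pr)
  inf <- finish_inference("adapt", "logistic", sel$support, beta_adapt,
                          safe_inverse(crossprod(sel$XS * v, sel$XS)))
  if (clipped && !inf$degenerate) inf$reason <- "probabilities_clipped"
  inf
}

#' Oracle (refit) inference for logistic models
#'
#' Algorithm 2 for the logistic family: unpenalized logistic MLE on the
#' selected design; covariance `(XS' V XS)^{-1}` at the refit
#' probabilities.  Complete or quasi-complete separation is flagged as
#' degenerate (such replicates are tallied and excluded from coverage
#' denominators downstream).
#'
#' @inheritParams adaptive_inference_linear
#' @return a `sel_inference` object.
#' @export
oracle_inference_logistic <- function(XS, y) {
  sel <- normalize_design(XS)
  n <- nrow(sel$XS); p_adapt <- ncol(sel$XS)
  if (p_adapt >= n)
    return(new_inference("oracle", "logistic", sel$support,
                         rep(NA_real_, p_adapt), NULL,
                         degenerate = TRUE, reason = "p_adapt_ge_n"))
  sep <- FALSE
  fit <- tryCatch(
    withCallingHandlers(
      stats::glm.fit(sel$XS, y, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients) || !fit$converged)
    return(new_inference("oracle", "logistic", sel$support,
                         rep(NA_real_, p_adapt), NULL,
                         degenerate = TRUE, reason = "refit_failed"))
  beta <- fit$coefficients
  if (sep || any(abs(beta) > 30))
    return(new_inference("oracle", "logistic", sel$support, beta, NULL,
                         degenerate = TRUE, reason = "separation"))
  pr <- pmin(pmax(fit$fitted.values, 1e-10), 1 - 1e-10)
  v <- pr * (1 - pr)
  finish_inference("oracle", "logistic", sel$support, beta,
                   safe_inverse(crossprod(sel$XS * v, sel$XS)))
}

normalize_design <- function(XS) {
  if (is.list(XS) && !is.null(XS$XS)) return(XS)
  stopifnot(is.matrix(XS), all(XS[, 1L] == 1))
  support <- seq_len(ncol(XS) - 1L)  # positional; names carry true indices
  nm <- colnames(XS)
  if (!is.null(nm) && all(grepl("^x[0-9]+$", nm[-1L])))
    support <- as.integer(sub("^x", "", nm[-1L]))
  list(XS = XS, support = support, degenerate = ncol(XS) >= nrow(XS))
}

#' Normal-approximation confidence intervals
#'
#' `estimate_j +/- z_{(1 + level)/2} * sqrt(cov_jj)` for every coefficient
#' of a `sel_inference` (intercept included).  A zero variance yields a
#' degenerate interval equal to the point estimate; a degenerate
#' inference yields `NA` bounds.
#'
#' @param inference a `sel_inference`.
#' @param level confidence level, default 0.95.
#' @return the `sel_inference` with `level`, `lower`, `upper` filled in.
#' @export
confidence_intervals <- function(inference, level = 0.95) {
  stopifnot(inherits(inference, "sel_inference"), level > 0, level < 1)
  inference$level <- level
  k <- inference$p_adapt
  if (inference$degenerate || is.null(inference$covariance)) {
    inference$lower <- rep(NA_real_, k)
    inference$upper <- rep(NA_real_, k)
    return(inference)
  }
  z <- stats::qnorm((1 + level) / 2)
  se <- sqrt(pmax(diag(inference$covariance), 0))
  inference$lower <- inference$estimates - z * se
  inference$upper <- inference$estimates + z * se
  inference
}
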