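# LASSO, elastic net and combined L1/L2 penalized GLMs via glmnet.
#
# All fits keep the intercept unpenalized, leave the predictors
# unstandardized (the simulated designs already have unit variance), use
# the package's geometric penalty path, and tune by K-fold CV with the
# minimum-CV rule (squared error for linear, binomial deviance for
# logistic).

glmnet_family <- function(family) {
  switch(family, linear = "gaussian", logistic = "binomial",
         stop("unsupported family '", family, "'"))
}

# Solve a single-penalty glmnet problem.  A short descending run-in path
# is prepended for numerical stability; the target penalty is the last
# path entry, extracted by position (glmnet rescales the lambda values
# when penalty factors are supplied, so matching by value is unsafe).
glmnet_single <- function(X, y, family, lambda, penalty.factor = NULL,
                          alpha = 1, thresh = 1e-9) {
  pf <- if (is.null(penalty.factor)) rep(1, ncol(X)) else penalty.factor
  path <- sort(unique(lambda * c(4, 1)), decreasing = TRUE)
  fit <- glmnet::glmnet(X, y, family = glmnet_family(family), alpha = alpha,
                        lambda = path, penalty.factor = pf,
                        standardize = FALSE, thresh = thresh)
  k <- length(fit$lambda)
  list(intercept = as.numeric(fit$a0[k]),
       beta = as.numeric(fit$beta[, k]))
}

# CV over (lambda, alpha) with shared folds; returns the minimum-CV fit.
cv_enet <- function(X, y, family, grid, alphas) {
  foldid <- grid_folds(grid, nrow(X))
  base <- lambda_grid(X, y, grid$nlambda, grid$lambda_min_ratio)
  fam <- glmnet_family(family)
  best <- NULL
  warned <- FALSE
  for (a in alphas) {
    lam <- base / max(a, 1e-3)
    cv <- withCallingHandlers(
      glmnet::cv.glmnet(X, y, family = fam, alpha = a, lambda = lam,
                        foldid = foldid, standardize = FALSE,
                        type.measure = "deviance"),
      warning = function(w) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      })
    i <- which.min(cv$cvm)
    if (is.null(best) || cv$cvm[i] < best$cvm) {
      co <- as.numeric(stats::coef(cv$glmnet.fit, s = cv$lambda[i]))
      best <- list(cvm = cv$cvm[i], alpha = a, lambda = cv$lambda[i],
                   intercept = co[1L], beta = co[-1L])
    }
  }
  best$warned <- warned
  best
}

#' LASSO with cross-validated penalty
#'
#' Minimizes the scaled negative log-likelihood plus an L1 penalty on the
#' slopes, with the penalty chosen by K-fold cross validation on the
#' geometric path of [tuning_grid()].  Exact zeros come from the
#' coordinate-descent solver.
#'
#' @param X predictor matrix.
#' @param y outcome.
#' @param family `"linear"` or `"logistic"`.
#' @param grid a [tuning_grid()].
#' @return a [penalized_fit()].
#' @export
fit_lasso <- function(X, y, family = c("linear", "logistic"),
                      grid = tuning_grid()) {
  family <- match.arg(family)
  stopifnot(nrow(X) > grid$cv_folds)
  best <- cv_enet(X, y, family, grid, alphas = 1)
  penalized_fit("lasso", family, best$intercept, best$beta,
                tuning = list(lambda = best$lambda),
                zero_tol = grid$zero_tol,
                diagnostics = list(cv_warning = best$warned))
}

#' Elastic net with cross-validated penalty and mixing
#'
#' Penalty `lambda * (alpha * ||beta||_1 + (1 - alpha) * ||beta||_2^2 / 2)`
#' with `(lambda, alpha)` chosen jointly by K-fold CV over the grid's
#' mixing values and the geometric penalty path (rescaled by `1/alpha` so
#' each path starts at its null model).
#'
#' @inheritParams fit_lasso
#' @return a [penalized_fit()].
#' @export
fit_elastic_net <- function(X, y, family = c("linear", "logistic"),
                            grid = tuning_grid()) {
  family <- match.arg(family)
  best <- cv_enet(X, y, family, grid, alphas = grid$alpha)
  penalized_fit("enet", family, best$intercept, best$beta,
                tuning = list(lambda = best$lambda, alpha = best$alpha),
                zero_tol = grid$zero_tol,
                diagnostics = list(cv_warning = best$warned))
}

#' Penalized GLM with L1 and/or L2 penalties
#'
#' The general likelihood-penalization workhorse: pure L1 (`l2 = FALSE`)
#' reduces to [fit_lasso()], pure L2 (`l1 = FALSE`) is ridge (no exact
#' zeros), and the combination searches the grid's mixing values by CV.
#' The logistic version is the "penalized logistic regression" of the
#' simulation study.
#'
#' @inheritParams fit_lasso
#' @param l1,l2 which penalties to allow.
#' @return a [penalized_fit()].
#' @export
fit_penalized_glm <- function(X, y, family = c("linear", "logistic"),
                              grid = tuning_grid(), l1 = TRUE, l2 = TRUE) {
  family <- match.arg(family)
  if (!l1 && !l2) stop("at least one of l1, l2 must be TRUE")
  alphas <- if (l1 && l2) grid$alpha else if (l1) 1 else 0
  best <- cv_enet(X, y, family, grid, alphas = alphas)
  penalized_fit("penalized", family, best$intercept, best$beta,
                tuning = list(lambda = best$lambda, alpha = best$alpha),
                zero_tol = grid$zero_tol,
                diagnostics = list(cv_warning = best$warned))
}
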