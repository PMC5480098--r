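# Tuning-parameter grids and the common fit container.

#' Tuning grid for the penalized estimators
#'
#' Collects every tuning knob shared by the estimator panel: the geometric
#' penalty path, the elastic-net mixing grid, the relaxed-LASSO relaxation
#' grid, the SCAD concavity constant, the ridge grid for stepwise logistic
#' regression, and the cross-validation layout.
#'
#' @param nlambda number of points on the geometric penalty path.
#' @param lambda_min_ratio smallest penalty as a fraction of the largest.
#' @param alpha elastic-net mixing values in `(0, 1]` searched by CV.
#' @param phi relaxed-LASSO relaxation values in `[0, 1]` searched by CV
#'   (`phi = 0` is an unpenalized refit on the stage-1 support).
#' @param scad_a SCAD concavity constant (> 2); 3.7 is the conventional
#'   default.
#' @param ridge_lambda ridge penalties searched for the stepwise logistic
#'   method.
#' @param cv_folds number of cross-validation folds.
#' @param fold_seed integer seed for fold assignment; folds depend only on
#'   `(n, cv_folds, fold_seed)` so all methods see the same folds within a
#'   replicate.
#' @param zero_tol absolute threshold below which a coefficient is
#'   reported as an exact zero.
#' @return an object of class `tuning_grid`.
#' @export
tuning_grid <- function(nlambda = 50L, lambda_min_ratio = 1e-3,
                        alpha = c(0.2, 0.4, 0.6, 0.8, 1),
                        phi = c(0, 0.25, 0.5, 0.75, 1),
                        scad_a = 3.7,
                        ridge_lambda = c(1e-4, 1e-2, 1),
                        cv_folds = 5L, fold_seed = 1L, zero_tol = 1e-8) {
  stopifnot(nlambda >= 2, lambda_min_ratio > 0, lambda_min_ratio < 1,
            length(alpha) >= 1, all(alpha >= 0), all(alpha <= 1),
            length(phi) >= 1, all(phi >= 0), all(phi <= 1),
            scad_a > 2, length(ridge_lambda) >= 1, cv_folds >= 2)
  structure(
    list(nlambda = as.integer(nlambda), lambda_min_ratio = lambda_min_ratio,
         alpha = alpha, phi = phi, scad_a = scad_a,
         ridge_lambda = ridge_lambda, cv_folds = as.integer(cv_folds),
         fold_seed = as.integer(fold_seed), zero_tol = zero_tol),
    class = "tuning_grid")
}

grid_folds <- function(grid, n) {
  make_folds(n, grid$cv_folds, grid$fold_seed)
}

#' Construct a penalized fit object
#'
#' Common container returned by every estimator: the full-length
#' coefficient vector, the fitted intercept, the selected support
#' (`|beta| > zero_tol`), the chosen tuning values and convergence
#' diagnostics.
#'
#' @param method registry name of the estimator.
#' @param family model family.
#' @param intercept fitted intercept.
#' @param beta length-`p` coefficient vector.
#' @param tuning named list of chosen tuning values.
#' @param zero_tol zero-declaration threshold used for the support.
#' @param diagnostics named list of convergence / fallback flags.
#' @return an object of class `penalized_fit`.
#' @export
penalized_fit <- function(method, family, intercept, beta, tuning = list(),
                          zero_tol = 1e-8, diagnostics = list()) {
  beta <- as.numeric(beta)
  structure(
    list(method = method, family = family, intercept = as.numeric(intercept),
         beta = beta, support = which(abs(beta) > zero_tol),
         tuning = tuning, zero_tol = zero_tol, diagnostics = diagnostics),
    class = "penalized_fit")
}

#' @export
print.penalized_fit <- function(x, ...) {
  cat(sprintf("<penalized_fit> %s (%s): %d of %d coefficients selected\n",
              x$method, x$family, length(x$support), length(x$beta)))
  invisible(x)
}

#' Serialize / deserialize a penalized fit
#'
#' @param fit a [penalized_fit()].
#' @param path JSON file path.
#' @return `path` invisibly; `read_fit_json()` returns a `penalized_fit`.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "penalized_fit"))
  x <- unclass(fit)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  penalized_fit(x$method, x$family, x$intercept, x$beta,
                tuning = as.list(x$tuning), zero_tol = x$zero_tol,
                diagnostics = as.list(x$diagnostics))
}

#' Estimator registry
#'
#' Maps a method name to its fitting function.  `"ppls"` (penalized
#' partial least squares) is registered but off the default list: its
#' sparsity mechanism is only loosely determined by the published record,
#' so nothing downstream relies on it.
#'
#' @return named list of fitting functions with common signature
#'   `(X, y, family, grid)`.
#' @export
method_registry <- function() {
  list(
    lasso    = function(X, y, family, grid) fit_lasso(X, y, family, grid),
    lars     = function(X, y, family, grid) fit_lars(X, y, grid),
    enet     = function(X, y, family, grid) fit_elastic_net(X, y, family, grid),
    relaxo   = function(X, y, family, grid) fit_relaxed_lasso(X, y, grid),
    scad     = function(X, y, family, grid) fit_scad(X, y, family, grid),
    penalized = function(X, y, family, grid)
      fit_penalized_glm(X, y, family, grid, l1 = TRUE, l2 = TRUE),
    stepplr  = function(X, y, family, grid) {
      if (family != "logistic")
        stop("stepplr is a logistic-only method")
      fit_stepwise_ridge_logistic(X, y, grid)
    })
}

#' Default method names per family
#'
#' @param family `"linear"` or `"logistic"`.
#' @return character vector of registry names applicable to the family.
#' @export
default_methods <- function(family = c("linear", "logistic")) {
  family <- match.arg(family)
  if (family == "linear")
    c("lasso", "lars", "enet", "relaxo", "scad", "penalized")
  else
    c("lasso", "scad", "penalized", "stepplr")
}

#' Fit a registered estimator by name
#'
#' @param method registry name (see [method_registry()]).
#' @param X,y data.
#' @param family model family.
#' @param grid a [tuning_grid()].
#' @return a `penalized_fit`.
#' @export
fit_method <- function(method, X, y, family, grid = tuning_grid()) {
  reg <- method_registry()
  if (!method %in% names(reg))
    stop("unknown method '", method, "'; registered: ",
         paste(names(reg), collapse = ", "))
  reg[[method]](X, y, family, grid)
}
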