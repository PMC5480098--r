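# Data generation for one replicate: predictors, linear outcomes, and
# case-control sampled logistic outcomes.

# Draw n rows of predictors.  Multivariate normal draws go through the
# Cholesky factor of the correlation matrix (mean zero, unit variance);
# binary predictors are iid Bernoulli(1/2).
draw_predictors <- function(n, model, corr = NULL) {
  p <- model$p
  if (model$predictor_kind == "binary")
    return(matrix(rbinom(n * p, 1L, 0.5), n, p))
  if (is.null(corr)) corr <- diag(p)
  if (inherits(corr, "correlation_spec")) corr <- build_correlation(corr)
  stopifnot(nrow(corr) == p)
  Z <- matrix(rnorm(n * p), n, p)
  Z %*% chol(corr)
}

draw_errors <- function(n, error_kind) {
  switch(error_kind,
    normal = rnorm(n),
    t2 = rt(n, df = 2),
    t15 = rt(n, df = 15))
}

new_dataset <- function(X, y, model, seed, n0 = NA_integer_, n1 = NA_integer_) {
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  structure(
    list(X = X, y = y, n = nrow(X), n0 = n0, n1 = n1,
         model = model, seed = seed),
    class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %s n=%d p=%d seed=%s\n", x$model$family, x$n,
              ncol(x$X), format(x$seed)))
  invisible(x)
}

#' Simulate a continuous-outcome dataset
#'
#' Draws `X` from the multivariate normal with the given correlation
#' structure (or iid binary predictors), then generates
#' `y = beta0 + X[, support] %*% beta_star + eps` with errors from the
#' model's error law: standard normal, or Student t with 2 or 15 degrees
#' of freedom used unscaled (the t(2) law has infinite variance and is a
#' deliberate robustness violation, not a rescaled noise model).
#'
#' @param model a [true_model()] with `family = "linear"`.
#' @param corr a [correlation_spec()], a correlation matrix, or `NULL` for
#'   independent predictors.
#' @param n sample size.
#' @param seed integer seed; identical seeds give bit-identical datasets.
#' @return a `sim_dataset` with fields `X`, `y`, `n`, `model`, `seed`.
#' @export
simulate_linear <- function(model, corr = NULL, n, seed) {
  stopifnot(inherits(model, "true_model"), model$family == "linear", n >= 1)
  set.seed(seed)
  X <- draw_predictors(n, model, corr)
  lp <- model$beta0_star +
    drop(X[, model$support, drop = FALSE] %*% model$beta_star)
  y <- lp + draw_errors(n, model$error_kind)
  new_dataset(X, y, model, seed)
}

#' Simulate a case-control dataset
#'
#' Streams `(X, Y)` pairs with `Y ~ Bernoulli(plogis(beta0 + X' beta))`
#' from the population model and retains draws until exactly `n1` cases
#' and `n0` controls have been collected, mimicking a case-control study
#' with fixed margins.  Rows appear in collection order.
#'
#' @param model a [true_model()] with `family = "logistic"`.
#' @param corr correlation structure for `mvnormal` predictors; ignored
#'   for binary predictors.
#' @param n0,n1 number of controls and cases to retain.
#' @param seed integer seed.
#' @param max_draws cap on population draws, guarding against designs with
#'   vanishing case (or control) probability.
#' @return a `sim_dataset` with exactly `n0` zeros and `n1` ones in `y`.
#' @export
simulate_case_control <- function(model, corr = NULL, n0, n1, seed,
                                  max_draws = 1e6) {
  stopifnot(inherits(model, "true_model"), model$family == "logistic",
            n0 >= 0, n1 >= 0, n0 + n1 >= 1)
  set.seed(seed)
  need0 <- n0; need1 <- n1
  keptX <- vector("list", 0L); kepty <- vector("list", 0L)
  drawn <- 0
  batch <- max(1000L, 2L * (n0 + n1))
  while (need0 > 0 || need1 > 0) {
    if (drawn >= max_draws)
      stop("case-control sampling did not terminate within ", max_draws,
           " population draws (case probability too extreme?)")
    m <- as.integer(min(batch, max_draws - drawn))
    X <- draw_predictors(m, model, corr)
    lp <- model$beta0_star +
      drop(X[, model$support, drop = FALSE] %*% model$beta_star)
    y <- rbinom(m, 1L, logistic(lp))
    drawn <- drawn + m
    take1 <- which(y == 1L)[seq_len(min(need1, sum(y == 1L)))]
    take0 <- which(y == 0L)[seq_len(min(need0, sum(y == 0L)))]
    take <- sort(c(take0, take1))
    if (length(take)) {
      keptX[[length(keptX) + 1L]] <- X[take, , drop = FALSE]
      kepty[[length(kepty) + 1L]] <- y[take]
      need1 <- need1 - length(take1)
      need0 <- need0 - length(take0)
    }
  }
  X <- do.call(rbind, keptX)
  y <- do.call(c, kepty)
  new_dataset(X, y, model, seed, n0 = as.integer(n0), n1 = as.integer(n1))
}

#' Write / read a simulated dataset
#'
#' The data matrix goes to a plain CSV with header `x1..xp,y`; the
#' generating truth and seed go to a JSON sidecar (`<path>.json`) so a
#' dataset can be reloaded with full provenance.
#'
#' @param dataset a `sim_dataset`.
#' @param path CSV file path; the sidecar is written next to it.
#' @return `path`, invisibly (`write_dataset`); a `sim_dataset`
#'   (`read_dataset`).
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "sim_dataset"))
  df <- as.data.frame(dataset$X)
  df$y <- dataset$y
  utils::write.csv(df, path, row.names = FALSE)
  meta <- dataset$model
  class(meta) <- NULL
  side <- list(model = meta, seed = dataset$seed,
               n0 = dataset$n0, n1 = dataset$n1)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- side$model
  model <- true_model(family = m$family, p = m$p, p_star = m$p_star,
                      magnitude = m$magnitude, beta0_star = m$beta0_star,
                      error_kind = m$error_kind,
                      predictor_kind = m$predictor_kind)
  X <- as.matrix(df[, setdiff(names(df), "y"), drop = FALSE])
  n0 <- if (is.null(side$n0) || is.na(side$n0)) NA_integer_ else as.integer(side$n0)
  n1 <- if (is.null(side$n1) || is.na(side$n1)) NA_integer_ else as.integer(side$n1)
  new_dataset(X, df$y, model, side$seed, n0 = n0, n1 = n1)
}
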