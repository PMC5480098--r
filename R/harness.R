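# Simulation harness: one cell = (design, method, replicates, seed);
# the grid maps cells over a factorial design with deterministic
# per-replicate seeding and incremental CSV output.

#' Define one simulation design cell
#'
#' @param family `"linear"` or `"logistic"`.
#' @param corr_kind correlation structure of multivariate-normal
#'   predictors: `"identity"`, `"block"` or `"ar"`.
#' @param n sample size (linear family).
#' @param n0,n1 control / case counts (logistic family); default equal
#'   split of `n`.
#' @param p,p_star number of predictors and truly associated predictors.
#' @param magnitude common absolute effect size.
#' @param error_kind linear error law (`"normal"`, `"t2"`, `"t15"`).
#' @param predictor_kind `"mvnormal"` or `"binary"`.
#' @param rho correlation scalar for block/AR structures.
#' @param level confidence level for the intervals.
#' @return an object of class `simulation_design`.
#' @export
simulation_design <- function(family = c("linear", "logistic"),
                              corr_kind = c("identity", "block", "ar"),
                              n = 500L, n0 = NULL, n1 = NULL,
                              p = 50L, p_star = 10L, magnitude = 0.5,
                              error_kind = c("normal", "t2", "t15"),
                              predictor_kind = c("mvnormal", "binary"),
                              rho = 0.5, level = 0.95) {
  family <- match.arg(family)
  corr_kind <- match.arg(corr_kind)
  error_kind <- match.arg(error_kind)
  predictor_kind <- match.arg(predictor_kind)
  if (family == "logistic") {
    if (is.null(n0)) n0 <- as.integer(n)
    if (is.null(n1)) n1 <- as.integer(n)
    n <- n0 + n1
  }
  structure(
    list(family = family, corr_kind = corr_kind, n = as.integer(n),
         n0 = if (is.null(n0)) NA_integer_ else as.integer(n0),
         n1 = if (is.null(n1)) NA_integer_ else as.integer(n1),
         p = as.integer(p), p_star = as.integer(p_star),
         magnitude = magnitude, error_kind = error_kind,
         predictor_kind = predictor_kind, rho = rho, level = level),
    class = "simulation_design")
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf("<simulation_design> %s %s n=%d p=%d beta*=%g errors=%s\n",
              x$family, x$corr_kind, x$n, x$p, x$magnitude, x$error_kind))
  invisible(x)
}

design_model <- function(design) {
  true_model(family = design$family, p = design$p, p_star = design$p_star,
             magnitude = design$magnitude, error_kind = design$error_kind,
             predictor_kind = design$predictor_kind)
}

design_corr <- function(design) {
  if (design$predictor_kind == "binary") return(NULL)
  build_correlation(correlation_spec(design$corr_kind, p = design$p,
                                     rho = design$rho))
}

design_descriptors <- function(design, method) {
  list(method = method, family = design$family, sigma = design$corr_kind,
       predictors = design$predictor_kind, n = design$n, n0 = design$n0,
       n1 = design$n1, p = design$p, p_star = design$p_star,
       beta_star = design$magnitude, error = design$error_kind)
}

# simulate -> fit -> both inference algorithms for replicate r
run_replicate <- function(design, method, grid, master_seed, r,
                          corr = NULL) {
  if (is.null(corr)) corr <- design_corr(design)
  model <- design_model(design)
  seed_r <- child_seed(master_seed, r)
  ds <- if (design$family == "linear")
    simulate_linear(model, corr, design$n, seed_r)
  else
    simulate_case_control(model, corr, design$n0, design$n1, seed_r)
  grid_r <- grid
  grid_r$fold_seed <- fold_seed(master_seed, r)
  fit <- fit_method(method, ds$X, ds$y, design$family, grid_r)
  sel <- select_design(ds$X, fit)
  beta_adapt <- c(fit$intercept, fit$beta[sel$support])
  if (design$family == "linear") {
    adapt <- adaptive_inference_linear(sel, ds$y, beta_adapt)
    oracle <- oracle_inference_linear(sel, ds$y)
  } else {
    adapt <- adaptive_inference_logistic(sel, ds$y, beta_adapt)
    oracle <- oracle_inference_logistic(sel, ds$y)
  }
  adapt <- confidence_intervals(adapt, design$level)
  oracle <- confidence_intervals(oracle, design$level)
  replicate_outcome(model$beta_full, fit, adapt, oracle, replicate = r)
}

#' Run one simulation cell
#'
#' For `r = 1..reps`: simulate a dataset with the replicate's child seed,
#' fit the estimator, run both inference algorithms, and record the
#' outcome.  Fit failures are caught and counted; a cell whose failure
#' rate exceeds 50% is marked failed (its metrics are `NA`).  The result
#' is deterministic given `(design, method, master_seed)` and invariant
#' to the order in which replicates would be executed.
#'
#' @param design a [simulation_design()].
#' @param method registry name of the estimator.
#' @param reps number of replicates.
#' @param master_seed integer master seed of the cell.
#' @param grid a [tuning_grid()]; the fold seed is re-derived per
#'   replicate.
#' @param keep_outcomes also return the per-replicate outcome list and
#'   audit log.
#' @return a `metrics_row` (one-row data.frame); with
#'   `keep_outcomes = TRUE`, a list `(row, outcomes, log)`.
#' @export
run_cell <- function(design, method, reps = 1000L, master_seed = 1L,
                     grid = tuning_grid(), keep_outcomes = FALSE) {
  stopifnot(inherits(design, "simulation_design"), reps >= 1)
  corr <- design_corr(design)
  outcomes <- list()
  n_failed <- 0L
  for (r in seq_len(reps)) {
    out <- tryCatch(
      run_replicate(design, method, grid, master_seed, r, corr = corr),
      error = function(e) e)
    if (inherits(out, "error")) n_failed <- n_failed + 1L
    else outcomes[[length(outcomes) + 1L]] <- out
  }
  desc <- design_descriptors(design, method)
  if (n_failed > reps / 2 || !length(outcomes)) {
    row <- as.data.frame(c(desc, list(
      fp_rate = NA_real_, fn_rate = NA_real_,
      cov_zero_null_adapt = NA_real_, cov_zero_null_oracle = NA_real_,
      cov_zero_signal_adapt = NA_real_, cov_zero_signal_oracle = NA_real_,
      cov_truth_adapt = NA_real_, cov_truth_oracle = NA_real_,
      n_replicates = length(outcomes),
      n_degenerate_adapt = NA_integer_, n_degenerate_oracle = NA_integer_,
      n_failed = n_failed)))
    row$failed <- TRUE
    class(row) <- c("metrics_row", class(row))
  } else {
    row <- aggregate_metrics(outcomes, desc, n_failed = n_failed)
    row$failed <- FALSE
  }
  row$master_seed <- master_seed
  if (keep_outcomes)
    list(row = row, outcomes = outcomes,
         log = if (length(outcomes)) outcomes_to_log(outcomes) else NULL)
  else row
}

cell_id <- function(design, method) {
  paste(method, design$family, design$corr_kind, design$predictor_kind,
        design$n, design$p, design$magnitude, design$error_kind, sep = "|")
}

#' Run a factorial grid of simulation cells
#'
#' Maps [run_cell()] over every (design, method) combination.  Each cell
#' gets a deterministic master seed derived from `master_seed` and its
#' position in the enumeration, so an interrupted run resumed from the
#' partial CSV reproduces the uninterrupted table exactly.
#'
#' @param designs list of [simulation_design()] objects.
#' @param methods character vector of registry names; methods not
#'   applicable to a design's family are skipped.
#' @param reps replicates per cell.
#' @param master_seed integer master seed of the whole grid.
#' @param grid a [tuning_grid()].
#' @param out_csv optional path; results are appended after every cell.
#' @param resume reuse rows already present in `out_csv`.
#' @param verbose emit per-cell progress on stderr.
#' @return a `data.frame` with one row per cell (class `results_table`).
#' @export
run_grid <- function(designs, methods, reps = 1000L, master_seed = 1L,
                     grid = tuning_grid(), out_csv = NULL, resume = TRUE,
                     verbose = TRUE) {
  if (inherits(designs, "simulation_design")) designs <- list(designs)
  done <- NULL
  if (!is.null(out_csv) && resume && file.exists(out_csv))
    done <- utils::read.csv(out_csv, stringsAsFactors = FALSE)
  rows <- list()
  idx <- 0L
  for (design in designs) {
    for (method in methods) {
      applicable <- method %in% default_methods(design$family) ||
        (design$family == "linear" && method %in%
           c("lasso", "lars", "enet", "relaxo", "scad", "penalized")) ||
        (design$family == "logistic" && method %in%
           c("lasso", "enet", "scad", "penalized", "stepplr"))
      if (!applicable) next
      idx <- idx + 1L
      id <- cell_id(design, method)
      if (!is.null(done) && id %in% done$cell_id) {
        rows[[length(rows) + 1L]] <- done[done$cell_id == id, , drop = FALSE]
        next
      }
      cseed <- child_seed(master_seed, idx)
      if (verbose)
        message(sprintf("[%d] %s (seed %d, %d reps)", idx, id, cseed, reps))
      row <- run_cell(design, method, reps = reps, master_seed = cseed,
                      grid = grid)
      row$cell_id <- id
      rows[[length(rows) + 1L]] <- row
      if (!is.null(out_csv)) {
        tab <- do.call(rbind, rows)
        utils::write.csv(tab, out_csv, row.names = FALSE)
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame()
  } else {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
  }
  class(out) <- c("results_table", class(out))
  out
}

#' Enumerate the study's factorial designs
#'
#' `"linear"`: three correlation structures x n in {100, 200, 500} x
#' effect size in {0.25, 0.5, 1.0}, normal errors.  `"logistic"`:
#' predictors either independent multivariate normal or iid binary, equal
#' case/control counts in {100, 200, 500}, same effect sizes.
#' `"linear_t2"`: the robustness variant with t(2) errors and
#' independent predictors.  `"pgtn"`: the high-dimensional variant with
#' p = 500 and independent predictors.
#'
#' @param which grid family.
#' @return list of [simulation_design()] objects.
#' @export
study_designs <- function(which = c("linear", "logistic", "linear_t2",
                                    "pgtn")) {
  which <- match.arg(which)
  ns <- c(100L, 200L, 500L)
  betas <- c(0.25, 0.5, 1.0)
  out <- list()
  if (which == "linear") {
    for (ck in c("identity", "block", "ar"))
      for (n in ns) for (b in betas)
        out[[length(out) + 1L]] <-
          simulation_design("linear", ck, n = n, magnitude = b)
  } else if (which == "linear_t2") {
    for (n in ns) for (b in c(0.25, 0.5))
      out[[length(out) + 1L]] <-
        simulation_design("linear", "identity", n = n, magnitude = b,
                          error_kind = "t2")
  } else if (which == "logistic") {
    for (pk in c("mvnormal", "binary"))
      for (n in ns) for (b in betas)
        out[[length(out) + 1L]] <-
          simulation_design("logistic", "identity", n0 = n, n1 = n,
                            magnitude = b, predictor_kind = pk)
  } else {
    for (n in ns) for (b in betas)
      out[[length(out) + 1L]] <-
        simulation_design("linear", "identity", n = n, p = 500L,
                          magnitude = b)
  }
  out
}

#' Run a high-dimensional (p > n) cell
#'
#' Restricts the method list to the estimators that remain usable when
#' `p` exceeds `n` (`lasso`, `lars`, `relaxo`); ridge-initialized SCAD
#' can be allowed explicitly.  Inference proceeds only when the selected
#' dimension stays below `n`; larger supports are flagged degenerate.
#'
#' @inheritParams run_cell
#' @param allow_scad permit the ridge-initialized SCAD despite its
#'   instability in this regime.
#' @return a `metrics_row`.
#' @export
run_pgt_n <- function(design, method, reps = 200L, master_seed = 1L,
                      grid = tuning_grid(), allow_scad = FALSE,
                      keep_outcomes = FALSE) {
  allowed <- c("lasso", "lars", "relaxo", if (allow_scad) "scad")
  if (!method %in% allowed)
    stop("method '", method, "' is not supported when p > n; allowed: ",
         paste(allowed, collapse = ", "),
         if (method == "scad") " (set allow_scad = TRUE to override)" else "")
  run_cell(design, method, reps = reps, master_seed = master_seed,
           grid = grid, keep_outcomes = keep_outcomes)
}
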