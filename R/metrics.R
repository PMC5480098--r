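# Performance criteria: false-positive / false-negative selection rates
# and the three coverage criteria, averaged per coefficient across
# replicates first and then across the relevant coefficient set.

#' Record the outcome of one replicate
#'
#' Collects, for one simulated dataset, everything the performance
#' criteria need: the generating truth, the selected support, and the
#' per-coefficient confidence bounds from both inference algorithms
#' (`NA` where a coefficient was not selected or the algorithm was
#' degenerate).
#'
#' @param beta_true length-`p` true coefficient vector.
#' @param fit a [penalized_fit()].
#' @param adapt,oracle `sel_inference` objects with confidence intervals
#'   filled in (see [confidence_intervals()]); may be `NULL` when
#'   inference was impossible.
#' @param replicate replicate index, kept for audit logs.
#' @return an object of class `replicate_outcome`.
#' @export
replicate_outcome <- function(beta_true, fit, adapt = NULL, oracle = NULL,
                              replicate = NA_integer_) {
  p <- length(beta_true)
  stopifnot(length(fit$beta) == p)
  selected <- logical(p)
  selected[fit$support] <- TRUE
  unpack <- function(inf) {
    ci <- matrix(NA_real_, p, 2L)
    degen <- is.null(inf) || isTRUE(inf$degenerate)
    if (!degen && length(inf$support)) {
      idx <- match(inf$support, seq_len(p))
      ci[idx, 1L] <- inf$lower[-1L]
      ci[idx, 2L] <- inf$upper[-1L]
    }
    list(ci = ci, degenerate = degen)
  }
  a <- unpack(adapt); o <- unpack(oracle)
  structure(
    list(replicate = replicate, beta_true = beta_true, selected = selected,
         ci_adapt = a$ci, ci_oracle = o$ci,
         degenerate_adapt = a$degenerate, degenerate_oracle = o$degenerate),
    class = "replicate_outcome")
}

check_outcomes <- function(outcomes) {
  if (!length(outcomes)) stop("no replicate outcomes supplied")
  stopifnot(all(vapply(outcomes, inherits, TRUE, "replicate_outcome")))
  invisible(outcomes)
}

#' False-positive selection rate
#'
#' A false positive occurs for a truly-zero coefficient whose regularized
#' estimate is nonzero.  The per-coefficient FP rate is averaged over the
#' `p - p_star` zero coefficients.
#'
#' @param outcomes list of [replicate_outcome()] objects.
#' @return scalar rate in `[0, 1]`.
#' @export
fp_rate <- function(outcomes) {
  check_outcomes(outcomes)
  zeros <- which(outcomes[[1L]]$beta_true == 0)
  if (!length(zeros)) stop("no truly-zero coefficients: FP rate undefined")
  sel <- vapply(outcomes, function(o) o$selected[zeros],
                logical(length(zeros)))
  mean(rowMeans(matrix(sel, nrow = length(zeros))))
}

#' False-negative selection rate
#'
#' Mirror of [fp_rate()] over the truly-nonzero coefficients.
#'
#' @inheritParams fp_rate
#' @return scalar rate in `[0, 1]`.
#' @export
fn_rate <- function(outcomes) {
  check_outcomes(outcomes)
  sig <- which(outcomes[[1L]]$beta_true != 0)
  if (!length(sig)) stop("no truly-nonzero coefficients: FN rate undefined")
  mis <- vapply(outcomes, function(o) !o$selected[sig], logical(length(sig)))
  mean(rowMeans(matrix(mis, nrow = length(sig))))
}

ci_of <- function(o, algorithm) {
  if (algorithm == "adapt") list(ci = o$ci_adapt, degen = o$degenerate_adapt)
  else list(ci = o$ci_oracle, degen = o$degenerate_oracle)
}

#' Coverage of zero
#'
#' A coefficient is "zero-covered" in a replicate when its regularized
#' estimate is exactly zero (dropped, hence no interval) or its
#' confidence interval contains zero.  Computed per coefficient over
#' non-degenerate replicates, then averaged over the truly-zero
#' (`which = "null"`) or truly-nonzero (`which = "signal"`) coefficients.
#'
#' @inheritParams fp_rate
#' @param which coefficient set: `"null"` or `"signal"`.
#' @param algorithm `"adapt"` or `"oracle"`.
#' @return scalar rate in `[0, 1]`.
#' @export
coverage_of_zero <- function(outcomes, which = c("null", "signal"),
                             algorithm = c("adapt", "oracle")) {
  check_outcomes(outcomes)
  which <- match.arg(which); algorithm <- match.arg(algorithm)
  set <- if (which == "null") outcomes[[1L]]$beta_true == 0
         else outcomes[[1L]]$beta_true != 0
  idx <- base::which(set)
  if (!length(idx)) stop("empty coefficient set for coverage of zero")
  num <- den <- numeric(length(idx))
  for (o in outcomes) {
    ai <- ci_of(o, algorithm)
    for (k in seq_along(idx)) {
      j <- idx[k]
      if (!o$selected[j]) {               # dropped: covered by definition
        num[k] <- num[k] + 1; den[k] <- den[k] + 1
      } else if (!ai$degen && !is.na(ai$ci[j, 1L])) {
        num[k] <- num[k] + (ai$ci[j, 1L] <= 0 && 0 <= ai$ci[j, 2L])
        den[k] <- den[k] + 1
      }                                    # degenerate: excluded entirely
    }
  }
  ok <- den > 0
  if (!any(ok)) return(NA_real_)
  mean(num[ok] / den[ok])
}

#' Coverage of the true coefficients
#'
#' Over (replicate, signal coefficient) pairs with a nonzero estimate,
#' the fraction whose confidence interval contains the true value,
#' averaged per coefficient and then over the signal coefficients
#' (`conditional = TRUE`, matching the "for beta-hat != 0" conditioning
#' of the reported tables).  With `conditional = FALSE` the denominator
#' is all non-degenerate replicates, so a dropped coefficient counts as
#' non-covered.
#'
#' @inheritParams coverage_of_zero
#' @param conditional condition on selection (default) or not.
#' @return scalar rate in `[0, 1]`; `NA` when no signal coefficient was
#'   ever selected.
#' @export
coverage_of_truth <- function(outcomes, algorithm = c("adapt", "oracle"),
                              conditional = TRUE) {
  check_outcomes(outcomes)
  algorithm <- match.arg(algorithm)
  bt <- outcomes[[1L]]$beta_true
  idx <- which(bt != 0)
  if (!length(idx)) stop("no truly-nonzero coefficients")
  num <- den <- numeric(length(idx))
  for (o in outcomes) {
    ai <- ci_of(o, algorithm)
    if (ai$degen) next
    for (k in seq_along(idx)) {
      j <- idx[k]
      if (o$selected[j] && !is.na(ai$ci[j, 1L])) {
        num[k] <- num[k] + (ai$ci[j, 1L] <= bt[j] && bt[j] <= ai$ci[j, 2L])
        den[k] <- den[k] + 1
      } else if (!conditional) {
        den[k] <- den[k] + 1
      }
    }
  }
  ok <- den > 0
  if (!any(ok)) return(NA_real_)
  if (any(!ok))
    warning(sum(!ok), " signal coefficient(s) never selected; excluded ",
            "from the coverage average")
  mean(num[ok] / den[ok])
}

#' Aggregate replicate outcomes into one results row
#'
#' Assembles the table row for one simulation cell and method: FP/FN
#' rates, the three coverage criteria for both algorithms, replicate and
#' degenerate-case tallies.
#'
#' @inheritParams fp_rate
#' @param design named list (or one-row data.frame) of design
#'   descriptors, e.g. family, method, correlation kind, n, effect size.
#' @param n_failed number of replicates whose fit failed outright (not
#'   present in `outcomes`).
#' @return a one-row `data.frame` of class `metrics_row`.
#' @export
aggregate_metrics <- function(outcomes, design = list(), n_failed = 0L) {
  check_outcomes(outcomes)
  row <- c(
    as.list(design),
    list(
      fp_rate = fp_rate(outcomes),
      fn_rate = fn_rate(outcomes),
      cov_zero_null_adapt = coverage_of_zero(outcomes, "null", "adapt"),
      cov_zero_null_oracle = coverage_of_zero(outcomes, "null", "oracle"),
      cov_zero_signal_adapt = coverage_of_zero(outcomes, "signal", "adapt"),
      cov_zero_signal_oracle = coverage_of_zero(outcomes, "signal", "oracle"),
      cov_truth_adapt = suppressWarnings(
        coverage_of_truth(outcomes, "adapt")),
      cov_truth_oracle = suppressWarnings(
        coverage_of_truth(outcomes, "oracle")),
      n_replicates = length(outcomes),
      n_degenerate_adapt = sum(vapply(outcomes, `[[`, TRUE,
                                      "degenerate_adapt")),
      n_degenerate_oracle = sum(vapply(outcomes, `[[`, TRUE,
                                       "degenerate_oracle")),
      n_failed = as.integer(n_failed)))
  out <- as.data.frame(row, stringsAsFactors = FALSE)
  class(out) <- c("metrics_row", class(out))
  out
}

#' Long-format audit event log
#'
#' One row per (replicate, coefficient): truth, selection status, and
#' both algorithms' confidence bounds and degeneracy flags.  Every metric
#' can be recounted exactly from this table.
#'
#' @inheritParams fp_rate
#' @return a `data.frame`.
#' @export
outcomes_to_log <- function(outcomes) {
  check_outcomes(outcomes)
  do.call(rbind, lapply(outcomes, function(o) {
    p <- length(o$beta_true)
    data.frame(
      replicate = o$replicate, coefficient = seq_len(p),
      beta_true = o$beta_true, selected = o$selected,
      adapt_lower = o$ci_adapt[, 1L], adapt_upper = o$ci_adapt[, 2L],
      adapt_degenerate = o$degenerate_adapt,
      oracle_lower = o$ci_oracle[, 1L], oracle_upper = o$ci_oracle[, 2L],
      oracle_degenerate = o$degenerate_oracle)
  }))
}

#' Full-precision CSV round trip for results tables
#'
#' Numeric columns are written with 17 significant digits so a table read
#' back with [read_metrics_csv()] is bit-identical to the original.
#'
#' @param tab a `metrics_row` / results data.frame.
#' @param path CSV file path.
#' @return `path` invisibly; `read_metrics_csv()` returns the table.
#' @export
write_metrics_csv <- function(tab, path) {
  out <- as.data.frame(tab)
  num <- vapply(out, is.double, TRUE)
  out[num] <- lapply(out[num], function(x) {
    s <- sprintf("%.17g", x)
    plain <- !grepl("[.e]", s)       # keep integral doubles typed as double
    s[plain] <- paste0(s[plain], ".0")
    ifelse(is.na(x), NA_character_, s)
  })
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
read_metrics_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
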