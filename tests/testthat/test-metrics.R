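# small helper: fabricate an outcome with explicit selection and CIs
fake_outcome <- function(beta_true, beta_hat, ci_adapt = NULL,
                         ci_oracle = NULL, r = 1L) {
  p <- length(beta_true)
  fit <- penalized_fit("toy", "linear", 0, beta_hat)
  mk <- function(ci) {
    if (is.null(ci)) return(NULL)
    sup <- fit$support
    inf <- postselsim:::new_inference("adapt", "linear", sup,
                                      c(0, beta_hat[sup]),
                                      diag(1 + length(sup)))
    inf$level <- 0.95
    inf$lower <- c(0, ci[sup, 1])
    inf$upper <- c(0, ci[sup, 2])
    inf
  }
  replicate_outcome(beta_true, fit, mk(ci_adapt), mk(ci_oracle),
                    replicate = r)
}

test_that("FP and FN rates count exactly as defined", {
  o1 <- fake_outcome(c(1, 0, 0), c(0.5, 0.2, 0))
  expect_equal(fp_rate(list(o1)), 0.5)       # one of two nulls selected
  expect_equal(fn_rate(list(o1)), 0)

  o2 <- fake_outcome(c(1, -1), c(0, -1))
  expect_equal(fn_rate(list(o2)), 0.5)

  all_in <- fake_outcome(c(1, 0, 0), c(1, 1, 1))
  expect_equal(fp_rate(list(all_in, all_in)), 1.0)

  none_in <- fake_outcome(c(1, 0, 0), c(1, 0, 0))
  expect_equal(fp_rate(list(none_in)), 0)
  expect_error(fp_rate(list(fake_outcome(c(1, 1), c(1, 1)))), "zero")
  expect_error(fn_rate(list(fake_outcome(c(0, 0), c(0, 0)))), "nonzero")
})

test_that("coverage of zero honours the drop-or-contain rule", {
  bt <- c(1, 0)
  # null selected with CI straddling zero -> covered
  ci <- rbind(c(0.5, 1.5), c(-0.1, 1.1))
  o <- fake_outcome(bt, c(1, 0.5), ci_adapt = ci)
  expect_equal(coverage_of_zero(list(o), "null", "adapt"), 1)
  # CI excluding zero -> not covered
  ci2 <- rbind(c(0.5, 1.5), c(0.2, 0.8))
  o2 <- fake_outcome(bt, c(1, 0.5), ci_adapt = ci2)
  expect_equal(coverage_of_zero(list(o2), "null", "adapt"), 0)
  # dropped coefficient is covered with no CI at all
  o3 <- fake_outcome(bt, c(1, 0), ci_adapt = rbind(c(0.5, 1.5), c(NA, NA)))
  expect_equal(coverage_of_zero(list(o3), "null", "adapt"), 1)
  # signal set uses the same rule on the nonzero coefficients
  expect_equal(coverage_of_zero(list(o), "signal", "adapt"), 0)
})

test_that("coverage of truth conditions on selection", {
  bt <- c(1, 0)
  hit <- fake_outcome(bt, c(1, 0), ci_oracle = rbind(c(0.8, 1.2), c(NA, NA)))
  miss <- fake_outcome(bt, c(1, 0), ci_oracle = rbind(c(0.1, 0.6), c(NA, NA)))
  drop <- fake_outcome(bt, c(0, 0), ci_oracle = rbind(c(NA, NA), c(NA, NA)))
  expect_equal(coverage_of_truth(list(hit, hit), "oracle"), 1)
  expect_equal(coverage_of_truth(list(miss), "oracle"), 0)
  # dropped replicates leave the conditional rate untouched
  expect_equal(coverage_of_truth(list(hit, drop), "oracle"), 1)
  # ... but count against the unconditional variant
  expect_equal(coverage_of_truth(list(hit, drop), "oracle",
                                 conditional = FALSE), 0.5)
  # never-selected coefficient: NA with a warning
  expect_warning(
    v <- coverage_of_truth(list(fake_outcome(c(1, 1, 0), c(1, 0, 0),
      ci_oracle = rbind(c(0.8, 1.2), c(NA, NA), c(NA, NA)))), "oracle"),
    "never selected")
  expect_equal(v, 1)
})

test_that("per-coefficient coverage of zero is at least the drop rate", {
  m <- true_model("linear", p = 10, p_star = 4, magnitude = 0.5)
  d <- simulation_design("linear", "identity", n = 80, p = 10, p_star = 4,
                         magnitude = 0.5)
  res <- run_cell(d, "lasso", reps = 30, master_seed = 17,
                  grid = tuning_grid(nlambda = 20), keep_outcomes = TRUE)
  log <- res$log
  for (j in which(m$beta_full == 0)) {
    sub <- log[log$coefficient == j, ]
    drop_rate <- mean(!sub$selected)
    keep <- !sub$selected | (!sub$oracle_degenerate & !is.na(sub$oracle_lower))
    s2 <- sub[keep, ]
    cov_j <- mean(!s2$selected |
                    (s2$oracle_lower <= 0 & 0 <= s2$oracle_upper))
    expect_gte(cov_j + 1e-12, drop_rate)
  }
})

test_that("every metric is recountable exactly from the audit log", {
  d <- simulation_design("linear", "identity", n = 100, p = 12, p_star = 4,
                         magnitude = 0.5)
  res <- run_cell(d, "lasso", reps = 50, master_seed = 23,
                  grid = tuning_grid(nlambda = 25), keep_outcomes = TRUE)
  rc <- recount_from_log(res$log)
  row <- res$row
  expect_identical(rc$fp, row$fp_rate)
  expect_identical(rc$fn, row$fn_rate)
  expect_identical(rc$cz_null_adapt, row$cov_zero_null_adapt)
  expect_identical(rc$cz_null_oracle, row$cov_zero_null_oracle)
  expect_identical(rc$cz_sig_adapt, row$cov_zero_signal_adapt)
  expect_identical(rc$cz_sig_oracle, row$cov_zero_signal_oracle)
  expect_equal(rc$ct_adapt, row$cov_truth_adapt)
  expect_equal(rc$ct_oracle, row$cov_truth_oracle)
})

test_that("aggregation validates input and round-trips through CSV", {
  expect_error(aggregate_metrics(list()), "no replicate outcomes")

  o <- fake_outcome(c(1, 0), c(1, 0),
                    ci_adapt = rbind(c(0.5, 1.5), c(NA, NA)),
                    ci_oracle = rbind(c(0.5, 1.5), c(NA, NA)))
  row <- aggregate_metrics(list(o), design = list(method = "toy", n = 10))
  expect_identical(row$n_replicates, 1L)
  rates <- unlist(row[c("fp_rate", "fn_rate", "cov_truth_oracle")])
  expect_true(all(rates >= 0 & rates <= 1))

  d <- simulation_design("linear", "identity", n = 80, p = 10, p_star = 4,
                         magnitude = 1)
  full <- run_cell(d, "lasso", reps = 7, master_seed = 3,
                   grid = tuning_grid(nlambda = 20))
  path <- file.path(tempdir(), "row.csv")
  write_metrics_csv(full, path)
  back <- read_metrics_csv(path)
  keep <- vapply(full, is.numeric, TRUE) & !vapply(full, anyNA, TRUE)
  for (cn in names(full)[keep])
    expect_identical(back[[cn]], as.data.frame(full)[[cn]], label = cn)
  unlink(path)
})
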