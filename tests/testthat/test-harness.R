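small_grid <- function(seed = 1L) tuning_grid(nlambda = 15, fold_seed = seed)

test_that("every (method, family) pair completes a one-replicate cell", {
  dl <- simulation_design("linear", "identity", n = 120, p = 15, p_star = 4,
                          magnitude = 1)
  for (m in default_methods("linear")) {
    row <- run_cell(dl, m, reps = 1, master_seed = 2, grid = small_grid())
    expect_s3_class(row, "metrics_row")
    expect_false(row$failed)
    expect_identical(row$n_replicates, 1L)
    expect_true(row$fp_rate >= 0 && row$fp_rate <= 1)
  }
  dg <- simulation_design("logistic", "identity", n0 = 80, n1 = 80, p = 15,
                          p_star = 4, magnitude = 1)
  for (m in default_methods("logistic")) {
    row <- run_cell(dg, m, reps = 1, master_seed = 2, grid = small_grid())
    expect_false(row$failed)
    expect_true(row$fn_rate >= 0 && row$fn_rate <= 1)
  }
})

test_that("a cell is bit-reproducible from its master seed", {
  d <- simulation_design("linear", "ar", n = 90, p = 12, p_star = 4,
                         magnitude = 0.5)
  a <- run_cell(d, "lasso", reps = 5, master_seed = 99, grid = small_grid())
  b <- run_cell(d, "lasso", reps = 5, master_seed = 99, grid = small_grid())
  expect_identical(a, b)
  c <- run_cell(d, "lasso", reps = 5, master_seed = 100, grid = small_grid())
  expect_false(identical(a$fp_rate, c$fp_rate))
})

test_that("replicate bookkeeping adds up", {
  d <- simulation_design("linear", "identity", n = 60, p = 10, p_star = 4,
                         magnitude = 0.5)
  res <- run_cell(d, "lasso", reps = 8, master_seed = 5,
                  grid = small_grid(), keep_outcomes = TRUE)
  row <- res$row
  expect_identical(row$n_replicates + row$n_failed, 8L)
  expect_lte(row$n_degenerate_oracle, row$n_replicates)
  expect_identical(nrow(res$log), 8L * 10L)
})

test_that("the factorial enumerations match the study layout", {
  lin <- study_designs("linear")
  expect_length(lin, 27)           # 3 structures x 3 n x 3 effect sizes
  expect_identical(unique(vapply(lin, `[[`, "", "family")), "linear")
  log_ <- study_designs("logistic")
  expect_length(log_, 18)          # 2 predictor laws x 3 n x 3 effects
  expect_true(all(vapply(log_, function(d) d$n0 == d$n1, TRUE)))
  pg <- study_designs("pgtn")
  expect_true(all(vapply(pg, `[[`, 0L, "p") == 500L))
})

test_that("grids run, resume and stay deterministic", {
  designs <- list(
    simulation_design("linear", "identity", n = 60, p = 8, p_star = 2,
                      magnitude = 1),
    simulation_design("linear", "block", n = 60, p = 8, p_star = 2,
                      magnitude = 1, rho = 0.3))
  csv <- file.path(tempdir(), "grid.csv")
  unlink(csv)
  # interrupted run: first design only
  partial <- run_grid(designs[1], "lasso", reps = 3, master_seed = 11,
                      grid = small_grid(), out_csv = csv, verbose = FALSE)
  expect_identical(nrow(partial), 1L)
  # resumed full run reuses the stored first row
  full <- run_grid(designs, "lasso", reps = 3, master_seed = 11,
                   grid = small_grid(), out_csv = csv, verbose = FALSE)
  # uninterrupted reference run
  unlink(csv)
  ref <- run_grid(designs, "lasso", reps = 3, master_seed = 11,
                  grid = small_grid(), out_csv = NULL, verbose = FALSE)
  expect_equal(full$fp_rate, ref$fp_rate, tolerance = 1e-12)
  expect_equal(full$cov_truth_oracle, ref$cov_truth_oracle,
               tolerance = 1e-12)
  expect_identical(full$cell_id, ref$cell_id)
  unlink(csv)

  empty <- run_grid(designs, character(0), reps = 1, verbose = FALSE)
  expect_identical(nrow(empty), 0L)
})

test_that("the p > n pathway restricts methods and keeps inference sane", {
  d <- simulation_design("linear", "identity", n = 100, p = 500,
                         magnitude = 1)
  expect_error(run_pgt_n(d, "scad"), "not supported")
  expect_error(run_pgt_n(d, "penalized"), "not supported")
  res <- run_pgt_n(d, "lasso", reps = 2, master_seed = 4,
                   grid = small_grid(), keep_outcomes = TRUE)
  expect_false(res$row$failed)
  # lasso support size is bounded by n, so p_adapt < n in every replicate
  expect_identical(res$row$n_degenerate_oracle, 0L)
  for (o in res$outcomes) expect_lt(sum(o$selected), 100)
})

test_that("the CLI front end drives the harness", {
  out <- file.path(tempdir(), "cli-row.csv")
  suppressMessages(postselsim_cli(c(
    "run-cell", "--family", "linear", "--method", "lasso",
    "--sigma", "identity", "--n", "60", "--p", "10", "--p_star", "4",
    "--beta", "1", "--reps", "2", "--seed", "3", "--out", out)))
  got <- utils::read.csv(out)
  expect_identical(nrow(got), 1L)
  expect_identical(got$method, "lasso")

  cfg <- file.path(tempdir(), "cfg.json")
  jsonlite::write_json(list(
    methods = "lasso", reps = 1, seed = 2,
    cells = list(list(family = "linear", sigma = "identity", n = 60,
                      p = 10, p_star = 4, beta = 1))),
    cfg, auto_unbox = TRUE)
  dir_out <- file.path(tempdir(), "cli-grid")
  suppressMessages(postselsim_cli(c("run-grid", "--config", cfg,
                                    "--out", dir_out)))
  expect_true(file.exists(file.path(dir_out, "results.csv")))
  rep_out <- capture.output(
    suppressMessages(postselsim_cli(c("report", "--in", dir_out,
                                      "--format", "md"))))
  expect_true(any(grepl("^\\| method", rep_out)))
  unlink(c(out, cfg), recursive = TRUE)
  unlink(dir_out, recursive = TRUE)
})
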