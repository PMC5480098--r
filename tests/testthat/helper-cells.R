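# Shared Monte-Carlo cells for the headline-reproduction tests.  Cells are
# computed once per test run and memoized, since several checks read
# different columns of the same cell.

.cell_cache <- new.env(parent = emptyenv())

acceptance_cell <- function(key) {
  if (!is.null(.cell_cache[[key]])) return(.cell_cache[[key]])
  logi <- function(method, seed, reps = 200) {
    d <- simulation_design("logistic", "identity", n0 = 500, n1 = 500,
                           magnitude = 1.0)
    run_cell(d, method, reps = reps, master_seed = seed)
  }
  row <- switch(key,
    lasso_logistic = logi("lasso", 101),
    scad_logistic = logi("scad", 102),
    penalized_logistic = logi("penalized", 103),
    stepplr_logistic = logi("stepplr", 104),
    lasso_t2 = run_cell(
      simulation_design("linear", "identity", n = 500, magnitude = 0.5,
                        error_kind = "t2"),
      "lasso", reps = 500, master_seed = 105),
    enet_block_100 = run_cell(
      simulation_design("linear", "block", n = 100, magnitude = 0.25),
      "enet", reps = 200, master_seed = 106),
    enet_block_200 = run_cell(
      simulation_design("linear", "block", n = 200, magnitude = 0.5),
      "enet", reps = 200, master_seed = 107),
    enet_block_500 = run_cell(
      simulation_design("linear", "block", n = 500, magnitude = 1.0),
      "enet", reps = 200, master_seed = 108),
    relaxo_b025 = run_cell(
      simulation_design("linear", "identity", n = 500, magnitude = 0.25),
      "relaxo", reps = 200, master_seed = 109),
    relaxo_b05 = run_cell(
      simulation_design("linear", "identity", n = 500, magnitude = 0.5),
      "relaxo", reps = 200, master_seed = 110),
    stop("unknown cell key: ", key))
  .cell_cache[[key]] <- row
  row
}
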