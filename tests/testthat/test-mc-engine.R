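fast_config <- function(...) {
  simulation_config(n_iterations = 100, n_boot = 25, master_seed = 7,
                    compute_fits = FALSE, ...)
}

test_that("identical contour sets never differ significantly", {
  co <- make_test_cohort(n = 150, rank_correlation = 1, seed = 2)
  expect_equal(cor(co$D_gt, co$D_alt, method = "spearman"), 1)
  cell <- run_cell(co, ntcp_params(1, 1), fast_config())
  expect_equal(cell$summary$fraction_significant_gt_better, 0)
  expect_equal(cell$summary$fraction_significant_alt_better, 0)
  expect_equal(cell$summary$mean_auc_diff, 0, tolerance = 1e-12)
})

test_that("preconditions are enforced", {
  co <- make_test_cohort(n = 50, seed = 3)
  expect_error(run_cell(co, ntcp_params(1, 1), fast_config(),
                        cohort_size = 60), "exceeds")
  raw <- generate_cohort(50, seed = 3)
  expect_error(run_cell(raw, ntcp_params(1, 1), fast_config()),
               "normalized")
})

test_that("runs are bit-exact reproducible from the master seed", {
  co <- make_test_cohort(n = 120, seed = 4)
  cfg <- simulation_config(n_iterations = 40, n_boot = 20, master_seed = 99,
                           compute_fits = TRUE)
  a <- run_cell(co, ntcp_params(1, 1), cfg, cell_index = 2L)
  b <- run_cell(co, ntcp_params(1, 1), cfg, cell_index = 2L)
  expect_identical(a$iterations, b$iterations)
  # a different master seed moves the Monte Carlo estimate only within noise
  cfg2 <- simulation_config(n_iterations = 40, n_boot = 20, master_seed = 123,
                            compute_fits = TRUE)
  c2 <- run_cell(co, ntcp_params(1, 1), cfg2, cell_index = 2L)
  p <- a$summary$fraction_significant_gt_better
  se <- sqrt(max(p * (1 - p), 0.25 / 40) / 40)
  expect_lt(abs(c2$summary$fraction_significant_gt_better - p), 4 * se + 0.26)
})

test_that("event rate matches the cohort mean NTCP within Monte Carlo error", {
  co <- make_test_cohort(n = 400, seed = 6)
  p <- ntcp_params(1, 0.5)
  cfg <- simulation_config(n_iterations = 300, n_boot = 0, master_seed = 17,
                           compute_fits = FALSE)
  cell <- run_cell(co, p, cfg)
  target <- mean(ntcp(co$D_gt, p))
  se <- sqrt(target * (1 - target) / (400 * 300))
  expect_lt(abs(cell$summary$mean_event_pct / 100 - target), 4 * se)
})

test_that("subsampling draws without replacement and keeps records", {
  co <- make_test_cohort(n = 100, seed = 13)
  cfg <- simulation_config(n_iterations = 30, n_boot = 0, master_seed = 5,
                           compute_fits = FALSE, keep_indices = TRUE)
  cell <- run_cell(co, ntcp_params(1, 1), cfg, cohort_size = 40)
  expect_equal(nrow(cell$iterations), 30L)
  for (idx in cell$indices) {
    expect_length(idx, 40L)
    expect_false(anyDuplicated(idx) > 0)
  }
  # subsamples differ across iterations
  expect_gt(length(unique(vapply(cell$indices, paste, character(1),
                                 collapse = ","))), 1L)
})

test_that("swapping ground truth and alternative swaps the superiority", {
  co <- make_test_cohort(n = 250, rank_correlation = 0.85, seed = 31)
  swapped <- normalize_cohort(
    dose_cohort(D_gt = co$D_alt * co$normalization_factor,
                D_alt = co$D_gt * co$normalization_factor,
                parameter_name = co$parameter_name))
  p <- ntcp_params(1, 1.5)
  cfg <- simulation_config(n_iterations = 150, n_boot = 50, master_seed = 8,
                           compute_fits = FALSE)
  fwd <- run_cell(co, p, cfg)$summary
  rev <- run_cell(swapped, p, cfg)$summary
  # whichever set generates the outcomes wins; direction flips with the roles
  expect_gt(fwd$fraction_significant_gt_better,
            fwd$fraction_significant_alt_better)
  expect_gt(rev$fraction_significant_gt_better,
            rev$fraction_significant_alt_better)
  expect_gt(fwd$mean_auc_diff, 0)
  expect_gt(rev$mean_auc_diff, 0)
})

test_that("degenerate iterations are recorded invalid and excluded", {
  # a tiny cohort at a shallow slope produces some all-0/all-1 outcome draws
  co <- make_test_cohort(n = 4, seed = 19)
  cfg <- simulation_config(n_iterations = 200, n_boot = 10, master_seed = 3,
                           compute_fits = FALSE)
  cell <- run_cell(co, ntcp_params(1, 0.3), cfg)
  its <- cell$iterations
  expect_true(any(!its$valid))
  expect_true(all(its$invalid_reason[!its$valid] == "degenerate_outcome"))
  expect_equal(cell$summary$n_valid + cell$summary$n_invalid, 200L)
  expect_equal(cell$summary$fraction_significant_gt_better,
               mean(its$significant_gt_better[its$valid]))
})

test_that("sweep covers the grid and is reproducible", {
  co <- make_test_cohort(n = 80, seed = 23)
  cfg <- simulation_config(gamma_grid = c(0.5, 1), cohort_sizes = c(40L, 80L),
                           n_iterations = 25, n_boot = 10, master_seed = 42,
                           compute_fits = FALSE)
  sw1 <- run_sweep(co, cfg)
  expect_equal(nrow(sw1$summary), 4L)  # 2 gammas x 2 sizes
  expect_setequal(sw1$summary$gamma, c(0.5, 1))
  expect_setequal(sw1$summary$cohort_size, c(40L, 80L))
  sw2 <- run_sweep(co, cfg)
  expect_identical(sw1$summary, sw2$summary)
  # named multi-parameter form checks patient consistency
  other <- make_test_cohort(n = 60, seed = 24)
  expect_error(run_sweep(list(MHD = co, V5Gy = other), cfg),
               "same patients")
})

test_that("sweep output files are written and bit-stable", {
  co <- make_test_cohort(n = 60, seed = 29)
  cfg <- simulation_config(gamma_grid = c(1), n_iterations = 20, n_boot = 10,
                           master_seed = 11, compute_fits = TRUE)
  sw <- run_sweep(co, cfg)
  d <- tempfile(); dir.create(d)
  write_iterations_csv(sw, file.path(d, "iterations.csv"))
  write_summary_csv(sw, file.path(d, "summary.csv"))
  write_run_meta(sw, file.path(d, "run_meta.json"))
  its <- read.csv(file.path(d, "iterations.csv"))
  expect_equal(nrow(its), 20L)
  expect_true(all(c("cell_index", "gamma", "auc_diff",
                    "significant_gt_better") %in% names(its)))
  meta <- jsonlite::read_json(file.path(d, "run_meta.json"))
  expect_equal(meta$config$master_seed, 11L)
})
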