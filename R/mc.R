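#' Configuration of a Monte Carlo simulation
#'
#' Collects the grid and bookkeeping settings of the Monte Carlo framework:
#' for each cell of (gamma, dosimetric parameter, cohort size) the engine
#' runs `n_iterations` iterations, each simulating one binary outcome per
#' patient from the predefined logistic NTCP model, fitting one model per
#' contour set, and comparing the two models' AUCs with a paired bootstrap.
#'
#' @param gamma_grid positive gamma values to sweep (default 0.1 to 1.5 in
#'   steps of 0.1).
#' @param D50 midpoint of the predefined model (default 1, the mean of the
#'   normalized ground-truth parameter).
#' @param n_iterations Monte Carlo iterations per cell (default 3000).
#' @param n_boot bootstrap draws per iteration (default 100); `0` skips the
#'   bootstrap comparison and records only the point AUCs.
#' @param alpha significance level of the bootstrap superiority rule
#'   (default 0.05).
#' @param cohort_sizes integer cohort sizes; `NULL` means the full cohort
#'   only.  Sizes below the full size are drawn by subsampling patients
#'   without replacement in every iteration.
#' @param master_seed integer master seed; every cell and iteration derives
#'   its own substream from it deterministically.
#' @param refit_in_bootstrap refit `(D50, gamma)` within each bootstrap draw
#'   (sensitivity mode; AUCs are unchanged by the refit).
#' @param compute_fits fit the two NTCP models in every iteration (default
#'   `TRUE`).  The significance fraction and AUC statistics are rank
#'   statistics of the dose vectors and are unaffected when fits are
#'   skipped, so event-rate or calibration studies may disable them.
#' @param fit_control a [fit_control()] list for the per-iteration fits.
#' @param keep_indices retain each iteration's subsample indices in memory.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(gamma_grid = seq(0.1, 1.5, by = 0.1),
                              D50 = 1,
                              n_iterations = 3000L,
                              n_boot = 100L,
                              alpha = 0.05,
                              cohort_sizes = NULL,
                              master_seed = 1L,
                              refit_in_bootstrap = FALSE,
                              compute_fits = TRUE,
                              fit_control = ntcpsim::fit_control(),
                              keep_indices = FALSE) {
  stopifnot(all(gamma_grid > 0), D50 > 0, n_iterations >= 1, n_boot >= 0,
            alpha > 0, alpha < 0.5,
            is.null(cohort_sizes) || all(cohort_sizes >= 2))
  structure(list(gamma_grid = gamma_grid, D50 = D50,
                 n_iterations = as.integer(n_iterations),
                 n_boot = as.integer(n_boot), alpha = alpha,
                 cohort_sizes = if (is.null(cohort_sizes)) NULL
                                else as.integer(cohort_sizes),
                 master_seed = as.integer(master_seed),
                 refit_in_bootstrap = isTRUE(refit_in_bootstrap),
                 compute_fits = isTRUE(compute_fits),
                 fit_control = fit_control,
                 keep_indices = isTRUE(keep_indices)),
            class = "simulation_config")
}

# Deterministic 31-bit substream seeds: Lehmer-style mixing keeps every
# intermediate below 2^53 so double arithmetic is exact.
derive_seed <- function(...) {
  h <- 17
  for (v in c(...)) {
    stopifnot(is.finite(v))
    h <- (h * 48271 + as.numeric(v) %% 2147483647) %% 2147483647
  }
  as.integer(h %% 2147483646 + 1)  # never 0
}

#' Run one Monte Carlo cell
#'
#' Executes `config$n_iterations` iterations for a single combination of
#' predefined model parameters and cohort size.  Each iteration:
#' subsamples `cohort_size` patients without replacement (the identity when
#' equal to the full size); computes each subsampled patient's NTCP from the
#' ground-truth dose parameter under `params`; draws one Bernoulli outcome
#' per patient; fits one logistic NTCP model on `(D_gt, y)` and one on
#' `(D_alt, y)`; and compares the two models' AUCs with a paired bootstrap.
#' Iterations with degenerate outcomes (all 0 or all 1) or failed fits are
#' recorded as invalid with a machine-readable reason and excluded from the
#' aggregates; if more than half the iterations are invalid the run fails.
#'
#' Every iteration runs under its own seed derived from
#' `config$master_seed` (and `cell_index`), with a fixed draw order
#' (subsample, outcomes, bootstrap), so any iteration is bit-exactly
#' reproducible in isolation.
#'
#' @param cohort a normalized [dose_cohort()].
#' @param params the predefined [ntcp_params()] generating the outcomes.
#' @param config a [simulation_config()].
#' @param cohort_size patients per iteration (default: full cohort).
#' @param cell_index integer distinguishing this cell's seed stream within a
#'   sweep.
#' @return An object of class `mc_cell`: list with `iterations` (one data
#'   frame row per iteration), `summary` (one-row data frame of aggregates
#'   over valid iterations), and the cell metadata.
#' @seealso [run_sweep()]
#' @export
run_cell <- function(cohort, params, config = simulation_config(),
                     cohort_size = NULL, cell_index = 1L) {
  stopifnot(inherits(cohort, "dose_cohort"), inherits(params, "ntcp_params"),
            inherits(config, "simulation_config"))
  if (!isTRUE(cohort$normalized))
    stop("cohort must be normalized before simulation (see normalize_cohort)")
  n_full <- length(cohort$D_gt)
  if (is.null(cohort_size)) cohort_size <- n_full
  if (cohort_size > n_full)
    stop(sprintf("cohort_size (%d) exceeds the cohort (%d patients)",
                 cohort_size, n_full))

  cell_seed <- derive_seed(config$master_seed, cell_index)
  n_it <- config$n_iterations
  rec <- data.frame(
    iteration = seq_len(n_it), seed = NA_integer_,
    cohort_size = cohort_size, event_fraction = NA_real_,
    D50_gt = NA_real_, gamma_gt = NA_real_,
    D50_alt = NA_real_, gamma_alt = NA_real_,
    auc_gt = NA_real_, auc_alt = NA_real_, auc_diff = NA_real_,
    frac_boot_gt_higher = NA_real_,
    significant_gt_better = NA, significant_alt_better = NA,
    n_degenerate_redraws = NA_integer_,
    valid = FALSE, invalid_reason = "")
  indices <- if (config$keep_indices) vector("list", n_it) else NULL

  for (i in seq_len(n_it)) {
    it_seed <- derive_seed(cell_seed, i)
    rec$seed[i] <- it_seed
    set.seed(it_seed)
    idx <- if (cohort_size < n_full)
      sample.int(n_full, cohort_size, replace = FALSE) else seq_len(n_full)
    if (config$keep_indices) indices[[i]] <- idx
    Dg <- cohort$D_gt[idx]; Da <- cohort$D_alt[idx]

    out <- simulate_outcomes(ntcp(Dg, params),
                             rng_state_tag = sprintf("cell%d/it%d",
                                                     cell_index, i))
    rec$event_fraction[i] <- out$event_fraction
    if (out$degenerate) {
      rec$invalid_reason[i] <- "degenerate_outcome"
      next
    }
    y <- out$labels

    if (config$compute_fits) {
      fg <- tryCatch(fit_ntcp(Dg, y, control = config$fit_control),
                     ntcpsim_error = function(e) e)
      fa <- tryCatch(fit_ntcp(Da, y, control = config$fit_control),
                     ntcpsim_error = function(e) e)
      if (inherits(fg, "condition") || inherits(fa, "condition")) {
        rec$invalid_reason[i] <- "fit_failure"
        next
      }
      rec$D50_gt[i] <- fg$params_hat$D50; rec$gamma_gt[i] <- fg$params_hat$gamma
      rec$D50_alt[i] <- fa$params_hat$D50; rec$gamma_alt[i] <- fa$params_hat$gamma
    }

    rec$auc_gt[i] <- auc(Dg, y)
    rec$auc_alt[i] <- auc(Da, y)
    rec$auc_diff[i] <- rec$auc_gt[i] - rec$auc_alt[i]

    if (config$n_boot > 0L) {
      cmp <- bootstrap_compare(Dg, Da, y, n_boot = config$n_boot,
                               alpha = config$alpha,
                               refit = config$refit_in_bootstrap,
                               fit_args = list(control = config$fit_control))
      rec$frac_boot_gt_higher[i] <- cmp$frac_boot_gt_higher
      rec$significant_gt_better[i] <- cmp$significant_gt_better
      rec$significant_alt_better[i] <- cmp$significant_alt_better
      rec$n_degenerate_redraws[i] <- cmp$n_degenerate_redraws
    }
    rec$valid[i] <- TRUE
  }

  if (mean(!rec$valid) > 0.5)
    stop(sprintf("more than 50%% of iterations invalid (%d of %d); run aborted",
                 sum(!rec$valid), n_it))

  structure(list(iterations = rec,
                 indices = indices,
                 summary = summarize_cell(rec, cohort$parameter_name,
                                          params, cohort_size),
                 parameter_name = cohort$parameter_name,
                 params = params, cohort_size = cohort_size,
                 cell_index = cell_index, cell_seed = cell_seed,
                 config = config),
            class = "mc_cell")
}

summarize_cell <- function(rec, parameter_name, params, cohort_size) {
  v <- rec[rec$valid, , drop = FALSE]
  has_boot <- any(!is.na(v$significant_gt_better))
  data.frame(
    parameter_name = parameter_name,
    gamma = params$gamma, D50 = params$D50, cohort_size = cohort_size,
    n_iterations = nrow(rec), n_valid = nrow(v),
    n_invalid = nrow(rec) - nrow(v),
    fraction_significant_gt_better =
      if (has_boot) mean(v$significant_gt_better) else NA_real_,
    fraction_significant_alt_better =
      if (has_boot) mean(v$significant_alt_better) else NA_real_,
    mean_auc_diff = mean(v$auc_diff), sd_auc_diff = sd(v$auc_diff),
    mean_auc_gt = mean(v$auc_gt), sd_auc_gt = sd(v$auc_gt),
    mean_auc_alt = mean(v$auc_alt), sd_auc_alt = sd(v$auc_alt),
    mean_event_pct = 100 * mean(v$event_fraction),
    sd_event_pct = 100 * sd(v$event_fraction))
}

#' @export
print.mc_cell <- function(x, digits = 4, ...) {
  s <- x$summary
  cat(sprintf("Monte Carlo cell: %s, gamma = %g, D50 = %g, cohort size %d\n",
              s$parameter_name, s$gamma, s$D50, s$cohort_size))
  cat(sprintf("  %d iterations (%d valid)\n", s$n_iterations, s$n_valid))
  if (!is.na(s$fraction_significant_gt_better))
    cat(sprintf("  ground truth significantly better in %.1f%% of iterations\n",
                100 * s$fraction_significant_gt_better))
  cat(sprintf("  AUC difference %.*g +/- %.*g; events %.1f +/- %.1f %%\n",
              digits, s$mean_auc_diff, digits, s$sd_auc_diff,
              s$mean_event_pct, s$sd_event_pct))
  invisible(x)
}

#' Sweep the Monte Carlo simulation over gamma, parameter and cohort size
#'
#' Runs [run_cell()] for every combination of `config$gamma_grid`, the
#' supplied dosimetric-parameter cohorts, and `config$cohort_sizes`.
#' Per-cell seeds are derived deterministically from the master seed, so any
#' cell can be reproduced in isolation and cells are order-independent.
#'
#' @param cohorts a single normalized [dose_cohort()], or a named list of
#'   them (one per dosimetric parameter, covering the same patients).
#' @param config a [simulation_config()].
#' @param keep_iterations retain each cell's per-iteration records (needed
#'   by [write_iterations_csv()]).
#' @param verbose print one progress line per cell.
#' @return An object of class `mc_sweep`: list with `summary` (one row per
#'   cell, long format), `cells` (list of `mc_cell` objects, iterations
#'   stripped unless `keep_iterations`), and `config`.
#' @export
run_sweep <- function(cohorts, config = simulation_config(),
                      keep_iterations = TRUE, verbose = FALSE) {
  if (inherits(cohorts, "dose_cohort"))
    cohorts <- structure(list(cohorts),
                         names = cohorts$parameter_name)
  stopifnot(length(cohorts) >= 1,
            all(vapply(cohorts, inherits, logical(1), "dose_cohort")))
  ids <- lapply(cohorts, `[[`, "patient_ids")
  if (length(unique(ids)) != 1L)
    stop("all cohorts must cover the same patients in the same order")
  n_full <- length(cohorts[[1L]]$D_gt)
  sizes <- if (is.null(config$cohort_sizes)) n_full else config$cohort_sizes
  if (any(sizes > n_full)) stop("cohort_sizes exceed the cohort")

  grid <- expand.grid(size_i = seq_along(sizes),
                      gamma_i = seq_along(config$gamma_grid),
                      param_i = seq_along(cohorts))
  cells <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    g <- config$gamma_grid[grid$gamma_i[k]]
    co <- cohorts[[grid$param_i[k]]]
    sz <- sizes[grid$size_i[k]]
    if (verbose)
      message(sprintf("cell %d/%d: %s gamma=%g size=%d",
                      k, nrow(grid), co$parameter_name, g, sz))
    cell <- run_cell(co, ntcp_params(config$D50, g), config,
                     cohort_size = sz, cell_index = k)
    if (!keep_iterations) cell$iterations <- NULL
    cells[[k]] <- cell
  }
  summary <- do.call(rbind, lapply(cells, `[[`, "summary"))
  summary <- cbind(cell_index = seq_len(nrow(grid)), summary)
  rownames(summary) <- NULL
  structure(list(summary = summary, cells = cells, config = config),
            class = "mc_sweep")
}

#' @export
print.mc_sweep <- function(x, ...) {
  cat(sprintf("Monte Carlo sweep: %d cell(s), %d iteration(s) each\n",
              nrow(x$summary), x$config$n_iterations))
  print(x$summary[, c("cell_index", "parameter_name", "gamma", "cohort_size",
                      "fraction_significant_gt_better", "mean_auc_diff",
                      "sd_auc_diff", "mean_event_pct")])
  invisible(x)
}

#' Write sweep results to disk
#'
#' `write_iterations_csv()` writes one row per Monte Carlo iteration across
#' all cells; `write_summary_csv()` one row per cell; `write_run_meta()` a
#' JSON record of the configuration and seeds.
#'
#' @param sweep an `mc_sweep` from [run_sweep()] (with `keep_iterations =
#'   TRUE` for the iterations file).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_iterations_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "mc_sweep"))
  its <- lapply(sweep$cells, function(cell) {
    if (is.null(cell$iterations))
      stop("sweep was run with keep_iterations = FALSE")
    cbind(cell_index = cell$cell_index,
          parameter_name = cell$parameter_name,
          gamma = cell$params$gamma,
          cell$iterations)
  })
  write.csv(do.call(rbind, its), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_iterations_csv
#' @export
write_summary_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "mc_sweep"))
  write.csv(sweep$summary, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_iterations_csv
#' @export
write_run_meta <- function(sweep, path) {
  stopifnot(inherits(sweep, "mc_sweep"))
  cfg <- sweep$config
  meta <- list(
    package = "ntcpsim",
    version = as.character(utils::packageVersion("ntcpsim")),
    r_version = R.version.string,
    config = list(gamma_grid = cfg$gamma_grid, D50 = cfg$D50,
                  n_iterations = cfg$n_iterations, n_boot = cfg$n_boot,
                  alpha = cfg$alpha, cohort_sizes = cfg$cohort_sizes,
                  master_seed = cfg$master_seed,
                  refit_in_bootstrap = cfg$refit_in_bootstrap,
                  compute_fits = cfg$compute_fits),
    cell_seeds = vapply(sweep$cells, `[[`, integer(1), "cell_seed"))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
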