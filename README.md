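# ntcpsim

Contours used to develop normal tissue complication probability (NTCP)
models are increasingly generated automatically. When two contour sets of
the same organ at risk disagree — manual vs. deep-learning, manual vs.
atlas, or two observers — the dosimetric parameters extracted from them
differ, and so do the toxicity models fitted on those parameters. `ntcpsim`
is a Monte Carlo framework for quantifying that effect: it answers *how
often would the model built from the "true" contours be statistically
better than the model built from the alternative contours*, as a function
of the steepness of the dose–response, the dosimetric parameter used, and
the cohort size.

It is intended for radiotherapy outcome modellers and for developers of
auto-contouring algorithms who want to know whether their contours are
accurate enough for NTCP model development.

## The method

The dose–response is the logistic NTCP model

```
NTCP(D) = 1 / (1 + exp(s (D50 − D))),    s = 4 γ / D50,
```

where `D` is a per-patient dosimetric parameter (e.g. mean heart dose or a
VxGy), `D50` the value at 50 % complication probability, and `γ` the
normalized slope of the curve at `D50` (`γ = D50 · dNTCP/dD` there). The
cohort's ground-truth parameter is normalized to mean 1 and the same factor
is applied to the alternative set, so the predefined model uses `D50 = 1`.

Each Monte Carlo iteration then:

1. subsamples the cohort (optionally) without replacement;
2. computes each patient's NTCP from the **ground-truth** parameter under a
   predefined `(D50, γ)` and converts it to a binary outcome by one
   Bernoulli draw per patient;
3. fits one logistic NTCP model by maximum likelihood on the ground-truth
   parameters and one on the alternative parameters, against the *same*
   outcomes;
4. compares the two models' AUCs with a paired bootstrap (100 draws,
   α = 5 %): a model is significantly better in that iteration when its
   AUC is higher in over 95 % of the draws.

Aggregating thousands of iterations gives the fraction of cohorts in which
the ground-truth model is significantly superior, plus the mean ± SD of the
pairwise AUC difference and of the event rate. A Gaussian-copula synthetic
cohort generator (right-skewed marginal, controllable Spearman correlation
between the two contour sets' parameters) provides inputs when no real
paired cohort is at hand, and a contour-metrics module computes the
quantities that feed the pipeline from voxel data: Dice, surface Dice at a
physical tolerance, mean dose, and VxGy.

## Worked example

```r
library(ntcpsim)

# paired synthetic cohort: 605 patients, Spearman 0.9 between contour sets
cohort <- normalize_cohort(generate_cohort(605, rank_correlation = 0.9, seed = 1))

# predefined dose-response: D50 at the cohort mean, normalized slope 1
truth <- ntcp_params(D50 = 1, gamma = 1)

# one Monte Carlo iteration by hand
set.seed(42)
y <- simulate_outcomes(ntcp(cohort$D_gt, truth))$labels
fit_ntcp(cohort$D_gt, y)
#> Logistic NTCP model fit (maximum likelihood)
#>   n = 605 patients, 253 events
#>   D50 = 1.003, gamma = 1.173 (s = 4.676)
#>   logLik = -231.8, AUC = 0.9012
bootstrap_compare(cohort$D_gt, cohort$D_alt, y)
#> Paired bootstrap AUC comparison
#>   AUC (ground truth) = 0.9012, AUC (alternative) = 0.8501, diff = +0.05101
#>   ground truth higher in 100% of 100 draws (alpha = 0.05)
#>   ground truth significantly better
```

The fitted `(D50, γ)` land near the generating values (1, 1); with a
Spearman correlation of only 0.9 between the two contour sets and a steep
slope, the ground-truth model wins this iteration outright.

The engine repeats this over a grid:

```r
cfg <- simulation_config(gamma_grid = c(0.5, 1), n_iterations = 300, master_seed = 1)
sweep <- run_sweep(cohort, cfg)
sweep$summary[, c("gamma", "fraction_significant_gt_better",
                  "mean_auc_diff", "sd_auc_diff", "mean_event_pct")]
#>   gamma fraction_significant_gt_better mean_auc_diff sd_auc_diff mean_event_pct
#> 1   0.5                          0.717        0.0250     0.01057           47.2
#> 2   1.0                          0.987        0.0391     0.00887           42.9
```

Reading: at `γ = 0.5` the ground-truth model is significantly better in
72 % of simulated cohorts, rising to 99 % at `γ = 1` — steeper
dose–response curves make the same contour differences more consequential.
The mean AUC advantage of the ground-truth model grows with `γ` while the
event rate drifts below 50 % as the right-skewed dose distribution
interacts with the steeper curve. `write_iterations_csv()`,
`write_summary_csv()` and `write_run_meta()` persist a sweep;
`dice()`, `surface_dice()`, `mean_dose()` and `vxgy()` compute the contour
metrics from voxel masks (ASCII NRRD I/O via `read_nrrd()`/`write_nrrd()`).

See `vignettes/ntcp-contour-simulation.Rmd` for the modelling details and
design choices.

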