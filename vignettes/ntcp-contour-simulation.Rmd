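---
title: "Monte Carlo assessment of contouring differences in NTCP modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo assessment of contouring differences in NTCP modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntcpsim)
```

## The problem

Toxicity (NTCP) models map a dosimetric parameter — mean heart dose, the
percentage of an organ receiving at least x Gy, and so on — to the
probability of a complication. The parameter is computed from a contour of
the organ at risk, and contours disagree: between observers, between
protocols, and between automatic contouring algorithms and experts. The
question this package addresses is not "how different are the contours"
but "how much does that difference degrade the toxicity model built on
top of them" — and which factors (dose–response steepness, choice of
parameter, cohort size) govern the degradation.

The device is a designated *ground truth*: one contour set is declared
correct and used to generate outcomes, so that the model fitted on its
parameters is, by construction, the best achievable on that cohort. The
model fitted on the *alternative* set's parameters against the same
outcomes can only do as well or worse, and the gap is attributable solely
to the contour discrepancy plus the irreducible noise of dichotomizing
probabilities into binary events. The estimate is therefore deliberately
optimistic (an upper bound on the impact): in real data the outcome is
never fully explained by one parameter.

## The model

The dose–response is the logistic NTCP curve

$$\mathrm{NTCP}(D) = \frac{1}{1 + e^{s(D_{50} - D)}}, \qquad
  s = \frac{4\gamma}{D_{50}},$$

with $\gamma = D_{50}\,\mathrm{dNTCP}/\mathrm{d}D$ at the midpoint, so
$\mathrm{NTCP}(D_{50}) = 1/2$ and the derivative there is $\gamma/D_{50} =
s/4$. `ntcp()` evaluates the curve through `plogis()`, which branches on
the sign of the exponent; probabilities saturate cleanly instead of
overflowing for $|s(D_{50}-D)|$ far beyond 700.

Dose parameters are treated as dimensionless after normalization:
`normalize_cohort()` divides both contour sets' vectors by the mean of the
*ground-truth* vector, so the ground truth has mean exactly 1 while the
alternative keeps its relative bias (its mean is generally not 1). The
predefined generating model then uses $D_{50} = 1$. The API accepts any
positive $D_{50}$, so unnormalized scales (Gy, %) also work; `γ` is
dimensionless on the normalized scale and per-Gy otherwise, and both
conventions appear in the NTCP literature. For probit-form
(Lyman–Kutcher–Burman) parameters, `gamma_from_lkb_m()` converts the slope
parameter $m$ via $\gamma_{50} = 1/(m\sqrt{2\pi})$ — the relation that
maps $m = 1.21$ to $\gamma = 0.33$.

## One Monte Carlo iteration

1. **Subsample.** When the cell's cohort size is below the full cohort,
   patients are drawn without replacement. Subsampling happens first, then
   outcomes are simulated from the subsample's NTCPs; the reverse order is
   distributionally identical, but fixing one order makes the seed
   hierarchy meaningful.
2. **Simulate outcomes.** One independent Bernoulli draw per patient from
   the predefined model's NTCP of the ground-truth parameter
   (`simulate_outcomes()`). Both models in the iteration see the *same*
   label vector. Draws where all labels coincide are flagged degenerate:
   nothing can be fitted or ranked, so the iteration is recorded invalid
   with a machine-readable reason and excluded from aggregates (the count
   is reported; a run with more than 50 % invalid iterations aborts).
3. **Fit both models.** `fit_ntcp()` maximizes the Bernoulli
   log-likelihood in $(D_{50}, \log\gamma)$ with an analytic gradient
   (L-BFGS-B), multi-started from $D_{50} \in \{\mathrm{median}(D), 1\}$,
   $\gamma \in \{0.25, 1\}$, inside box bounds $D_{50} \in [0.01, 100]
   \cdot \mathrm{median}(D)$ and $\gamma \in [0.01, 50]$. The likelihood
   clips probabilities to $[\varepsilon, 1-\varepsilon]$,
   $\varepsilon = 10^{-12}$ (configurable via `fit_control()`). Under
   complete separation the likelihood is monotone in $\gamma$ and the MLE
   diverges; the fit detects this (in-sample AUC of the dose vector equal
   to 1), reports $\gamma$ at the upper box bound, and sets a `separation`
   diagnostic rather than failing. Ties in the dose vector are permitted;
   nothing is jittered.
4. **Compare.** The models' discrimination is the in-sample AUC, computed
   by midranks (Mann–Whitney; ties count one half). `bootstrap_compare()`
   draws 100 paired resamples of patient indices — the *same* indices
   applied to both dose vectors and the labels — recomputes both AUCs per
   draw, and declares a model significantly better when its AUC is
   strictly higher in more than $(1-\alpha)$ of the draws
   ($\alpha = 0.05$); within-draw ties count as not-higher, and resamples
   with degenerate labels are redrawn and counted.

A deliberate shortcut: the bootstrap does **not** refit $(D_{50},\gamma)$
per draw. The fitted curve is a strictly increasing function of the dose
parameter whenever $\gamma > 0$, and AUC is invariant under strictly
monotone transforms, so the refitted model's in-sample AUC is identical to
the AUC of the raw dose values — refitting per draw changes nothing but the
runtime. This invariance is asserted on every single fit, and
`refit_in_bootstrap = TRUE` (or `refit = TRUE` in `bootstrap_compare()`)
performs the literal refit as a sensitivity check; a unit test confirms
both modes give identical verdicts. The same invariance means that
summaries which only involve AUCs, their bootstrap comparison, or the
event rate are unchanged when the per-iteration fits are skipped
(`compute_fits = FALSE`), which several long-running checks exploit.

AUC here is in-sample — fit and evaluation on the same cohort, with no
train/test split. That mirrors the upper-bound logic above and is an
acknowledged optimism, not an oversight.

## Seeds and reproducibility

`simulation_config(master_seed = …)` roots a deterministic hierarchy:
the master seed and the cell index derive a cell seed, which derives one
seed per iteration (a Lehmer-style integer mix, all arithmetic exact in
doubles, results in $[1, 2^{31}-2]$). Each iteration seeds R's RNG once
and draws in a fixed order — subsample, outcomes, bootstrap — so any
iteration of any cell is bit-exactly reproducible in isolation, cells are
order-independent, and two runs from the same master seed produce
byte-identical `iterations.csv` and `summary.csv`.

## The synthetic cohort generator

No paired clinical cohort ships with the package, so `generate_cohort()`
emulates one. The ground-truth marginal defaults to a lognormal scaled to
mean 1 with coefficient of variation 0.7 — mean-normalized mean-heart-dose
distributions are strongly right-skewed with a heavy upper tail, and a
CV near 0.7 reproduces that shape; it is a documented, configurable
default, not a claim about any real cohort. A `beta100` marginal (scaled
Beta, default shapes 1.5 and 4) serves for VxGy-like bounded percentages.

The alternative vector is coupled through a Gaussian copula: latent
normals with correlation $\rho_z = 2\sin(\pi\rho_s/6)$ hit a target
Spearman $\rho_s$ exactly in expectation; at $\rho_s = 1$ the latent
variable is copied, so ranks agree exactly. Rank correlation (not Pearson)
is the control knob because every performance quantity in the framework is
rank-based. Optional multiplicative/additive bias is applied to the
alternative afterwards, then clipped to the marginal's support (clipping
can create a point mass at the bounds — accepted and documented). The
ground-truth draw itself is never modified by the coupling.

What the generator does *not* emulate: spatially structured, systematic
contouring errors (it couples parameters, not contours), correlations
between different dosimetric parameters of the same patient, and any
cohort-specific distribution. Passing tests on synthetic cohorts
demonstrate the machinery's correctness and the direction and shape of the
trends, not the numerical values any particular clinical dataset would
produce — those depend on its dose distributions.

`generate_phantom_pair()` builds sphere/ellipsoid voxel phantoms with
analytic volumes, overlaps and dose fields (uniform, linear gradient,
Gaussian falloff) as oracles for the metric module.

## Contour metrics

`dice()` is voxel-count overlap. `surface_dice()` represents each mask's
surface by the voxel faces separating foreground from background (grid
edges count as background), takes face *centers* as surface points and
face *areas* as surface amounts, and scores the fraction of total surface
area lying within the tolerance of the other surface, with distances in
physical millimetres respecting anisotropic spacing. Published surface-
agreement definitions leave the surface parameterization open (voxel
faces vs. meshes); voxel faces with face-center distances is this
package's convention, chosen for exactness and testability — with
isotropic spacing it reduces to face counts. Nearest-surface distances are
computed exactly (chunked pairwise), not via an approximate grid distance
transform. A small tolerance slack of $10^{-9}$ mm guards the
exact-coincidence case against floating-point rounding.

`mean_dose()` is the arithmetic mean over foreground voxels (uniform
voxel volume); `vxgy()` uses an *inclusive* threshold ("at least x Gy").
Both grids must share geometry exactly — mismatched grids raise an error
rather than silently resampling. Voxel I/O is ASCII-encoded NRRD with
spacing and origin metadata (`read_nrrd()`/`write_nrrd()`).

## Numerical and design choices, in brief

- Logistic evaluated via `plogis` (sign-branching): stable at any slope.
- Likelihood clipping $\varepsilon = 10^{-12}$; configurable.
- Optimizer: gradient-based L-BFGS-B on $(D_{50}, \log\gamma)$ with
  multi-start; a `(D50, log s)` chart is available and agrees at interior
  optima (tested). `stats::glm()` on the equivalent reparameterization
  (slope $= s$, intercept $= -sD_{50}$) is used in the test suite as an
  independent oracle, never as the implementation.
- Superiority rule: strict count inequality, `> (1 − α) · n_boot`;
  within-draw AUC ties count as not-higher. The rule is evaluated in both
  directions; the headline fraction uses the ground-truth direction.
- Degenerate outcome draws, degenerate bootstrap resamples, failed and
  separated fits each have an explicit, counted handling path.
- Normalization happens once, on the full cohort, before any subsampling;
  subsample means may drift from 1, which is intended.

## Problem sizes in the checks

The test suite exercises the study conditions at desk scale: the
event-rate check runs the full 3000 iterations on a 605-patient cohort at
$\gamma = 0.1$; parameter recovery uses 20 000 patients over 5 seeds
(±0.03 on both parameters); trend checks use 500 iterations per cell at
$\gamma \in \{0.25, 0.75, 1.5\}$ and cohort sizes $\{182, 302, 605\}$;
null-calibration uses 500 iterations with a monotone-transformed
alternative (exactly zero significant iterations, by rank identity).
These sizes were chosen so each statistical assertion has comfortable
Monte Carlo margins (binomial/4-σ bounds are computed inside the tests).

## Limitations

- Univariate models only; multivariable NTCP models are out of scope.
- Logistic link only for fitting (probit/LKB fits behave similarly over
  typical dose ranges and are not implemented; only the slope conversion
  is provided).
- In-sample AUC; no calibration metrics (Brier, calibration slope), no
  DeLong or permutation tests.
- No DICOM parsing or contour-to-mask rasterization; the metrics module
  starts from co-registered voxel masks.
- Synthetic cohorts are stand-ins: conclusions about a specific clinical
  dataset require that dataset's paired dose parameters, supplied via the
  cohort CSV interface.
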