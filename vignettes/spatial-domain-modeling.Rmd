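---
title: "Spatial-domain recurrence modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial-domain recurrence modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(domainsurv)
```

This vignette explains the models implemented in `domainsurv`, the
assumptions behind them, the tunable parameters and their defaults, what
the synthetic-cohort generator does and does not emulate, and the design
choices made where the methodology left room.

## The modeling problem

The input is a table of segmented cells from one ~0.6-mm TMA spot per
patient — centroid coordinates in micrometres, cell area, a per-cell
quality index, E-cadherin positivity, and one log2 intensity per
biomarker — together with recurrence follow-up (time in years, event
indicator) and clinical covariates (age, gender, TNM stage I–III). The
goal is a 5-year recurrence risk score and, secondarily, biomarker
networks that differ between recurrence outcomes.

The central modeling premise is that the tumor microenvironment is
spatially organized: the same biomarker can be hazardous in the
epithelium and protective in the stroma (or vice versa), and signals can
concentrate at the epithelial–stromal interface. Pooling all cells
averages such signals away, so every analysis step is performed per
spatial domain.

## Quality control and normalization

* Cells are kept when area is **strictly greater than** 10 px (at x20)
  and quality index is **at least** 0.9 — note the deliberate asymmetry,
  which the tests pin down. Both cuts are configurable
  (`min_cell_size_px`, `min_quality`).
* Intensities are expected in log2; `raw_intensities = TRUE` applies
  `log2(x + 1)` once (re-application is an error, guarded by a flag).
* Slide-to-slide variability is removed by an additive per-biomarker
  shift on the log2 scale equalizing every slide's median to the grand
  median. We define the grand median as the median of the per-slide
  medians; this makes the post-condition exact (all slide medians equal
  to machine precision). An additive log-scale shift is multiplicative
  on the raw scale and preserves within-slide ranks, so all Kendall
  correlations are invariant to it — a property the test suite asserts.
  Whether median normalization should be global or per biomarker is not
  dictated by the protocol; per biomarker was chosen as the variant that
  actually removes channel-specific slide effects.
* Common-exposure adjustment is assumed done upstream; exposure metadata
  is not part of the data model.

## Virtual dissection

Compartments come from E-cadherin: positive cells are epithelial,
everything else stromal (a precomputed `compartment` column is passed
through). The boundary domain is built in three steps: a square lattice
of circle centers (diameter 50 µm, spacing `diameter/10` = 5 µm by
default) covering the spot's bounding box; retention of circles holding
at least one epithelial *and* one stromal centroid; and the union of the
retained circles. Cells whose centroids fall in the union form the
epithelial–stromal domain. The epithelial and stromal domains *keep*
their band cells — the band overlaps both compartments.

For a straight interface and dense cells this construction converges to
a band of twice the circle diameter (100 µm): circles reach up to one
radius from the interface on either side, and each retained circle
extends one further radius. `band_width()` therefore measures the union
extent; at the default 5 µm spacing the measured width on a 2 µm cell
grid is 95 µm — one lattice step of discretization below the limit,
because the outermost lattice column whose circle would just graze the
far compartment misses it by less than one spacing step.

Choices made where the construction was open: a regular square lattice
anchored at the bounding-box minimum (a data-driven placement would make
the band seed-dependent); centroid-in-disc membership (cell extent is
not in the data model); continuous µm coordinates.

## Feature engineering

Per biomarker and spot, expression is defined conservatively as
intensity strictly above the nearest-rank 85th percentile of that
marker's distribution over the whole spot (`percentile_threshold`). The
spot — not the domain — anchors the threshold; domains inherit it. Per
domain the feature vector is:

* `mean__<m>`: mean intensity over the domain's expressing cells
  (missing if none),
* `tau__<m1>__<m2>`: Kendall τ-b over the domain cells expressing both
  markers (missing when fewer than 3 co-express).

For a panel of P markers this gives P + P(P−1)/2 features — 1540 at
P = 55. τ-b (tie-corrected, via `stats::cor`) is used because
thresholded data can tie; rank correlation is robust to monotone
distortions of intensity, which the tests assert directly. Whether mean
features should average all cells or only expressing cells is slightly
ambiguous in the source protocol; expressing-only was chosen for
consistency with the thresholding rationale, and the threshold vector
can be supplied explicitly to compute either variant.

Penalized regression needs complete columns: features missing in more
than 20% of patients are dropped, the rest median-imputed
(`missing_max_frac`). Note an important interaction discovered while
validating the generator: a strong *negative* domain shift of a marker
pushes its cells below the spot threshold, so extreme planted effects
convert signal into missingness. Effect sizes in the bundled test
cohorts are chosen below that regime.

## The two-step penalized Cox model

Per domain, with the Breslow form of the partial likelihood (which is
exactly the likelihood as printed — no tie correction):

1. **Selection.** LASSO Cox (α = 1) with λ chosen by 10-fold
   cross-validated partial-likelihood deviance. Stability: the chosen λ
   is held fixed and the LASSO is refit on stratified bootstrap
   resamples (sampling with replacement within recurrence-year strata);
   features selected in ≥ 90% of refits survive. Running a full CV
   inside each of the 500 bootstraps would multiply the cost ~20-fold
   for the same estimand; fixing λ is the standard stability-selection
   formulation. "Consistently concordant at the 90% level" is read as
   selection frequency ≥ 0.9 — the alternative reading (a per-feature
   concordance index ≥ 0.9) is implausible for single features.
2. **Sign stability.** The surviving features are refit with ridge
   (α = 0) Cox on the same resampling scheme; features whose coefficient
   sign matches the full-data ridge refit in ≥ 90% of resamples are
   kept.
3. **Estimation.** A final ridge refit on the surviving features only.
   This decouples coefficient learning from the original 1540-feature
   space: the tests assert that deleting never-selected columns leaves
   the final coefficients unchanged.

Features are standardized to zero mean and unit variance before
penalization so that mean-intensity and correlation features face a
comparable penalty; coefficients are reported on the standardized scale
with the transform stored. The two screens use independent bootstrap
streams (whether the original used shared resamples is unstated).
Degenerate strata (a recurrence year with fewer than 2 patients) are
merged with the adjacent year. An empty final feature set yields a
degenerate model with risk ≡ 1, by design.

The overall score multiplies the domain hazard ratios:
`exp(Σ_s f_sᵀβ_s)`. Comparison baselines: the *null* model applies the
identical pipeline to the undissected spot's features; the *intensity*
model to the spot's mean-intensity features only; the *clinical* model
is an unpenalized Cox fit on age, gender, and stage; "+ clinical"
variants concatenate a model's risk score with the clinical covariates
in an unpenalized Cox fit.

## Evaluation harness

Train/test pairs are generated by stratified ~50/50 splits: strata are
recurrence-by-year (years 1..5) plus "no recurrence by horizon", so
every yearly risk set stays populated on both sides — a form of risk-set
sampling. (The splits could alternatively be out-of-bag bootstrap
resamples; 50/50 splits were chosen and the fraction is a parameter.)

The binary 5-year outcome masks patients censored before the horizon
without an event; they still contribute to Cox fitting, Kaplan–Meier
curves, and the IPCW time-dependent AUC, so no information is discarded
overall. The ROC is the empirical curve over all observed thresholds;
AUC is computed as the Mann–Whitney concordance (ties half-weighted),
which equals the area under the empirical curve and is what the
brute-force pair oracle checks. The operating point maximizes Youden's
J with ties broken toward higher specificity; LR+ = sens/(1−spec) and
LR− = (1−sens)/spec follow. Time-dependent AUC uses cumulative cases /
dynamic controls with inverse-probability-of-censoring weights from the
Kaplan–Meier censoring estimator, on a yearly grid t = 1..5.

Inside the comparison harness the per-split fits default to the fast
mode (`n_bootstraps = 0`: plain CV-LASSO selection + ridge refit);
the stability screens are switchable back on through the config. The
harness emits the per-split AUC table; any post-hoc test between models
can be run on it externally.

## Spatial-domain networks

Per patient and domain, the Kendall correlation matrix over the
model-selected biomarkers (pairs without enough co-expressing cells are
set to 0) is shrunk toward the identity, `C ← (1−δ)C + δI`, with the
smallest δ on a 0.01 grid giving a minimum eigenvalue ≥ 1e−6, then
inverted; partial correlations are ρ_ij = −P_ij/√(P_ii P_jj). The
rank-correlation matrix is deliberately fed to the Gaussian
partial-correlation formula as-is (no sine transform to a Pearson
equivalent) — faithful to the method being implemented. Per pair, the
per-patient ρ values of the two outcome groups are binned into 40
equal-width histograms on [−1, 1] (with a 1e−12 pseudocount so empty
bins are harmless); the Jensen–Shannon divergence (base 2, bounded by 1
bit) between them is the information distance. The distance matrix is
thresholded at the nearest-rank 99th percentile of its upper triangle,
strict inequality, so with ties no edge passes; isolated nodes are kept
— the network may be a set of disconnected subnetworks. Bin count and
percentile are config knobs; 40 bins resolves a 30-patient group without
making most bins empty.

Per-patient partial correlations demand reasonably dense spots: with the
85th-percentile threshold, a pair's τ is computed from roughly
(0.15·n)²/n cells, so spots of a few hundred cells yield very noisy
matrices, large shrinkage, and unstable partials. The network tests use
2000-cell compartments for this reason.

## The synthetic-cohort generator

`generate_cohort()` emulates: a circular spot (600 µm) with a central
epithelial blob (radius 180 µm) and stromal annulus; log2 intensities =
baseline (6) + per-patient shift (sd 0.3) + compartment-specific latent
factors (3 per compartment, loading sd 0.3) + cell noise (sd 1); ~5% of
cells drawn to fail QC; and recurrence from a proportional-hazards model
whose linear predictor is a weighted sum of per-patient standard-normal
drivers of the planted features, with exponential baseline hazard
calibrated by root finding so the expected within-horizon recurrence
fraction hits the target (65/432 by default), and uniform censoring on
(0, 1.5 × horizon), event times quantized to days. Planted `mean__`
features shift their marker in their domain by `mean_effect_sd` per
driver SD; planted `tau__` features modulate a shared factor for the
pair. Rows of the planted table may share a driver with opposite
cell-level effects, emulating a marker that redistributes between
compartments — the spot-level feature then cancels while the domain
features carry signal.

What it does *not* emulate: cell morphology, spatial intensity gradients
within a compartment, marker-specific dynamic ranges, segmentation
errors, or inter-marker biology beyond the factor structure. Passing
tests on this generator therefore demonstrate that the pipeline recovers
the statistical structure it assumes — not that real tissue satisfies
those assumptions.

Two deliberate simplifications in test fixtures: the model-recovery
suite generates cohorts directly at the feature level
(`simulate_feature_cohort()`), because per-SD hazard ratios on τ
features cannot be planted exactly through the cell-level route; and the
study-shaped preset (`make_paper_scale_fixture()`: 432 patients, 65
recurrences) enforces its exact counts by rank-assigning the 65 smallest
latent event times to recurrence over an even grid on (0, 5], rather
than meeting the counts only in expectation.

Problem sizes used by the test suite were chosen to exercise each claim
at the smallest scale where its effect is clearly resolved: feature
recovery at n = 400 patients with 100-bootstrap screens over three
cohorts; the spatial-vs-undissected comparison at n = 200 over 50
splits; network detection with 30 patients per group over 20 seeds.

## Known limitations

* The spot-anchored expression threshold couples domains: a strong shift
  in one compartment moves the threshold and hence the other
  compartment's features. This is inherent to the method, and it is why
  antagonistic same-marker effects are hard to learn from small cohorts.
* Breslow tie handling only; no Efron correction, no elastic-net
  intermediate α, no time-varying covariates.
* The proportional-hazards assumption is not gated; a standard
  Schoenfeld-type residual check from `survival::cox.zph` can be applied
  to the final ridge refit by the user.
* GraphML export stores edge weights only; richer node metadata is left
  to downstream tools.
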