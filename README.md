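# domainsurv

Spatial-domain survival analytics for hyperplexed immunofluorescence
tissue microarrays (TMAs).

Resected early-stage colorectal tumors recur in a substantial minority of
patients, and deciding who needs adjuvant therapy from a single 0.6-mm TMA
core is hard: biomarker signals that predict recurrence can point in
*opposite* directions in the tumor epithelium, the surrounding stroma, and
the interface between them, so models built on the undissected tissue
average them away. `domainsurv` implements a spatially informed modeling
pipeline for per-cell segmented imaging data (tens of biomarker channels
per cell) that:

1. **QC / normalization** — keeps cells with area > 10 px (at x20) and
   quality index ≥ 0.9, log2-transforms raw intensities, and equalizes
   per-biomarker slide medians.
2. **Virtual dissection** — labels cells epithelial/stromal by E-cadherin,
   then builds the epithelial–stromal boundary domain by tessellating each
   spot with partially overlapping 50 µm circles, keeping circles that
   contain both E-cadherin-positive and -negative cells; their union is a
   ~100 µm band around the interface.
3. **Feature engineering** — per domain, a length-`M = P + P(P−1)/2`
   feature vector (1540 for a 55-marker panel): thresholded mean
   intensities (only cells above the spot-level 85th-percentile intensity
   of each marker count as expressing it) and tie-corrected Kendall
   rank correlations (τ-b) for every biomarker pair over co-expressing
   cells.
4. **Prognostic model** — per domain, a two-step penalized Cox
   proportional-hazards fit: LASSO (α = 1) feature selection under the
   partial likelihood

   L(β) = ∏ₖ exp(f_{i_k}ᵀβ) / Σ_{i∈R_k} exp(f_iᵀβ),
   P_{λ,α}(β) = Σ_m λ(α|β_m| + ½(1−α)β_m²),

   stabilized over bootstrap resamples (features kept when selected in
   ≥ 90% of 500 stratified bootstraps, and when their ridge coefficient
   sign is stable in ≥ 90%), followed by a ridge (α = 0) refit on the
   surviving features only. The overall risk score is the product of the
   three domain hazard ratios, ∏_s exp(f_sᵀβ_s).
5. **Evaluation** — stratified train/test splits that preserve the
   per-year recurrence proportions, binary 5-year ROC/AUC, the Youden
   operating point with likelihood ratios, Kaplan–Meier risk
   stratification, IPCW time-dependent AUC, and a six-model comparison
   harness (clinical, intensity, undissected "null", spatial, and their
   +clinical combinations).
6. **Network inference** — per patient, a shrinkage-stabilized Kendall
   correlation matrix over the model-selected biomarkers is inverted to
   partial correlations ρ_ij = −p_ij/√(p_ii p_jj); per biomarker pair, the
   Jensen–Shannon divergence (bits) between the recurrence and
   no-recurrence groups' ρ distributions forms an information-distance
   matrix, thresholded at the 99th percentile into a spatial-domain
   network.

Because cohorts of this kind are not publicly available, the package
includes a first-class synthetic-cohort generator (`generate_cohort()`)
that emulates the data's structure — spatially arranged compartments,
latent-factor-driven log2 intensities with domain-specific correlation,
proportional-hazards recurrence with right censoring — with known ground
truth for every planted effect.

## Worked example

```r
library(domainsurv)

# a 40-patient cohort with a protective signal in the interface band
planted <- data.frame(domain = "epi_stromal", feature = "mean__M01",
                      beta = 1.2)
scfg <- synthetic_cohort_config(n_patients = 40, n_markers = 6,
                                n_epithelial = 120, n_stromal = 120,
                                band_halfwidth_um = 25, planted = planted,
                                target_event_frac = 0.4, seed = 9)
cohort <- generate_cohort(scfg, seed = 9)

cfg <- run_config(n_bootstraps = 0, seed = 9)   # fast mode: plain CV-LASSO
res <- run_pipeline(cohort$spots, cohort$surv, cfg, out_dir = "out",
                    n_splits = 3)

res$model
#> <spatial_model> domains:
#>   epithelial: 1 features
#>   stromal: 1 features
#>   epi_stromal: 3 features
round(res$evaluation$roc$auc, 3)
#> [1] 0.772
```

The spatial model found features in the interface band (where the signal
was planted); the in-sample AUC of 0.77 for 5-year recurrence reflects
the planted hazard ratio of e^1.2 per SD against a 40-patient cohort.
`out/` holds per-domain feature matrices, risk scores, the serialized
model, and GraphML networks, each with a JSON sidecar recording the seed
and config hash.

A thin CLI over the same functions lives at `inst/cli/domainsurv.R`
(subcommands `simulate`, `qc`, `dissect`, `features`, `all`).

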