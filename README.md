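# olivesig

Plasma multi-metabolite signatures of olive-oil consumption and their
association with incident cardiometabolic disease.

## What it does

Self-reported olive-oil intake (from food-frequency questionnaires, FFQ) is
noisy; a weighted panel of plasma metabolites selected against reported
intake gives an objective correlate of consumption that can be carried into
aetiological models. `olivesig` implements that workflow end to end for
total, virgin (VOO) and common (COO) olive oil, in the style of a
Mediterranean high-cardiovascular-risk trial population:

* **Preprocessing** — participant exclusion flow (missing FFQ, sex-specific
  energy bounds, ≥ 20% missing metabolites) and metabolite QC (internal
  standards, drugs, > 20% missing) with auditable exclusion logs;
  pooled-plasma-reference ("nearest neighbor") standardization; iterative
  forest imputation; Blom rank-based inverse normal transformation; and
  residual-method energy adjustment.
* **Metabolome-wide screen** — covariate-adjusted per-SD linear associations
  for every metabolite with Benjamini–Hochberg control and volcano plots.
* **Signature derivation** — a coordinate-descent elastic net
  (`(1/2n)‖y − Xβ‖² + λ[α‖β‖₁ + (1−α)/2‖β‖₂²]`, KKT-certified at 1e-6),
  tenfold cross-validated (α, λ) tuning with both the minimum-MSE and
  within-1-SD λ rules, ten disjoint 90/10 train–validation splits,
  **consistency selection** (metabolites nonzero in all ten splits), mean ±
  SD weights, and Pearson validation with Fisher-z intervals at baseline
  and at the 1-year repeat visit.
* **Case-cohort survival** — Barlow weights with the classical time-split
  for subcohort cases, weighted Cox partial likelihood (Breslow ties)
  stratified by intervention group × center with robust cluster variance,
  hazard ratios per 1 SD of the signature across four nested covariate
  models, year-1 mode, and likelihood-ratio / Wald interaction tests.
* **Sensitivity** — PCA of the three signatures' coefficients (zero-filled,
  centered/scaled, fixed sign convention) and 3×3 score-by-intake
  specificity correlations.
* **Synthetic cohort** — a generator with planted sparse metabolite signals
  (population R² exactly as configured), block-correlated panels, a
  correlated year-1 visit, study-like intake tertile means (~22/40/56 g/day
  total olive oil), survival outcomes, simple-random case-cohort sampling
  and presets that force the study's printed case/subcohort/overlap counts
  (251/694/53 for T2D, 229/788/37 for CVD).

Everything is tibble-in/tibble-out with `tidy()`, `glance()` and
`autoplot()` methods for the fitted objects.

## Worked example

```r
library(olivesig)

cfg <- sim_config(seed = 7)          # 1800 participants x 381 metabolites,
sim <- generate_cohort(cfg)          # 40 active metabolites, planted R² 0.16
base <- dplyr::filter(sim$cohort, visit == "baseline")

met  <- blom_transform(dplyr::filter(sim$metabolites, visit == "baseline"))
oo   <- energy_adjust_residual(base$intake_total_oo, base$energy)

sig <- derive_signature(met, oo, alpha = 0.4, exposure_name = "total_oo",
                        seed = 7)
glance(sig)
#> # A tibble: 1 x 9
#>   exposure alpha n_selected n_positive n_negative r_discovery ci_lower ci_upper     n
#>   <chr>    <dbl>      <int>      <int>      <int>       <dbl>    <dbl>    <dbl> <int>
#> 1 total_oo   0.4         49         26         23       0.313    0.271    0.354  1800
```

The signature keeps 49 metabolites that were selected in all ten
cross-validation splits; its pooled out-of-split correlation with
energy-adjusted intake is 0.31 (95% CI 0.27–0.35) — below the ceiling
`sqrt(0.16) = 0.40` implied by the planted signal by the estimation loss
paid at 40 weak scattered signals (see the methods vignette for why this
gap is irreducible at this SNR). Relating the score to simulated incident
disease:

```r
score <- apply_signature(sig, met)
out   <- generate_outcomes(base, score, cfg, outcome_name = "CVD")
des   <- case_cohort_preset(out, "PREDIMED-CVD", seed = 7)
fit   <- fit_case_cohort_cox(des, score, base, model_spec(1), outcome = "CVD")
fit
#> <oo_cch_fit> CVD model 1: HR/SD 0.705 (0.586, 0.847), p = 0.00019, 229 cases / 980 participants
```

The generator planted a true hazard ratio of 0.79 per SD
(`cfg$log_hr_per_sd = log(0.79)`); the Barlow-weighted fit on 229 cases
plus a 788-member subcohort recovers it within sampling error (robust SE
≈ 0.09 on the log scale; the forced-count preset also carries a small
design artifact discussed in the methods vignette).

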