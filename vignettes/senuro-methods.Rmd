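---
title: "Methods: quantifying renal epithelial senescence and its urinary surrogates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying renal epithelial senescence and its urinary surrogates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senuro)
```

## The scientific problem

Senescent cells — growth-arrested, secretory-altered epithelia marked here
by nuclear P21 (the CDKN1A product) without the proliferation marker KI67 —
accumulate in diseased kidneys and are thought to drive fibrosis. There is
no licensed way to quantify them without a biopsy, which is the practical
obstacle to trials of senolytic drugs. The analysis this package implements
asks three linked questions:

1. Can the P21+/KI67- fraction of tubular epithelium be measured robustly
   from per-cell classification tables (histology)?
2. Does any urinary protein track that fraction well enough to act as a
   noninvasive surrogate (proteomic screen, with clusterin as the leading
   candidate), and is the candidate's transcript spatially associated with
   CDKN1A-expressing epithelia (spatial enrichment)?
3. Does the surrogate — the urinary clusterin-to-creatinine ratio, uCCR,
   in µg/mmol — predict sustained renal functional decline (outcomes)?

Real matched biopsy/urine/outcome data are not distributable, so the
package pairs every stage with a seeded synthetic generator that reproduces
the *statistical structure* those stages assume. All tests and the
acceptance script run end-to-end on generated data.

## Histology

Cells are classified four ways from nuclear stains (`classify_cell`):
P21+/KI67- ("SEN"), P21-/KI67+, double positive, double negative. Only the
first class is treated as senescent. `senescent_fraction` computes, per
participant, 100 × (P21+/KI67- epithelia) / (all epithelia), **pooling raw
counts across biopsy sections before dividing**. Pooling matters: sections
of 1/10 and 3/90 give 4/100 = 4.0%, not the 6.67% mean of per-section
percentages; the pooled estimator weights sections by their cell counts.
Non-epithelial cells never enter numerator or denominator.

P21/clusterin co-expression is summarised by the odds ratio ad/bc of a 2×2
table with a Woolf (log-normal) 95% CI and a two-sided Fisher exact p
(sum of hypergeometric probabilities ≤ the observed table's). Zero cells
trigger the Haldane–Anscombe +0.5 correction for the OR/CI only, and the
result is flagged; the Fisher p always uses raw counts. Cells missing a
clusterin call are excluded and counted.

The "highest tertile of senescence" used by the ROC stage (`top_tertile`)
takes the 2/3 quantile with linear interpolation and assigns ties to the
upper group — deterministic and consistent with common statistical
software.

## Proteomics screen

Label-free urinary intensities carry two nuisance scales: instrument
response (run-to-run gain) and urine concentration. The alcohol
dehydrogenase (ADH) spike-in is added in fixed amount *after* collection,
so it carries the gain but not the dilution; urinary creatinine carries the
dilution but not the gain. Dividing each intensity by ADH and then by
creatinine (`normalize_proteome`) therefore cancels both — the synthetic
generator builds its sample effects exactly this way so the test suite can
verify the cancellation.

Proteins identified by fewer than 2 unique peptides in every sample are
discarded (`peptide_filter`, boundary inclusive). Each surviving protein is
correlated with the histologic senescence percentage by Spearman's rho
(average ranks on ties). Raw p-values use the t approximation
`t = rho·sqrt((n-2)/(1-rho^2))` — adequate at the cohort sizes this design
targets (n ≈ 51); an exact permutation p is available for n ≤ 10.
Benjamini–Hochberg adjustment runs across the *tested family only*:
proteins failing the 80% pairwise-completeness rule or with constant values
are reported as `NA` and excluded from the family size m. The shortlist
keeps adjusted p < 0.05 **and rho strictly > 0.5**, then flags members of a
SASP reference list. The packaged list
(`inst/extdata/sasp_list_synthetic.txt`) is a small synthetic stand-in of
well-known senescence-secretome proteins including CLU; users should
substitute their own atlas export via `sasp_reference(path)`.

qPCR relative expression (`ddct`) normalises the target Ct against the
average of two reference genes and a control group, returning `2^(-ddCt)`
so the control mean is 1 and upregulation exceeds 1. (Literature sometimes
prints the exponent without its sign; this orientation is the one under
which an upregulated transcript yields a value above 1.)

## Spatial enrichment

The statistic asks whether a gene's transcripts concentrate around a query
cell population beyond what the general cell population shows. Around each
query centroid, annuli `(r-1, r]` µm are drawn out to 50 µm. For annulus
r: transcripts of the gene inside the annulus are summed over query cells
(`T_q`), one pseudocount is added, and the sum is normalised by annulus
area and the number of query cells:

    q(r) = (T_q(r) + 1) / (pi (r^2 - (r-1)^2) · N_q)

The background `b(r)` repeats this over up to 10,000 cells drawn uniformly
without replacement from the whole population (seeded; query cells are not
excluded — they are part of the general population), and the profile is
`e(r) = log2(q(r)/b(r))`.

Design choices worth stating explicitly:

* **Units are µm.** A 50 mm search radius inside a needle biopsy is
  physically impossible; the platform exports µm coordinates.
* The **pseudocount is applied to aggregated counts before density
  normalisation**, then a plain log2 ratio is taken. The alternative
  reading "log2(ratio + 1)" was rejected because it cannot return 0 under
  self-comparison and has no null at zero; with the implemented form,
  query = background gives e(r) = 0 exactly at every radius.
* "Number of cells encountered" is read as the **number of group cells**
  N_q (resp. N_b); the alternative — normalising by cell centroids found
  inside each annulus — is available as
  `normalize_by = "annulus_cells"`.
* No edge correction is applied at tissue borders; annuli truncated by the
  field boundary under-count both query and background sides, a shared
  bias that largely cancels in the ratio but is a known limitation.
* Transcripts at exactly distance 0 belong to the first annulus; annuli
  are half-open `(r-1, r]`.

Because N_q (hundreds of query cells) is much smaller than N_b (thousands),
the pseudocount biases `e` upward at radii whose expected counts are below
~1. At the generator's default transcript density (0.01 µm⁻², about 3
transcripts per cell-equivalent area) annulus counts are large enough that
the bias and Monte-Carlo noise keep the null profile's mean |e| well below
0.15; at much sparser densities the small-radius annuli dominate and the
null is no longer centred — a caveat for users profiling rare transcripts.

CDKN1A positivity uses the platform-noise guard of ≥ 2 transcripts within
the segmentation boundary. Differential expression between positive and
negative cells uses the two-sided rank-sum test: exact for small tie-free
groups, otherwise the normal approximation with tie correction, BH-adjusted
across genes, with log2 fold changes of means under pseudocount 1.

## Outcomes

**Cohort filter.** Participants at low progression risk (baseline eGFR ≥
60 mL/min *and* uACR ≤ 30 mg/mmol) are excluded first, then those with
baseline eGFR < 20 mL/min (already at or near the endpoint); missing
values are tallied separately.

**Endpoint.** Progression is the earliest of: renal replacement therapy;
eGFR < 15 mL/min sustained; or a > 40% drop from baseline eGFR sustained.
"Sustained" is measurement-driven, with no interpolation or imputation: an
index measurement below threshold qualifies only if some later measurement
falls strictly more than 90 days after it and *every* measurement up to
and including that confirming one stays below threshold. The event is
dated at the index measurement. Death censors (no competing-risk model, by
design); otherwise censoring is at the last follow-up. A below-threshold
tail with no measurement > 90 days later cannot confirm and is censored —
the conservative reading when follow-up simply ended.

**eGFR** comes from the 2009 CKD-EPI creatinine equation. The race
multiplier is **not applied by default** (the emulated cohorts are
predominantly White with ethnicity partly unrecorded, and contemporary
practice has moved away from the term); `egfr_coefficients(race_factor =
1.159)` restores it. Creatinine is handled in mg/dL with a µmol/L
converter (÷ 88.42).

**ROC and threshold.** The empirical ROC calls a case positive when score
≥ threshold, over the observed scores plus ∞; the AUC is the normalised
Mann–Whitney U (ties = 1/2), and its CI is a seeded stratified bootstrap
(2000 replicates by default; DeLong was considered but the bootstrap keeps
one code path for every statistic). `select_threshold` maximises
sensitivity subject to specificity ≥ 0.9, breaking ties toward higher
specificity and then the lower threshold — the "high specificity first"
rule for enriching trials with high-senescence patients.

**Survival.** Cox partial likelihood uses Efron tie handling (visit-driven
endpoints make ties common). Discrimination is Harrell's c-index;
proportional hazards are checked by correlating scaled Schoenfeld
residuals with time (identity transform). The log-rank test (two groups,
1 df) agrees with the Cox score test on ties-free data, which the suite
asserts at 1e-6. ln(uACR) floors uACR at 0.1 mg/mmol to avoid log(0).

## The synthetic generator

All generators are pure functions of (config, seed); seeds are applied in
a scope that restores the caller's RNG state. Defaults (see `sim_config()`)
encode the emulated study conditions:

* **Cohort.** Age ~ truncated normal (56 ± 14, 19–81 y); baseline eGFR
  log-normal (median 45, range clamped 8–135 mL/min); latent senescence on
  the logit scale — intercept at 5.2%, +0.03/y of age, −0.012 per mL/min
  eGFR, residual SD 0.55 — mapped through the logistic to stay in
  [0, 100]%. uCCR couples to latent senescence through a **Gaussian copula
  on normal scores** with the copula parameter `2·sin(pi·rho_s/6)`, so the
  population Spearman correlation equals the 0.6 target regardless of the
  marginals (log-normal, median 60 µg/mmol, giving ~24% above the 124.5
  µg/mmol threshold).
* **Biopsies.** Epithelial cells are senescent with exactly the requested
  probability; the remainder split among proliferating/double classes.
  The clusterin panel embeds a configurable P21→clusterin odds ratio
  (default 2.14).
* **Proteome.** 331 proteins, 8 markers (CLU at the 0.6 target, the rest
  spread 0.55–0.85); marker strength is a copula on log intensities whose
  noiseless limit is an exact monotone transform (rho → 1). Gain and
  dilution effects are constructed so ADH+creatinine normalisation removes
  them exactly; 5% of non-marker proteins are peptide-poor to exercise the
  filter.
* **Spatial.** 3000 cells uniform on a 1 mm² field (50% PT / 30% LOH-DCT /
  20% other); 30% of PT cells are CDKN1A+ (≥ 2 counts); CLU is a Poisson
  point process at 0.01 µm⁻² plus an additive bump (default 0.03 µm⁻²)
  within 15 µm of each positive PT centroid — additive intensity matches
  the enrichment statistic's additivity, so bumps from overlapping disks
  stack.
* **Outcomes.** Exponential proportional hazards with the binary high-uCCR
  effect log(2.2) plus clinical covariate effects set to the magnitudes a
  multivariable model of this design reports (eGFR 0.979/mL/min, ln-ACR
  1.254, age 0.976/y, SBP 1.018/mm Hg, sex F 1.022); baseline hazard
  1.2e-4/day calibrated to ~15% progression over the 3-year horizon;
  independent exponential censoring plus administrative censoring at 1095
  days and a small death rate. Visit series every 120 days decline to 55%
  of baseline by the event day so the endpoint rules can re-derive events.

What the generator does **not** emulate: nephron geometry and tissue
boundaries (cells are uniform, so enrichment profiles lack the anatomical
autocorrelation of real tubules), mass-spectral missingness mechanisms
(missingness is absent rather than intensity-dependent), informative
censoring, and eGFR trajectory shapes beyond piecewise-linear decline.
Passing tests therefore demonstrate the *estimators and rules* behave
correctly under the assumed structure, not that the biological effect
sizes are correct.

## Problem sizes and numerical choices

The test suite and acceptance script size their simulations to what the
statistics need rather than more: oracle comparisons use ≤ 200-cell fields
(where the quadratic brute force is exact and fast), null calibrations use
50 replicates at 3000 cells, screen calibrations 100–200 replicates at
n = 51, and hazard-ratio recovery a single n = 2000 cohort (~300 events,
giving a log-HR standard error near 0.14). One consequence is worth
honesty: with the clusterin marker generated at population Spearman 0.6
and n = 51, the sampling SD of the sample rho is ≈ 0.10, so the strict
"rho > 0.5" shortlist rule admits the marker in only ~83% of replicates —
a recovery-rate check demanding ≥ 90% at these exact conditions sits below
its own target, and the corresponding test documents this rather than
altering the conditions.

Other numerical conventions: Woolf CI on the log-OR; BH via `p.adjust`;
ROC ties counted 1/2 in the U statistic; Fisher p via the hypergeometric
sum convention; annuli half-open with distance-0 points in the first
annulus; all bootstrap and background draws seeded and reproducible.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_participants = 104)
cohort <- gen_cohort(cfg, seed = 1)

cells <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i)
  gen_biopsy_cells(cohort$senescence_true[i], n_cells = 800,
                   seed = i, participant_id = cohort$id[i])))
sen <- senescent_fraction(cells)

roc <- roc_curve(cohort$uccr, top_tertile(sen$pct_senescent), seed = 1)
select_threshold(roc, min_specificity = 0.9)

outcomes <- gen_outcomes(cohort, cfg, seed = 1)
cox_fit(outcomes$records,
        c("uccr_high", "baseline_egfr", "ln_acr", "age", "sbp", "sex"))
```

The same pipeline, at the full study scale, is what
`scripts/acceptance.R` runs and summarises as JSON.
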