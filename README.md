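# senuro

Quantifying renal epithelial senescence and its urinary surrogates.

Senescent tubular epithelia — nuclear P21 (CDKN1A) positive, KI67 negative
— accumulate in chronic kidney disease (CKD) and are implicated in
fibrosis, but measuring them requires a biopsy. `senuro` implements the
full analysis chain of a biomarker study that replaces the biopsy readout
with a urinary surrogate, the urinary clusterin-to-creatinine ratio
(uCCR, µg/mmol):

* **Histology** — the senescent fraction per participant,
  `100 · n(P21+KI67− epithelia) / n(epithelia)`, with biopsy-section
  counts pooled before division; P21/clusterin co-expression odds ratios
  (`ad/bc`, Woolf CI, Fisher exact p).
* **Proteomics screen** — ADH-spike-in then creatinine normalisation of
  urinary LC-MS/MS intensities, a ≥ 2 unique-peptide filter, Spearman
  correlation of each protein against tissue senescence with
  Benjamini–Hochberg FDR control, and a shortlist rule (adjusted p < 0.05,
  ρ > 0.5, SASP-list flag). qPCR relative expression by 2^(−ΔΔCt).
* **Spatial enrichment** — for subcellular-resolution spatial
  transcriptomics: the log2 ratio of annulus-normalised transcript density
  around a query cell population (e.g. CDKN1A+ proximal tubule cells,
  positivity at ≥ 2 transcripts) over a seeded random-cell background,
  `e(r) = log2[(T_q(r)+1)/(A(r)·N_q) ÷ (T_b(r)+1)/(A(r)·N_b)]`
  in 1 µm annuli to 50 µm; plus rank-sum differential expression.
* **Outcomes** — risk-based cohort filtering, a sustained (> 90 days)
  composite endpoint of ESKD or > 40% eGFR decline from baseline
  (CKD-EPI 2009), empirical ROC with specificity-first threshold
  selection, Kaplan–Meier/log-rank, and Cox proportional hazards (Efron
  ties) with Harrell's c-index and Schoenfeld-residual PH checks.
* **Synthetic data** — seeded generators producing matched cohorts,
  biopsy cell tables, proteome panels, spatial fields and longitudinal
  outcomes with the statistical structure the analysis assumes, so the
  whole pipeline is testable without access to patient data.

## A worked example

```r
library(senuro)

## biopsy-scale cohort: histology + uCCR
cfg    <- sim_config(n_participants = 104)
cohort <- gen_cohort(cfg, seed = 1)
cells  <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i)
  gen_biopsy_cells(cohort$senescence_true[i], n_cells = 800,
                   seed = i, participant_id = cohort$id[i])))
sen <- senescent_fraction(cells)
median(sen$pct_senescent)
#> [1] 4.788904

roc <- roc_curve(cohort$uccr, top_tertile(sen$pct_senescent), seed = 1)
roc
#> Empirical ROC: 35 positives / 69 negatives, AUC = 0.709 (95% CI 0.605-0.811)

## outcome-scale cohort: survival analysis of high vs low uCCR
big  <- sim_config(n_participants = 2000)   # true HR = 2.2 for high uCCR
coh2 <- gen_cohort(big, seed = 1)
out  <- gen_outcomes(coh2, big, seed = 1)
cox_fit(out$records,
        c("uccr_high", "baseline_egfr", "ln_acr", "age", "sbp", "sex"))
#> Cox proportional hazards (Efron ties)
#>           term    hr          ci        p
#>  uccr_highTRUE 2.251 1.761-2.878 9.20e-11
#>  baseline_egfr 0.982 0.977-0.988 1.91e-10
#>         ln_acr 1.334 1.215-1.464 1.34e-09
#>            age 0.973 0.965-0.981 1.10e-10
#>            sbp 1.017 1.012-1.022 7.53e-10
#>           sexM 0.937 0.745-1.178    0.577
#> Harrell c-index: 0.720
```

The fitted hazard ratio for the high-uCCR indicator (2.25) recovers the
generator's true value of 2.2; the AUC of 0.71 reflects how well uCCR
identifies the top tertile of histologic senescence at this cohort size
and coupling strength (population Spearman 0.6). The median senescent
fraction (~5%) matches the generator's calibration for a secondary-care
CKD population.

See `vignettes/senuro-methods.Rmd` for the model and every numerical
convention (annulus normalisation, pseudocounts, endpoint sustainment
rules, tie handling).

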