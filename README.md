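# proteoconcord

Cross-cohort concordance analysis for label-free (DIA) proteomics.

When two study centres quantify the same tissue panel by mass
spectrometry — say a small discovery cohort of 8 adrenocortical carcinoma
samples and an independent cohort of 58 — the question that decides
whether their findings can be pooled is quantitative: *do the two
protein-group matrices agree, protein by protein, once technical
variation is removed?* `proteoconcord` implements the full analysis path
for that question:

- **Preprocessing** of proteins × samples quantification matrices:
  valid-value filtering (≥ 60% observed in at least one biological group,
  or ≥ 35% in every cohort), log2 transformation, quantile normalization
  (missing-aware, by fractional-rank interpolation of the mean quantile
  curve), iterative low-rank (PCA) imputation, and scalar-per-cohort
  batch centering.
- **Differential expression** with empirical-Bayes moderated
  t-statistics: per-protein variances `s2` are shrunk toward a scaled
  inverse-chi-square prior fitted by trigamma inversion of the
  log-variance moments, giving
  `t = Δ / sqrt(s2_post (1/n1 + 1/n2))` with
  `s2_post = (d0·s0² + df·s2)/(d0 + df)` on `df + d0` degrees of freedom,
  Benjamini-Hochberg FDR control, and signed DEP calls at `q < 0.05`.
- **Concordance scoring** between cohorts: per-protein Bland-Altman
  differences with limits of agreement and standardized Z-scores
  (flagged at `|z| > 1.96`), and the weighted **Global Similarity Index**

  `GSI = 0.25·(r+1)/2 + 0.25·max(0, ICC(2,1)) + 0.20·psim/100 +
  0.15·(1 − pdiff/100) + 0.15·max(0, 1 − |z|/1.96)` ∈ [0, 1],

  with per-protein similarity categories (very high / high / moderate /
  low).
- **Stratified 4-fold cross-validation** of per-protein robustness:
  train-vs-test correlation and relative stability of the cross-cohort
  difference, combined into a composite score and ranking.
- A **synthetic two-cohort generator** with known ground truth (log-normal
  abundances, configurable DEP fraction and effects, cohort batch shift,
  MNAR + MCAR missingness), so the whole pipeline is testable end to end
  without any raw data.

## Worked example

```r
library(proteoconcord)
out <- run_pipeline(demo_config(out_dir = "demo_out", seed = 1))
```

The demo simulates 400 proteins across two cohorts (USP: 5 normal + 8
carcinoma; SNUH: 58 carcinoma), injects abundance-dependent missingness,
and runs every stage. The log reads:

```
simulate: 400 proteins x 71 samples, 7.0% missing
preprocess: 400 -> 395 proteins (each_cohort @ 0.35), 1754 cells imputed
dea NHA_vs_ACC: 10 up, 7 down at FDR 0.05
concord: global GSI 0.9360, mean psim 99.32%
cv: k = 4, median composite 0.0014
```

Reading the numbers: 395 of 400 proteins pass the 35%-per-cohort filter
and 1754 missing cells are imputed; the normal-vs-carcinoma contrast
calls 17 DEPs at FDR 0.05 (the generator planted 5% true effects of
1 log2 unit); the two cohorts score a global GSI of 0.936 — "very high"
for 327 of 395 proteins — with mean percent similarity 99.3% and a
Bland-Altman bias of essentially zero (limits of agreement ±0.34 log2
units, 17 proteins flagged at `|z| > 1.96`, consistent with the 5%
expected under agreement); the low median cross-validation composite is
expected here because after batch centering most simulated proteins have
no true cross-cohort difference left to be stable about. All artifacts
(per-stage TSVs, `summary.json`, the echoed `run_config.yaml`) land in
`demo_out/`; identical config + seed reproduces them byte for byte.

The same stages are available as plain functions
(`read_quant_table()`, `preprocess_pipeline()`, `moderated_de()`,
`compute_gsi()`, `crossval_concordance()`), and
`scripts/run_pipeline.R` wraps `run_pipeline()` for shell use.

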