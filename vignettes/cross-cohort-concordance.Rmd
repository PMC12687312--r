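---
title: "Cross-cohort concordance analysis for label-free proteomics"
author: "proteoconcord authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-cohort concordance analysis for label-free proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoconcord)
```

## The problem

Label-free DIA proteomics produces a wide protein-group matrix: one
inferred abundance per protein per run. When two study centres profile the
same disease — here the motivating setting is adrenocortical neoplasia,
with a small centre (8 carcinoma samples) and a much larger independent
one (58) — the central methodological question is whether the two
quantitative profiles agree well enough to pool conclusions. This package
implements the full path from raw quantification matrices to a
reproducibility verdict: preprocessing, moderated-t differential
expression, a weighted Global Similarity Index (GSI) built on Bland-Altman
agreement statistics, and a stratified cross-validation of per-protein
robustness.

## Preprocessing model and its order

Stages are enforced in the order *filter → log2 → quantile normalization →
PCA imputation → optional cohort centering* by a scale flag carried on the
matrix (`raw` vs `log2`), so a double log2 transform or a normalization of
raw intensities is a hard error.

**Valid-value filters.** Two rules with different roles: `any_group` keeps
a protein observed in at least 60% of the samples of *some* biological
group (the within-study identification filter), and `each_cohort` keeps a
protein observed in at least 35% of the samples of *every* cohort (the
cross-cohort comparability filter). Both fractions are exposed as
parameters; the defaults are the two conventional thresholds above.

**Quantile normalization.** Each sample column is mapped onto the mean
quantile curve. With missing cells, each column's observed values are
ranked and placed at fractional quantile positions
`(rank − 1)/(n_obs − 1)`, and the reference curve — itself the mean of the
per-column interpolated quantile curves — is evaluated there by linear
interpolation. Ties take average ranks and therefore receive the mean of
their spanned reference quantiles. On complete data this reproduces the
classical mean-of-order-statistics construction exactly, and it is
idempotent on complete tie-free matrices.

**Imputation.** Missing values are completed by an iterative low-rank
model: initialize at row means, then alternate a rank-*k* SVD
approximation of the row-centered completed matrix with overwriting of the
missing cells only, until the largest change at a missing cell falls below
`tol` (default 1e-6, at most `max_iter = 500` alternations, warning and
best iterate on non-convergence). `k = 2` by default — enough to capture a
cohort axis and one biology axis without inventing structure. Observed
cells are bit-identical before and after; the imputed-cell set is recorded
on the returned object. The completion is deterministic; an exact rank-1
matrix with a deleted cell is recovered to numerical precision.

**Order of normalization and imputation.** Imputation runs *after*
quantile normalization so that the low-rank model sees
distribution-matched columns; otherwise inter-column intensity offsets
would leak into the imputed values as spurious rank-1 structure.

**Batch centering.** Cross-cohort technical shifts are removed as a single
scalar per cohort (each cohort's grand mean over observed cells is aligned
to the global grand mean). Deliberately *not* per-protein: per-protein
centering would annihilate exactly the per-protein cross-cohort
differences that the concordance analysis measures. The residual shift
after centering is auditable from the output (on simulated data with a
1.5 log2-unit injected shift it is below 0.05).

## Differential expression

Per protein, a two-group linear fit gives the mean log2 difference, the
pooled within-group variance `s2` and `df = n1 + n2 − 2`. Variances are
shrunk toward a scaled inverse-chi-square prior fitted across proteins by
the classical method of moments on log-variances: the centered
log-variances have theoretical excess variance `trigamma(d0/2)`, so the
prior degrees of freedom `d0` come from a monotone trigamma inversion
(Newton with bisection fallback, tolerance 1e-8) and the prior variance
`s0²` from the mean. The moderated statistic
`t = effect / sqrt(s2_post (1/n1 + 1/n2))` with
`s2_post = (d0 s0² + df s2)/(d0 + df)` is referred to a t distribution on
`df + d0` degrees of freedom (standard normal at `d0 = ∞`; ordinary pooled
t at `d0 = 0`). Benjamini-Hochberg adjustment is implemented as the
explicit step-up and a protein is a DEP when `q < 0.05`, signed by its
effect. Degenerate cases are pinned down: all-equal variances give
`d0 = ∞` with `s0²` equal to that common value (so `s2_post = s2`), and a
zero posterior variance yields `t = 0, p = 1` for a zero effect and
`p = 0` with a warning otherwise. The test suite cross-checks the whole
chain against an independent reference implementation of the moderated-t
construction on heteroscedastic data, to 1e-10.

## The Global Similarity Index

The two cohorts are reduced to per-protein mean vectors `mA`, `mB`
(defaults to all samples per cohort; compare within a matched diagnosis
group by subsetting the metadata first). Five components, each normalized
to [0, 1]:

| component | definition | scope | weight |
|---|---|---|---|
| c1 | `(pearson(mA, mB) + 1)/2` | global | 0.25 |
| c2 | `max(0, ICC(2,1))` | global | 0.25 |
| c3 | percent similarity / 100 | per protein | 0.20 |
| c4 | `1 − min(pdiff, 100)/100` | per protein | 0.15 |
| c5 | `max(0, 1 − |z|/1.96)` | per protein | 0.15 |

with `psim = 100 (1 − |d| / pair mean)`, `pdiff = 100 |d| / pair mean`
(`d = mA − mB` on the log2 scale), and `z` the standardized Bland-Altman
residual `(d − mean(d))/sd(d)`. Pearson and ICC are global because a
per-protein correlation across two cohort means is undefined; they are
broadcast to every protein so that per-protein GSI values and categories
remain reportable. The ICC variant is fixed to ICC(2,1) — two-way random
effects, absolute agreement, single rater — because the cohorts act as
two raters of the same proteins and a systematic offset *should* cost
similarity. The affine Pearson map, the ICC floor at zero and the linear Z
penalty vanishing at 1.96 are this package's normalizations (a convention
had to be fixed to place all components on [0, 1]); the weights
25/25/20/15/15 are the standard GSI weighting. Categories: very_high
(≥ 0.90), high (≥ 0.75), moderate (≥ 0.50), low — the cut-offs are this
package's convention for those category names.

Degenerate rule: identical cohort vectors give `sd(d) = 0`, all `z = 0`,
and therefore a self-comparison scores exactly 1 — both a sanity identity
and the acceptance anchor of the package. Percent similarity and percent
difference are computed on post-normalization log2 means by design (the
scale on which every other statistic lives); note that mean percent
similarity and 100×mean GSI are different summaries, and both are
reported.

## Stratified cross-validation

Samples are dealt round-robin to `k = 4` folds after a seeded shuffle
within each (cohort, group) stratum, so fold sizes within a stratum differ
by at most one; a stratum smaller than `k` is refused unless explicitly
allowed. For each fold, the per-protein cross-cohort difference is
estimated on the training ¾ and the held-out ¼. Across folds,
`corr` is the train-test Pearson and
`stability = 1 − sd(d_test)/(|mean(d_test)| + ε)` clamped to [0, 1]
(`ε = 1e-8`; both-below-ε means perfectly stable at zero and scores 1).
The composite is the even mixture `0.5 (corr + 1)/2 + 0.5 stability`,
ranked descending with lexicographic tie-breaks on protein id.

Two caveats decided here and worth knowing: the folds partition *samples*
within strata (the natural reading for cohort subsets; partitioning
proteins would test a different question), and because training and test
sets partition the same data, their estimation errors are anticorrelated —
for noise-dominated proteins `corr` sits near −1, so the composite ranking
is in practice driven by `stability`, which is exactly the quantity that
separates a reproducible cross-cohort difference from noise. When either
side is constant across folds (e.g. noiseless data) the correlation is
0/0 and is defined as 0.

## The synthetic-data generator

`simulate_cohorts()` emulates the motivating study design: cohort USP with
5 normal-adrenal and 8 carcinoma samples, cohort SNUH with 58 carcinoma
samples, 3024 proteins (the size of a typical post-filter cross-cohort
panel). Baseline log2 abundances are N(20, 2) across proteins — the
center and spread of typical DIA protein-group intensities — with
within-protein residual sd 0.5. Five percent of proteins carry a ±1 log2
(two-fold) effect in the tumour group; the second cohort is shifted by
0.5 log2 units as a whole (a realistic single-scalar batch offset).
Missingness is a completely-random 2% plus a logistic left-censoring term
`plogis(−steepness (log2 x − midpoint))` with steepness 1 and midpoint 16
(two baseline sds below the mean), the standard abundance-dependent
dropout surrogate. All draws come from one seeded stream in documented
order (baselines, DEP set, signs, residuals; missingness uses seed + 1 so
it is reproducible independently of the values).

What the generator does *not* emulate — and what passing tests therefore
do not certify about real data: protein-protein correlation structure,
peptide-level rollup artefacts, non-Gaussian heavy tails, per-protein
batch interactions, and shared-peptide protein-group ambiguity.

## Problem sizes and numerical choices

The test suite and the demonstration pipeline run at reduced but
structure-preserving sizes (hundreds to a few thousand proteins, the real
8/58 cohort geometry), chosen so a full run completes in seconds while
every statistical check — type-I calibration at 2000 null proteins, DEP
recovery at 1000 proteins with 100 true effects, prior-parameter recovery
at 5000 variances — retains enough resolution for its stated tolerance.
Other fixed conventions: protein-group keys collapse to the leader
accession; DIA-NN matrices treat `0` as missing (an absent quantity, not a
measurement) while generic tables treat only empty/NA tokens as missing;
canonical output is UTF-8 TSV with full `%.17g` precision so round-trips
are lossless.

## Known limitations

Only two-cohort comparisons (no multi-centre generalization of the GSI);
pairwise two-group contrasts rather than a multi-factor design matrix; the
scalar batch model cannot absorb per-protein batch effects (a ComBat-style
model is out of scope because it would also absorb the biology under
study); percent similarity depends on the log2 offset of the data and is
therefore a scale-convention-dependent summary — it is reported alongside,
never instead of, the offset-invariant components.

## A short worked run

```{r demo, eval = FALSE}
out <- run_pipeline(demo_config(out_dir = tempfile(), seed = 1))
out$global_gsi        # cross-cohort agreement on [0, 1]
out$dea$NHA_vs_ACC    # DEP tallies for the normal-vs-carcinoma contrast
```
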