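---
title: "Methods: chemoresponse signature discovery with chemosig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemoresponse signature discovery with chemosig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemosig)
```

## Overview

`chemosig` implements a discovery-to-validation workflow for transcriptomic
signatures of response to first-line platinum chemotherapy in BRCA wild-type
high-grade serous ovarian cancer (HGSOC). Patients are dichotomised by
platinum-free interval into sensitive (S, relapse after more than 12 months)
and resistant (R, relapse within 6 months). The workflow has five analysis
stages plus a synthetic-data generator:

1. **Count-based differential expression** on a discovery cohort
   (7 S vs 7 R by default): low-count filtering, median-of-ratios
   normalization, optional empirical-Bayes batch adjustment,
   negative-binomial (NB) Wald tests, Benjamini-Hochberg (BH) correction and
   two-tier gene selection.
2. **RT-qPCR validation** of the selected panel on a larger cohort
   (25 S vs 19 R by default): geometric-mean reference normalization
   (delta-Ct), exact Wilcoxon rank-sum tests with Hodges-Lehmann (HL) shift
   estimates, 2^-ddCt fold changes and cross-platform concordance
   regression.
3. **Random-forest signature ranking**: stratified 4-fold cross-validation,
   per-subject Brier scores, exclusion of high-uncertainty subjects
   (Brier > 1), retraining, and a 0-100 mean-percent ranking of mean
   decrease accuracy (MDA) and mean decrease Gini (MDG) importances.
4. **Cell-line resistance calling**: four-parameter-logistic (4PL)
   dose-response fits, IC50 comparison against the clinically achievable
   plasma concentration (Css/Cmax), exhaustive label-randomization tests on
   a small cell panel and patient/cell-line concordance evidence levels.
5. **Over-representation analysis (ORA)** of the selected genes with
   Fisher's exact test and a combined enrichment score.

`run_pipeline()` chains the stages in this order and writes per-stage tables
plus a deterministic JSON run report.

## The synthetic cohort generator

Raw patient data for this design are not distributable, so every stage is
exercised against a generator that reproduces the statistical structure the
analysis assumes.

**Counts.** `simulate_counts()` draws gene base abundances log-uniformly
over roughly four orders of magnitude (normalized to sum to one so the
`depth` parameter is the expected library size) and counts from an NB
distribution with `Var = mu + dispersion * mu^2`. Planted differential genes
receive a log2 fold change of ±`lfc_magnitude` (resistant over sensitive),
half up and half down with ties to up. Defaults mirror the study design:
7 + 7 discovery samples, 25 + 19 validation samples, dispersion 0.1,
depth 10^6. A `truth` object records the planted genes so recovery can be
scored; passing it back into `simulate_counts()` draws a second cohort
governed by the same ground truth.

**Batch effects.** The generator applies gene-by-batch location shifts drawn
`N(0, batch_sd)` on the log2 scale. A batch shift shared by *all* genes of a
sample is indistinguishable from a library-size change and is removed
exactly by median-of-ratios normalization; gene-specific shifts are the
simplest structure that actually requires the empirical-Bayes adjustment, so
that is what the generator plants. Batches are assigned round-robin within
each phenotype group, keeping batch and phenotype balanced.

**Ct values.** `simulate_ct()` maps size-factor-normalized expression to
cycle thresholds via `Ct = a - b log2(norm + 0.5) + offset + noise` with
`b > 0`, so higher expression yields lower Ct. Normalized rather than raw
counts enter the map to avoid conflating sequencing depth with biology. A
per-sample loading offset is shared by targets and reference genes and is
therefore removed by delta-Ct normalization; reference genes carry no group
effect and low noise (SD `noise_sd / 2`).

**Dose-response.** `simulate_dose_response()` evaluates the 4PL curve on a
half-log serial dilution from 0.001 to 100 uM — the standard design for a
five-decade cytotoxicity assay — in triplicate, with additive Gaussian
viability noise (default SD 5 in percent units). `default_cell_panel()`
provides a seven-line panel with two lines resistant to both drugs,
mirroring the primary-culture panel of the study design.

**What the generator does not emulate.** Tumor purity, amplicon/primer
effects, read-level noise, correlated gene modules and heavy-tailed count
outliers are out of scope. Passing tests therefore demonstrate the
statistical machinery under the assumed model, not robustness to every
artefact of real cohorts.

## Differential expression

**Filtering.** Genes with mean raw count below 50 are removed; a mean of
exactly 50 is kept ("less than" is read strictly).

**Normalization.** Median-of-ratios size factors: genes with any zero count
are excluded from the geometric-mean reference set, and each sample's factor
is the median ratio of its counts to the per-gene geometric means.

**Dispersion.** Per-gene method-of-moments estimates on normalized counts,
`(var - mean * mean(1/sf)) / mean^2`, floored at 1e-8, then averaged 50/50
with a parametric mean-dispersion trend `a0 + a1/mean`. The trend is fitted
by least squares to the *unfloored* estimates: fitting only the positive
ones would bias the trend upward because sampling noise pushes a substantial
fraction of small-sample moment estimates below zero.

**Wald test.** Each gene is fitted with an NB generalized linear model
(log link, `log(sf)` offset, phenotype as the only covariate) with the
dispersion plugged in. The standard errors are taken at family dispersion 1:
`summary.glm` would otherwise rescale them by a Pearson quasi-dispersion
estimated on 12 residual degrees of freedom, which turns the nominally
normal Wald statistic into a t-like quantity and inflates the type-I error
from about 0.05 to about 0.09 at the discovery-cohort size. The coefficient
is estimated on the natural-log scale and divided by `log(2)` for reporting,
so `log2FC` is in log2 units, resistant over sensitive. All-zero genes are
flagged and given `p = 1`, `log2FC = 0`.

With these choices the null calibration on the synthetic discovery design
(2000 genes, 7 vs 7) lands at a raw-p fraction below 0.05 of roughly
0.035-0.05 across seeds, and planted |log2FC| = 2 genes that pass the count
filter are recovered into tier 1 essentially completely. Recovery is scored
among planted genes *expressed above the count filter*: a planted gene whose
mean count never reaches the filter threshold is unmeasurable by design, not
a miss of the test.

**Selection.** Tier 1 is `padj < 0.05 & |log2FC| > 1`; the stricter tier 2
panel is `padj < 0.005 & |log2FC| > 1`. Both inequalities are strict, so a
gene at exactly |log2FC| = 1 is excluded.

**Batch adjustment.** `batch_adjust()` operates on `log2(normalized + 1)`
values — the scale on which a Gaussian location/scale model is defensible —
and is a deliberately simplified one-step parametric empirical-Bayes
adjustment: per-gene batch means and variances are shrunk toward across-gene
moments (normal prior on locations, inverse-gamma on scales, both by moment
matching) and removed, restoring the grand mean and pooled scale. Genes with
(near-)zero residual variance fall back to exact location removal, which
makes the no-noise constant-shift case exact. Batches with a single sample
trigger a location-only fallback with a warning. When the pipeline applies
the adjustment it maps the adjusted log values back to nonnegative integer
pseudo-counts so the NB machinery downstream is unchanged. Divergences from
the full iterative algorithm (no iteration, no covariate design) are
intentional and documented here; so are the omissions on the DE side
relative to the reference NB implementations (no LFC shrinkage, no outlier
filtering, no independent filtering).

## qPCR validation statistics

**Reference normalization.** The per-sample reference value is the geometric
mean of the reference-gene Ct values (taken literally on the Ct scale), and
`dCt = Ct_target - gmeanref`; `-dCt` is the testing scale, `2^-ddCt` the
fold change. Note that the geometric mean is not translation-equivariant, so
adding a constant to target and reference Cts leaves dCt exactly invariant
only when the reference Cts are equal; in realistic tables the deviation is
a few thousandths of a cycle.

**geNorm.** `genorm_m()` computes the classical stability measure: the mean,
over other candidates, of the SD of pairwise Ct differences. The NormFinder
alternative is out of scope.

**Wilcoxon and Hodges-Lehmann.** `wilcoxon_shift()` uses the exact rank-sum
null when there are no ties and `n_S * n_R <= 10000`, otherwise the normal
approximation with tie correction (the exact method is refused under ties).
The HL shift is the median of all pairwise R - S differences, and its 95%
confidence interval is obtained by inverting the rank-sum test over the grid
of pairwise differences. Degenerate input (all values identical) yields
`p = 1`, shift 0 and a degenerate-CI flag. Exactness is verified in the test
suite against full enumeration of label assignments for all group sizes up
to 8. Both raw and BH-adjusted p-values are reported per gene, since either
may reasonably gate the final signature call.

**Concordance.** `concordance_regression()` regresses standardized qPCR
values on standardized RNA-seq values per phenotype group; with standardized
inputs the OLS slope equals the Pearson correlation of the raw pairs, which
is the quantity reported together with its confidence interval and p-value.

## Random-forest signature ranking

Subjects are predicted by stratified 4-fold cross-validation: each subject
is scored exactly once by a 1000-tree forest (classical defaults:
`mtry = floor(sqrt(p))`, unlimited depth) trained without its fold; the
probability of the resistant class is the fraction of trees voting R, and R
is fixed as the positive class throughout.

**Brier scores.** The per-subject Brier score uses the two-class *sum* form
`sum_k (p_k - y_k)^2 = 2 (1 - p_true)^2`, which ranges over [0, 2]. This
choice is forced by the discard rule: under the single-probability form
(range [0, 1]) a threshold of "greater than 1" could never fire, whereas
under the sum form `brier > 1` is exactly `p_true < 1 - 1/sqrt(2) ~= 0.293`.
Exclusion is strict (`brier > 1` discards; equality retains).

After exclusion, cross-validation is re-run on the retained subjects for the
primary confusion report (the pre-filter report is also kept), and a single
fresh forest trained on all retained subjects supplies the importances —
the single-retrained-forest reading of the procedure. MDA is the
conventional permutation importance scaled by its standard error (as
reported by the classical implementation); MDG is the mean per-tree total
Gini-impurity decrease. Both columns are min-max normalized to 0-100
(worst predictor 0, best 100) and the per-gene ranking score is the
arithmetic mean of the two percentages. Ties in the held-out vote
(`p_R = 0.5`) predict sensitive, the conservative direction for a resistance
classifier.

Performance metrics use the standard definitions (sensitivity TP/(TP+FN),
specificity TN/(TN+FP), precision TP/(TP+FP), F1, accuracy; FPR, FDR, FNR as
proportions), with undefined ratios reported as `NA` rather than zero. For
the reported confusion counts (15, 24, 1, 2) the standard false-negative
rate is FN/(FN+TP) = 2/17 = 0.1176; the alternative 2/39 = 0.0513 equals
FN/(TP+TN) and is not a standard quantity, so only the standard form is
computed.

## Cell-line stage

**4PL fitting.** `fit_4pl()` fits
`v(c) = bottom + (top - bottom) / (1 + (c/ic50)^hill)` by nonlinear least
squares on log concentration, with data-driven starts (plateaus at the
response extremes, `hill = 1`, IC50 at the concentration nearest the
midpoint response) and bounds `ic50` within [min conc/10, max conc x 10] and
`hill` within [0.1, 10]. Because a start lying on an exactly-fitting
solution can abort the Gauss-Newton machinery with a spurious singular-
gradient error, mildly displaced starts are retried before giving up. A
response range under 10 percentage points (flat curve) or a failed fit
yields `converged = FALSE` and no IC50. The reported IC50 is the relative
EC50 — the curve's inflection parameter — which remains well defined when
the lower plateau sits above zero.

Under the default assay design (half-log dilutions, triplicate, noise SD 5)
the IC50 estimate is unbiased with a relative-error SD of about 0.11, which
is at the information bound for this design; about 82-85% of runs land
within 15% of truth. Tightening that to 90% would require a denser dose
grid or steeper curves than the standard design provides, so the package
documents the attainable precision rather than overstating it.

**Resistance calls.** A line is resistant to a drug iff its IC50 strictly
exceeds the plasma Css/Cmax threshold; equality is called sensitive because
resistance is defined by "higher than". The waterfall quantity
`log10(ic50) - log10(threshold)` is emitted for plotting. A line is a
*resistant model* when resistant to both drugs (the `"both"` rule, matching
a panel whose two resistant lines resisted both agents); an `"either"` rule
is exposed as an option.

**Randomization test.** With only seven cell lines, group comparisons use
the difference of group means with a label-randomization p-value: all
`choose(n, n_resistant)` assignments are enumerated when there are at most
10,000 (for 2 vs 5 that is 21, making 1/21 the smallest attainable
two-sided p), otherwise a seeded sample of assignments is drawn and the
observed labelling is counted in both numerator and denominator. This
preserves the inferential core of the original graph-based heuristic —
randomized-label p-values at alpha 0.05 — without the structural-equation
machinery, whose gene network is not specified anywhere and is therefore
not implemented.

**Evidence levels.** A gene reaches evidence level 2 when it is significant
in patients (Wilcoxon p < 0.05) *and* significant in the cell panel with the
same direction; level 1 with patient evidence only. Cell-line significance
uses `p <= 0.05` so that the minimum attainable exhaustive p on the 2-vs-5
panel (1/21 = 0.048) counts as significant, as it must for any gene to
reach level 2 on a panel this small.

## Over-representation analysis

Gene sets are read from GMT files (symbols upper-cased, duplicates dropped
with a warning). For each set the 2x2 table against the background universe
(default: all genes measured after the low-count filter) is tested with the
two-sided exact convention — total probability of hypergeometric tables
whose point probability does not exceed the observed one. The odds ratio is
the sample OR with a Haldane 0.5 correction when a cell is zero, with a
normal-approximation CI on the log scale; BH adjustment reuses the same
`bh_adjust()` as every other stage. The combined score is
`-log10(p) * z` with `z` the hypergeometric standardization of the overlap
count from the table margins. The upstream web tool's z is a proprietary
rank-permutation correction that is not published, so its printed combined
scores are not comparable to ours; this z is a documented stand-in with the
same qualitative behaviour (0 at the null expectation, sign giving
direction).

## Numerical choices and problem sizes

* Dispersion floor 1e-8; EB variance floors 1e-8; flat-gene fallbacks are
  exact location removals.
* Exhaustive-vs-sampled switches: 10,000 assignments (randomization test),
  `n_S * n_R <= 10000` and no ties (exact Wilcoxon).
* Importance normalization divides before scaling by 100 and clamps to
  [0, 100], so the extremes map exactly.
* The test-suite simulations use 300-2000 genes, cohorts of 7+7 and 25+19,
  20 forest seeds and 100 dose-response seeds — sizes chosen so the whole
  suite completes in a few minutes while keeping Monte-Carlo assertions
  stable under their fixed seeds.

## Known limitations

* The DE stage is a simplified reimplementation: direction and approximate
  magnitude agree with the reference NB tools, not bit-exact output.
* The batch adjustment is one-step EB, not the full iterative algorithm,
  and supports only location/scale structure.
* Probabilities from the forest are raw vote fractions; no calibration is
  applied.
* The ORA combined score is comparable within a run, not across tools.
* Amplification-efficiency correction and instrument-file parsing are out
  of scope for the qPCR stage; Ct tables must arrive as CSV.
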