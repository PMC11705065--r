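---
title: "Methods: identifying chemoresistance-associated ceRNA triplets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying chemoresistance-associated ceRNA triplets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceRNAresist)
```

## The problem and the model

Competing endogenous RNAs (ceRNAs) are transcripts that regulate one
another indirectly by competing for a shared pool of miRNAs: a long
non-coding RNA (lncRNA) carrying miRNA response elements can sponge a
miRNA and thereby de-repress that miRNA's mRNA targets. `ceRNAresist`
implements a screen for lncRNA-miRNA-mRNA *competing triplets* associated
with drug resistance, starting from paired resistant/sensitive cell-line
expression profiles and ending in three independent validation analyses.
The screen is a conjunction of filters, each encoding one prediction of
the ceRNA model:

1. **Dysregulation.** Each molecule must be differentially expressed
   between resistant and sensitive cells in *every* cell-line pair, in
   the *same* direction. Per pair, a moderated t-statistic is used:
   per-gene pooled two-sample variances are shrunk towards a prior
   estimated by moment matching across genes (empirical Bayes), and the
   reference t-distribution gains the prior degrees of freedom. lncRNAs
   and mRNAs must pass p < 0.05 *and* fold change > 1.5 (two-sided,
   |log2FC| > log2 1.5); miRNAs need only p < 0.05. The asymmetry
   reflects the lower dynamic range of miRNA arrays; raw (unadjusted)
   p-values are used deliberately — the screen is a preliminary filter
   whose output is further constrained downstream, and an optional
   `adjust_method` key enables Benjamini-Hochberg for users who want it.
2. **Binding.** A miRNA-target pair must be supported by the interaction
   evidence: curated/CLIP-supported tables supplied as input (the primary
   path), optionally intersected with a canonical seed-match scan
   (`predict_seed_matches()`, a transparent stand-in for full target
   prediction software — exact Watson-Crick seed complementarity, four
   canonical site types, no thermodynamics or conservation).
3. **Activity.** Both endpoints must be dysregulated in *opposite*
   directions (miRNA down with target up, or vice versa) — the signature
   of active miRNA-mediated repression.
4. **Competition.** Active miRNA-lncRNA and miRNA-mRNA interactions
   sharing a miRNA are merged into candidate triplets (a miRNA with L
   lncRNA and M mRNA partners yields L x M candidates).
5. **Co-expression.** The ceRNA model predicts *positive* lncRNA-mRNA
   correlation. Because bulk tumors mix malignant and stromal/immune
   cells, raw correlations are confounded by tumor purity; the filter
   therefore uses the first-order partial correlation controlling
   per-sample purity,
   $$\mathrm{pcc} = \frac{r_{xy} - r_{xz} r_{yz}}
   {\sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}},$$
   with x, y the lncRNA and mRNA expression and z the purity vector.
   A pair passes at pcc > 0.2 and p < 0.05, *one-sided positive*: a
   strongly negative correlation is evidence against competition, not
   for it.

Retained triplets are assembled into a typed network: `direct` edges
(miRNA-lncRNA, miRNA-mRNA binding) and `coexpression` edges
(lncRNA-mRNA), de-duplicated across triplets.

## Statistical choices and their rationale

**Partial-correlation inference.** The p-value for the purity-adjusted
correlation uses the standard transform
$t = \mathrm{pcc}\sqrt{(n-3)/(1-\mathrm{pcc}^2)}$ on n − 3 degrees of
freedom, the textbook first-order partial-correlation test. n is the
number of cohort samples with both expression and purity. The
implementation is checked against an independent residual-regression
oracle (correlating the residuals of x on z and y on z) to 1e-10.

**Moderated t.** The variance prior is fit by matching the mean and
variance of log sample variances to the moments of a scaled F
distribution (`estimate_variance_prior()`); with the prior weight forced
to zero (`prior_df = 0`) the statistic is exactly the ordinary
equal-variance two-sample t, and the test suite verifies both this
reduction and numerical agreement with the reference eBayes
implementation. Zero-variance genes with no prior are reported with
degenerate p (0 if the means differ, 1 otherwise) under a warning.

**Enrichment.** Network target mRNAs are annotated with a one-sided
hypergeometric upper-tail test per term (Fisher's-exact-style), against a
universe defaulting to all genes in the annotation input — an offline
choice in place of any service-defined genome background.

**Survival.** A ceRNA interaction's risk score is
$\mathrm{score}_s = \sum_i \beta_i \, \mathrm{expr}_{i,s}$ over the
molecules of the interaction, with each $\beta_i$ a *univariate* Cox
coefficient (partial likelihood, Efron ties, via the survival package).
Samples are split at the **median** score: strictly above the median is
high-risk; ties at the median go to the low-risk group (the tie rule is a
package convention). Groups are compared by Kaplan-Meier curves and the
log-rank chi-square on 1 df.

**Single-cell functional states.** Per-cell state activity is scored
with a rank-based single-sample enrichment statistic: genes are ranked
within the cell and the score is the normalized integral of the weighted
Kolmogorov-Smirnov running sum of the signature versus its complement
(signature steps weighted by rank^0.25, the conventional exponent).
This is a deliberate, documented ssGSEA-style statistic rather than a
reimplementation of GSVA's kernel-density scoring; it is rank-only and
hence invariant to any monotone transform of a cell's expression. A cell
with zero expression variance scores 0 by convention. Scores are
z-standardized per state across cells before correlation. Target-mRNA /
state associations use Spearman correlation with a one-sided positive
pass rule (rho > 0.3, p < 0.05); across multiple datasets, per-dataset
results are reported alongside the mean rho (p-values are not combined).

**Drug activity.** Upstream lncRNA expression is Pearson-correlated with
IC50 across the shared cell-line panel (IC50 on the scale distributed by
the source, conventionally natural-log). Positive passes are labelled
resistance-associated: high expression with high IC50 means low drug
sensitivity.

## What the synthetic generator emulates

`synthetic_truth()` plants a fixed wiring of 10 triplets over 2 lncRNAs
(up), 5 miRNAs (down) and 5 mRNAs (up) with 6 truly co-expressed pairs —
the same topology shape as a small published resistance network, so the
candidate cross-product (12) strictly exceeds the truth (10) and the
co-expression filter has real work to do. The generators emulate, per
input:

- **Cell-line profiles** (default 2 pairs x 2 conditions x 3
  replicates, 50 genes per class, noise sd 0.2 log2 units): planted
  molecules shifted by ±1.5 log2 in resistant samples of all pairs;
  six decoys per class shifted inconsistently (one pair only, or
  opposite directions) to exercise the consistency filter. Replicate
  counts are a package choice of a typical small array series.
- **Interaction tables**: the planted wiring plus random decoy edges
  that always have a non-planted endpoint.
- **Tumor cohort** (default n = 500): purity ~ Beta(5, 2) (a typical
  bulk-tumor purity distribution); every gene loads on standardized
  purity with weight 0.8, and co-expressed pairs additionally share a
  per-lncRNA latent factor scaled so the planted *partial* correlation
  is approximately `cohort_coexpr_strength` (0.6 by default; an mRNA
  shared between both lncRNAs correlates with each at strength/sqrt 2).
  This parameterization makes recovery properties hold by construction
  rather than tuning: with no true co-expression, naive Pearson between
  planted pairs is inflated to about q²/(1+q²) ≈ 0.39 while the partial
  correlation is centred at zero. Survival is exponential with hazard
  proportional to exp(Σ β x) (β = 0.4 on planted lncRNAs/mRNAs by
  default) and independent exponential censoring targeting a 0.4
  censoring fraction — typical for a TCGA-like cohort, a documented
  package choice.
- **Single-cell data**: one latent activity per state per cell drives
  both the state's signature genes and the designated target mRNAs (one
  state per target, round-robin) at a stated driving correlation.
- **Drug panel** (default 48 lines, the usual shared-panel size):
  planted lncRNAs share a latent resistance factor and IC50 is linear in
  that factor.

All generators draw from R's default Mersenne-Twister stream, seeded as
`seed + offset` with a fixed documented offset per generator, so one seed
determines the full bundle and editing one input leaves the others
byte-identical.

What passing on this synthetic family does *not* show: robustness to
real-data features it omits — heavy-tailed and count-like expression,
correlated replicates, batch effects, non-linear purity effects,
signature overlap, and informative censoring. The generator reproduces
the statistical structure the pipeline assumes, no more.

## Numerical conventions and degenerate inputs

- Duplicate gene rows on ingest are collapsed by their mean (the
  multi-probe convention), order-independently; duplicate sample ids are
  a hard error.
- `partial_correlation()` requires n ≥ 4, non-constant vectors, and
  |r_xz|, |r_yz| < 1 (otherwise "purity collinear"); the estimate is
  clamped to [−1, 1] against rounding.
- Cox fits stop at score norm 1e-9 or 50 iterations; fewer than 10
  samples, fewer than 3 events, or a non-finite coefficient are errors.
- Median-split stratification refuses a degenerate (single-group or
  constant-score) split.
- The consistency intersection requires ≥ 2 cell-line pairs unless
  `allow_single_pair = TRUE` is set explicitly.
- The pipeline consumes no randomness: identical inputs give identical
  outputs.

## Problem sizes used by the test and acceptance suites

The stochastic suites run the full pipeline on 20 bundles (cohort
n = 500) for recovery, 20 null cohorts (n = 300, 30 pairs each) for
confounding control, 100 null cohorts (n = 120) for log-rank
calibration with the risk model fit on an independent training cohort
(fitting and splitting on one cohort would bias the null), and 100
48-line null panels for the drug-correlation pass rate. These sizes give
Monte-Carlo error comfortably below the margins asserted while keeping
the default `R CMD check`-style run short.

## Known limitations

- The seed-match scan is not a substitute for thermodynamic or
  conservation-aware target prediction; supply curated interaction
  tables for real analyses.
- Only first-order purity adjustment is supported (one covariate); no
  higher-order partial correlation.
- The risk model is a sum of univariate Cox coefficients, not a
  multivariate fit; coefficients of correlated molecules absorb shared
  signal.
- Enrichment treats annotation terms as flat sets; no ontology-graph
  propagation.
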