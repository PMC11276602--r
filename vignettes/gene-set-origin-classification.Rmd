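---
title: "Predicting metastatic cancer origin from gene-set features: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting metastatic cancer origin from gene-set features: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A metastatic biopsy often arrives without a known primary site. Transcriptome
classifiers can recover the tissue of origin because tumors retain much of
the expression program of the organ they arose in. The practical obstacle is
data supply: the large public training cohorts are split between microarray
(normalized intensities) and RNA-seq (RSEM/TPM-like estimates), whose raw
expression scales are incompatible. Training on one platform and predicting
on the other fails not because the biology differs but because the
measurement does.

`cuporigin` implements a pipeline built around one idea: re-express every
sample in a platform-robust feature space of **gene-set enrichment scores**,
then remove the residual platform signal by explicit feature selection, and
only then train a classifier.

## Featurization: signed single-sample enrichment

For one sample, genes are ranked by decreasing expression (ties broken
lexicographically by symbol, so the ranking is a deterministic bijection).
For a gene set with $m$ members in a universe of $N$ genes, walk the ranking
and accumulate $+1/m$ at members and $-1/(N-m)$ at non-members. The
enrichment score (ES) is the deviation of largest magnitude of this running
sum — the signed two-sample Kolmogorov–Smirnov statistic comparing member
rank positions against non-members, equal to the unweighted (weight $p=0$)
GSEA statistic. ES lies in $[-1, 1]$: $+1$ means the members occupy exactly
the top $m$ ranks, $-1$ exactly the bottom $m$. When the positive peak and
negative trough tie in magnitude the positive one wins; internally the walk
is done on integer numerators over the common denominator $m(N-m)$, so the
tie rule is exact, not floating-point-dependent.

Because the score depends on the ranking only, it is invariant under **any**
strictly increasing transform of one sample's expression values — this is
the property that makes microarray and RNA-seq cohorts comparable, and the
test suite asserts it exactly rather than approximately.

Raw ES magnitudes shrink with set size, so scores are normalized (NES) by
dividing by the mean $|ES|$ of random same-size sets drawn uniformly from
the universe. Since a uniformly random set has uniformly random rank
positions regardless of the ranking, this null factor depends only on
$(N, m)$ and is computed once per set size, not per sample. Defaults:
`n_null = 100` draws, `seed = 13`, `min_set_size = 5` (below which the KS
statistic is too coarse to be useful). The null is a gene-sampling null, not
a phenotype-permutation null: scoring is single-sample, so there are no
phenotype labels to permute at this stage.

## Platform-neutral feature selection

Each gene-set feature gets a single-feature ROC AUC for discriminating the
two platforms, computed by the tie-corrected rank-sum identity
$\mathrm{AUC} = P(s_+ > s_-) + \tfrac12 P(s_+ = s_-)$ (exact, $O(n\log n)$).
A feature with AUC near 0.5 carries no platform information; features far
from 0.5 encode the measurement, not the biology. Selection retains the
band $|\mathrm{AUC} - 0.5| \le \delta$, boundary inclusive (with a $10^{-12}$
guard for the floating-point representation of band edges, so nominal edges
like 0.55 at $\delta = 0.05$ are kept). Smaller bands are nested inside
larger ones by construction. The default working band is $\delta = 0.25$;
`band_sweep()` exposes the full sweep over $\delta$ and training-cohort
compositions. Which platform is "positive" is irrelevant: swapping labels
maps every AUC $a \mapsto 1-a$ and leaves $|a - 0.5|$, hence the selection,
unchanged.

## The classifier

`train_origin_model()` fits a soft-voting ensemble of three members on the
selected, per-feature standardized NES matrix:

* a multinomial ridge-penalized logistic regression (glmnet), parameterized
  by an inverse regularization strength $C$ mapped to $\lambda = 1/(Cn)$;
* gradient-boosted trees (xgboost with `lossguide` growth and `max_leaves`,
  i.e. leaf-wise boosting), tuned over leaves and boosting rounds;
* an RBF-kernel SVM (e1071) with pairwise-coupled probability outputs; the
  kernel width is set by the median heuristic (inverse median squared
  pairwise distance of up to 256 training rows).

Each member is tuned independently by grid search over a small default grid
(`default_grid()`: $C \in \{0.1, 1, 10\}$; leaves $\in \{15, 31\}$ × rounds
$\in \{100, 300\}$ at learning rate 0.1; SVM cost $\in \{1, 10\}$) with
stratified k-fold cross-validation maximizing macro-F1 on the pooled
out-of-fold predictions. Standardization statistics are stored in the model
and re-applied at prediction time. The ensemble probability is the equal-
weight mean of the member probability vectors, renormalized; the per-sample
ranking orders classes by decreasing probability with ties broken by
vocabulary order. Everything is deterministic given the training seed
(xgboost runs single-threaded; the SVM probability calibration is run under
a derived fixed seed).

Training is unweighted by default; `balanced = TRUE` switches to
$n/(K n_c)$ class weights for imbalanced cohorts.

## Evaluation protocols

* **Top-k weighted accuracy**: fraction of samples whose true class is among
  the k highest-ranked predictions. Pooled over samples this is identical to
  the class-support-weighted mean of per-class top-k accuracies — the
  identity is asserted exactly in the tests, which is why the package treats
  "weighted accuracy" and pooled accuracy as the same number.
* **Confusion matrix** of top-1 calls with fixed vocabulary axes;
  trace/n equals top-1 accuracy.
* **Cross-platform transfer** (`cross_platform_validation()`): train on all
  samples of one platform, score macro-F1 on the other. Test classes absent
  from training are excluded from the macro mean with a warning rather than
  scored zero, since the model cannot name them by construction.
* **Stratified k-fold CV** (`kfold_cv()`): folds stratified by class only
  (samples of both platforms shuffled together).
* **Band sweep** (`band_sweep()`): accuracy of each training composition
  (platform A, platform B, A+B) at each $\delta$ on a fixed test matrix;
  empty bands are reported as failed rows, not errors.
* **Correlation diagnostic** (`platform_correlation_diagnostic()`): Pearson
  correlation between the two platforms' per-class mean feature vectors,
  computed at the gene-expression level and at the NES level. Featurization
  should raise it.

## The synthetic study conditions

Real training cohorts for this problem are consortium-scale downloads and a
private clinical validation cohort; the package instead ships a generator
(`synth_config()` / `synth_generate()`) whose defaults define the fixed
study conditions used by the test suite and the acceptance script:

* 10,000 genes, lognormal baseline (log2 baseline ~ N(7, 2), per-gene noise
  SD 1.0 on the log2 scale);
* 6 origin classes (named after organ sites), 20 samples per class per
  platform — 240 samples;
* 300 gene sets of 15–40 genes: 20% class-informative (member genes shifted
  up by `class_effect = 0.4` noise-SD units in samples of exactly one
  class, on both platforms), 20% platform-biased (member genes shifted by
  `platform_effect = 0.5` units on the RNA-seq platform only), the rest
  background;
* tumor-to-tumor variation in pathway activation: the class shift is
  multiplied by a lognormal per-(sample, set) factor (`activation_cv = 0.9`).
  Without this, informative sets would have an unrealistically tight NES
  distribution, and the small ranking perturbation caused by the biased
  genes would register as platform signal on them;
* a monotone per-platform distortion of the linear expression scale
  (`scale * value^exponent + offset`). The microarray transform is strongly
  compressive (exponent 0.3), emulating the narrow dynamic range of
  intensity data; RNA-seq is left on its RSEM-like scale.

The gene count matters: platform bias is injected *before* ranking, so
biased member genes perturb the global ranking of every sample on one
platform. With a small universe that perturbation contaminates the
platform-AUC of innocent features; at transcriptome scale (10,000 genes,
~5% of them biased) informative sets stay platform-neutral while biased
sets are strongly discriminative (AUC deviations of 0.3–0.5 from 0.5 at the
defaults).

What the generator does **not** emulate: count noise (negative binomial
library-size models), FFPE degradation, correlated co-expression modules,
class-dependent platform interactions, and set-to-set gene overlap beyond
what uniform sampling produces. Passing tests demonstrate that the pipeline
recovers planted structure under monotone platform distortion plus additive
platform bias — not clinical performance on real cohorts.

## What the fixed-seed properties assert

At the default conditions and seed, the suite verifies end to end that:
the per-class cross-platform correlation is strictly higher at the NES
level than at the gene level; at $\delta = 0.1$ at least 90% of biased sets
are excluded and at least 95% of informative sets retained; training on
microarray only and predicting RNA-seq reaches top-1 accuracy at least 0.85
with $\delta = 0.25$ selection and strictly beats the same pipeline without
selection; and training on both platforms is at least as good as either
alone on a held-out stratified third. These restate, at desk scale, the
claims that motivate the method: gene-set featurization harmonizes
platforms, AUC banding removes what platform signal remains, and combined-
platform training transfers best.

## Numerical choices and degenerate inputs

* ES ties (`|D+| = |D-|`) resolve positive; computed in integer arithmetic.
* Expression ties rank lexicographically by gene symbol (byte order), so
  featurization is bit-reproducible across runs and platforms.
* Duplicate gene rows collapse to the highest-mean row (the usual
  probe-to-symbol convention); symbols are whitespace-trimmed and matched
  case-sensitively, with no alias mapping.
* Gene sets covering the whole universe, or intersecting it below
  `min_set_size`, are dropped and recorded in the enrichment params.
* Constant features standardize with SD forced to 1 (they contribute
  nothing rather than NaNs).
* An empty AUC band is an error in `select_band()` but a "failed" row in
  `band_sweep()`, which continues.
* Grid-search ties take the first candidate in grid order.

## Problem sizes used by tests and the acceptance script

Module tests run on miniature cohorts (hundreds of genes, tens of
samples). The end-to-end properties and `scripts/acceptance.R` use the
default conditions above (10,000 × 240, 300 sets) with the single-point
`small_grid()` per ensemble member; the full `default_grid()` triples
training time without changing any of the compared pipelines, so the sweep
over it is left to users tuning real cohorts. Five-fold CV in the
acceptance script uses the $\delta = 0.25$ selection.

## Known limitations

* Exactly two platforms; multi-platform generalization is out of scope.
* No rejection option: a sample from an origin outside the training
  vocabulary will still be assigned a ranking over known classes.
* NES normalization uses a gene-sampling null; set-size-dependent subtleties
  of phenotype-permutation GSEA nulls do not apply here.
* The KS statistic is unweighted; weighted GSEA (p = 1), leading-edge genes
  and enrichment p-values are deliberately not provided — the pipeline
  consumes scores only.
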