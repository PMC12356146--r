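---
title: "Methods: SNP feature selection and neural case/control prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP feature selection and neural case/control prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genome-wide SNP panels describe each individual by the genotype (AA, AB, BB,
or a failed call "NC") at up to hundreds of thousands of positions, with a
binary disease label (Case/Control) per sample. Predicting the label from
the panel faces two obstacles: the features are categorical, and the vast
majority are irrelevant or mutually redundant. `snpsieve` implements a
complete, leakage-aware pipeline for this setting: cleaning, target
(mean) encoding, a suite of feature selectors, a zoo of compact neural
classifiers, and stratified cross-validated evaluation — plus a synthetic
genotype generator with planted causal SNPs so every stage can be tested
against known ground truth.

## Cleaning rules

Three rules are applied in a fixed order by `preprocess_genotypes()`:

1. **Invariant SNPs** are dropped. Invariance is judged on the *called*
   (non-NC) cells, because this step precedes imputation; a SNP that is
   all-AA-except-NC carries no case/control information either way. SNPs
   with zero called cells are dropped by the same rule.
2. **High No-Call SNPs** are dropped when their NC fraction is *strictly
   greater* than the threshold (default 0.10, "more than 10%"). A SNP at
   exactly 10% is kept — the boundary case is tested explicitly.
3. **Remaining NC cells** are imputed with the SNP's modal called genotype.
   Ties are broken deterministically in the order AA < AB < BB; the rule is
   arbitrary but fixed, so runs are reproducible and auditable.

## Mean encoding and data leakage

Each genotype G of each SNP is mapped to the case proportion among its
carriers:

$$E(G) = \frac{\#\{\text{Case samples with genotype } G\}}
             {\#\{\text{samples with genotype } G\}}$$

so a SNP with six AA samples of which four are Cases encodes AA as
4/6 ≈ 0.67. The encoding is supervised: it uses the labels. Fitted on all
samples and then cross-validated, it leaks test labels into the features
and inflates accuracy — measurably so on *null* data, where no real signal
exists. The package therefore exposes two modes:

* `encoding = "fold_safe"` (default): `cross_validate()` fits the map on
  each training fold only and encodes the test fold with the training map.
  Genotypes unseen at fit time receive the fallback value, the training
  fold's case prevalence — the minimal-assumption prior.
* `encoding = "global"`: the map (and the feature selection) is fitted once
  on the full dataset, the way a whole-dataset analysis would do it. This
  mode exists deliberately: the acceptance suite compares the two on null
  panels and demonstrates the inflation (about +3 accuracy points at
  n = 40 with 30 encoded SNPs, significant over 20 seeds).

Feature selection follows the same discipline: by default it is fitted
inside each training fold, because the selection is part of the pipeline
under validation.

## Feature selection

**AMGM + cosine redundancy (two-stage).** Each encoded SNP column is scored
by the ratio of its arithmetic to geometric mean. The ratio is 1 exactly
for constant columns and grows with spread, so it is a variability-based
relevance filter. Encoded values can be exactly 0, which degenerates the
geometric mean, so a shift of ε = 1e-6 is added (configurable; the ranking
is insensitive to ε well below the encoding resolution 1/n). The top
`n_intermediate` (default 1000) SNPs then pass a greedy cosine-redundancy
filter: walking in rank order, a SNP is kept iff its maximum cosine
similarity to the already-kept set is below τ (default 0.95), stopping at
`n_final` (default 100). If the greedy pass runs out of candidates, the
remaining slots are filled from the skipped SNPs in rank order, with a
warning, so the requested panel size is honored; both stage sizes and τ
are recorded in the result's provenance. One practical note: mean-encoded
columns are non-negative and share a large common-mean component, so their
pairwise cosines are generically high; at the default τ = 0.95 the greedy
pass often exhausts its candidates early and the fill rule (with its
warning) kicks in. The warning is informative, not an error — raising τ
toward 1 or centering the panel upstream are the levers if stricter
de-duplication is wanted.

**ReliefF** runs on encoded values: for every probe sample, the k = 10
nearest hits and misses (Manhattan distance on range-normalized features)
update each feature's weight by mean-diff-to-misses minus
mean-diff-to-hits. Range normalization makes the weights invariant to
positive rescaling; constant features weigh exactly 0. All samples are
probed, so the weights are deterministic.

**CMIM** runs on the *raw genotype categories*, not encoded values —
information-theoretic quantities are natural on categories, and using the
label-free representation keeps encoding-induced label information out of
the selector's input. Entropies are plug-in estimates in bits; the first
pick maximizes I(F; Y), each later pick maximizes the minimum over selected
S of I(F; Y | S) (computed with the standard running-minimum update). Ties
break by SNP id.

**SVM-RFE** fits a linear soft-margin SVM (C = 1, via `e1071`/libsvm) and
iteratively removes the `ceiling(0.1 × surviving)` features with the
smallest |weight| until `n_select` remain. The **hybrid** selector chains
CMIM (to `n_intermediate`) into SVM-RFE (to `n_select`) and degenerates to
either stage at the parameter bounds.

**Autoencoder + L1** trains a single-hidden-layer autoencoder to
reconstruct the encoded matrix with an L1 penalty on the encoder weights
and scores each feature by its total absolute encoder weight. Columns are
mean-centered but *not* variance-scaled: on mean-encoded genotypes the
between-genotype spread of the case proportion is precisely what makes a
SNP relevant, and z-scoring erases it — with scaling, the selector's recall
of planted causal SNPs drops to chance (we verified this directly), because
the simulator's causal SNPs are marginally independent of each other and
variance is the only unsupervised signal.

**Chi-squared / mutual information** rank SNPs by the genotype-by-class
contingency table (Pearson statistic without continuity correction, or
plug-in MI in bits).

## The model zoo

No neural-network framework is assumed: the package ships a compact,
self-contained engine (plain matrix arithmetic, Adam, binary cross-entropy,
inverted dropout, analytic backprop including backprop-through-time and 1-D
convolutions; the test suite verifies every backward pass against central
finite differences). All architectures share one train/predict
contract (`train_classifier()` / `predict()`), are interchangeable inside
`cross_validate()`, and are pure functions of (data, spec, seed).

* `fnn` — two hidden ReLU layers (`neurons_1`, `neurons_2`), dropout after
  each.
* `ae_baseline` / `ae_bayes` / `ae_sparse` — a linear-bottleneck
  autoencoder is pre-trained on the features (MSE), frozen, and a logistic
  head is trained on the codes. The bottleneck defaults to
  `ceiling(d / 4)` — a simple structural adaptation to the panel size,
  exposed as `bottleneck` for override. The sparse variant adds an L1
  activity penalty (weight 1e-4) on the codes. `ae_bayes` is the same
  architecture with hyperparameters chosen by `bayesian_search()`.
* `gru`, `bilstm` — the feature vector is consumed as a length-d sequence
  of scalars, one SNP per step, in panel order. SNPs have no intrinsic
  sequence; this is a documented convention, and the recurrent models are
  included to measure whether sequence-style processing helps at all. The
  Bi-LSTM concatenates the final hidden states of a forward and a reversed
  pass; dropout applies to the recurrent summary before the output layer.
* `cnn` — 1-D valid convolution (width `filter_size`, 8 filters) along the
  feature axis, ReLU, global average pooling, dropout, logistic output.
* `resnet` — a width-1 projection to 8 channels, then 2 residual blocks
  (two same-padded width-`filter_size` convolutions with an identity skip),
  global average pooling and a logistic head.
* `stacked_ae_fnn`, `stacked_ae_bilstm` — the pre-trained, frozen encoder
  feeds an FNN or Bi-LSTM head trained on the bottleneck codes; freezing is
  the simplest reading of "optimize the parts separately, then integrate".

Defaults (epochs 100, dropout 0.3, batch 32, learning rate 1e-3, neurons
64/32, units 32, filter size 3) are package choices, all overridable per
`model_spec()`; dropout is present in every architecture. Prediction uses
no dropout and no RNG, and the hard-label rule is probability ≥ 0.5 →
Case.

`bayesian_search()` performs sequential model-based optimization: random
initial configurations are scored by inner 3-fold stratified CV accuracy,
then a random-forest surrogate proposes each next configuration by
maximizing predicted accuracy plus one between-tree standard deviation over
a sampled candidate pool. Learning rates are searched on a log scale; the
full trial log is returned.

## Evaluation

`stratified_kfold()` partitions samples so fold sizes and per-class counts
each differ by at most one. Stratification is a deliberate choice: with
imbalanced panels, unstratified folds can be dominated by one class, which
produces the degenerate 0% sensitivity/specificity cells that plague this
kind of study. Metrics (accuracy, sensitivity = Case recall, specificity =
Control recall, F1) are computed per fold and averaged as plain means;
per-fold values are retained. A metric with a 0/0 denominator is reported
as 0 and flagged in a `degenerate` column rather than raised — a fold with
no predicted or true positives is a result worth seeing, not a crash.
`summarize_heatmap()` condenses many runs into a long table with one row
per (dataset, selector, panel size, model, metric), and `autoplot()` draws
the tile heatmap.

## The synthetic generator

`generate_genotypes()` emulates a GEO-style case/control series at desk
scale. Per SNP, a minor-allele frequency is drawn uniformly from
`maf_range` and genotypes follow Hardy-Weinberg proportions
(p², 2pq, q²) — the simplest defensible population model. Labels follow a
logistic model: the linear predictor sums, over the planted causal SNPs,
the sample's count of B (minor = risk, a fixed convention) alleles times
log(`causal_effect`); the intercept is calibrated by root-finding so the
expected case fraction equals `case_fraction`, mirroring the near-balanced
series the pipeline targets. The defaults (maf_range 0.05–0.5, 200 samples,
1000 SNPs, 10 causal SNPs at odds ×2 per allele, balanced classes) are our
choices of a realistic desk-scale panel; real series do not publish their
allele-frequency spectra, so the MAF default is flagged here rather than
claimed from data.

What the generator deliberately does **not** emulate: linkage
disequilibrium (SNPs are independent), population stratification, sex
chromosomes, genotyping-batch effects, and platform-specific missingness
structure (No-Calls are injected independently per cell at a configurable
rate). Tests passing on this generator therefore show that the pipeline
recovers planted, independent additive signals and is calibrated on null
panels — not that it handles correlated real-world panels, where redundancy
filtering and selector behavior can differ materially.

## Numerical choices and conventions

* Case → 1, Control → 0 everywhere; sensitivity is always Case recall.
* AMGM ε = 1e-6; geometric means in log space.
* Cosine threshold τ = 0.95 ("near 1" made concrete), exposed as a flag.
* Mode-imputation tie-break AA < AB < BB; CMIM/ranking ties break by SNP id,
  making all selectors permutation-equivariant in the column order.
* The 10% No-Call rule is strictly greater-than.
* Seeds: every stochastic step (simulation, NC injection, fold shuffling,
  weight init, batch order, dropout) draws from R's RNG under a locally
  seeded, restored state, so identical inputs and seeds give bit-identical
  outputs and user RNG state is never disturbed.
* Problem sizes in the test suite are desk-scale by design: panels of
  40–400 samples and 12–1250 SNPs, 20-seed Monte-Carlo loops for the
  recovery and calibration properties, and models a few thousand parameters
  large. They exercise every code path; scaling beyond that is a matter of
  runtime, not of code.

## Known limitations

* The mean encoding assigns one number per genotype; allele-dosage (0/1/2)
  encoding is out of scope by design.
* CMIM's plug-in entropies are biased at very small group sizes; with
  fewer than ~5 samples per genotype its conditional scores are noisy.
* The recurrent models' sequence convention (panel order) is arbitrary;
  their value is comparative, not mechanistic.
* The engine is CPU-only and single-threaded; it is sized for
  hundreds-of-features panels after selection, not raw genome-wide input.
* `bayesian_search()`'s surrogate needs a handful of completed trials
  before it beats random sampling; with budgets below ~6 it is effectively
  random search.
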