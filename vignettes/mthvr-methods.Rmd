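---
title: "Ancestry inference from mitochondrial HVR profiles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestry inference from mitochondrial HVR profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mthvr)
```

## The problem

Forensic mitochondrial DNA databases store haplotypes of the control region's
two hypervariable blocks — HVR1 (rCRS positions 16024–16569) and HVR2 (1–576)
— as lists of differences from the revised Cambridge Reference Sequence:
`16298C` (substitution), `16124.1C` (insertion of a C after 16124), `16189-`
(deletion). Because mitochondrial haplogroups are strongly, though
imperfectly, associated with coarse ancestry, such profiles carry usable
signal for assigning a sample to one of a small number of population labels
(e.g. Caucasian, African, Asian, Hispanic). `mthvr` implements this inference
as a complete, testable pipeline: profile I/O and validation, binary feature
encoding with three missing-data strategies, PCA, four classifiers,
cross-validated and independent-test evaluation with micro/macro accuracy,
region-informativeness scans, and a synthetic cohort generator so every stage
can be exercised without access to restricted databases.

Two facts shape the design. First, *absence of a polymorphism is data only
where the sample was sequenced*: each profile carries explicit typed ranges,
and every operation distinguishes "reference at a typed position" from
"unknown". Second, laboratories sequence lab-dependent subranges, so
real-world test profiles routinely miss some or all of HVR2 — handling that
missingness is a first-class concern, not an afterthought.

## Encoding

For a training set, the feature universe is the ordered set of its distinct
polymorphism tokens (`build_feature_space()`); a sample encodes as a binary
vector with 1 where it harbours the feature (`encode_binary()`). Test-only
polymorphisms carry no information for a model trained on this universe and
are dropped with a logged count.

Features are ordered along the *concatenated HVR axis* — HVR1 (16024→16569)
followed by HVR2 (1→576), the order in which the blocks sit on the circular
genome — with same-site features contiguous (substitution, then insertions by
index, then the deletion). A single ordering for encoding and for the scans
keeps "delete 10% of features from one end" geometrically meaningful; raw
numeric position ordering would interleave HVR2 before HVR1.

Three strategies address untyped positions in test data:

* **rCRS (reference imputation)** — untyped positions are read as
  reference, i.e. all their features encode 0 (`encode_rcrs()`). Cheap, but
  since the rCRS itself is of Caucasian origin, it drags profiles with
  missing data toward reference-like classes.
* **Probability** — the binary block is augmented with 1122 per-position
  variables: 1 if typed-and-polymorphic, 0 if typed-and-reference, and the
  training polymorphism *rate* at that position when untyped
  (`position_rates()`, `encode_probability()`). Rates are global, not
  class-conditional; class-conditional rates would bake the training
  composition bias directly into the encoding.
* **Common region** — the training features are restricted to the test
  sample's typed region and the whole model (PCA + classifier) is refit on
  that restriction (`restrict_to_common_region()`,
  `holdout_evaluate(strategy = "common_region")`). Most expensive, but the
  model only ever sees sequence both sides share. Models are cached by the
  test sample's typed-region signature; because laboratories reuse a small
  repertoire of primer schemes, many test samples share a signature and the
  cache is effective. Training samples are *not* dropped for partial overlap
  (their uncovered features encode 0); a minimum-overlap fraction is exposed
  (default 0) for stricter settings. A per-training-sample reading of the
  common-region idea (sample-dependent feature spaces) exists; the
  implemented single-space-per-test-signature reading is the tractable one
  and is what the caching remark in its source suggests.

On completely typed data the three binary encodings are bit-identical and the
probability encoding differs only by a deterministic 0/1 block; all four
strategies then yield identical predictions — tested as an invariant.

## PCA

`fit_pca()` centres columns and eigendecomposes the 1/(m−1) covariance;
`pca_transform()` projects onto the leading axes. Numerical choices: axes are
sign-fixed so each one's largest-magnitude component is positive
(eigenvector signs are arbitrary; fixing them makes results reproducible);
zero-variance columns are retained and yield zero eigenvalues; when n > m the
decomposition runs through the m×m Gram matrix, returning the data-supported
axes only (the remaining nullspace has eigenvalue 0 and is never selected).
The retained dimension k is chosen by 5-fold cross-validation
(`select_k()`) over the candidate grid {1, 2, 5, 10, 20, 50, 100, 150, 200}
∩ [1, min(m−1, n)], ties toward smaller k. The grid is a desk-scale choice
spanning the regimes these data imply; it is configurable per pipeline.

## Classifiers

* **SVM** (`train_svm()`): soft-margin maximum-margin classification with the
  radial basis kernel K(x₁,x₂) = exp(−γ|x₁−x₂|²), solved in the Wolfe dual by
  sequential minimal optimization (maximal-violating-pair working-set
  selection, KKT gap tolerance 1e−3) implemented in C++. Multiclass by
  one-against-one voting; vote ties break toward the earlier class in sorted
  order. Default tuning grids are the standard coarse log₂ grids
  C ∈ 2^{−5,−3,…,15}, γ ∈ 2^{−15,−13,…,3} (`tune_svm()`, ties toward smaller
  C then γ). No established dual solver ships in this environment, so the
  solver is part of the package and is held to analytic contract tests
  (two-point midpoint separator, box constraints, dual feasibility,
  exact separation of separable data at large C).
* **LDA/QDA** (`train_gaussian()`): class-conditional multivariate normals
  with pooled (LDA) or per-class (QDA) covariance, empirical priors by
  default (switchable to uniform), posteriors computed in log space via
  Cholesky factors. Sparse binary features make near-singular scatter
  routine, so a ridge ε = 1e−6 × mean diagonal (absolute floor 1e−8) is added
  explicitly; a singular fit without regularization errors with advice
  rather than guessing.
* **1NN** (`predict_1nn()`): Hamming distance on the binary encoding, nearest
  set majority vote, remaining ties by class order. PCA is *not* applied
  before 1NN — the distance is defined on the bits. The same mechanism serves
  as the haplogroup-assignment tool when the reference panel is
  haplogroup-labelled.

When `pipeline_spec(tune = TRUE)`, k is selected at the spec's fixed (C, γ)
and (C, γ) are then tuned at the selected k; a joint nested grid search per
CV fold is out of desk-scale reach, and the staged search preserves the
leakage-safe "everything re-selected on the training part" property.

## Evaluation

`confusion_table()` rows are true classes, columns predicted classes; a
training class absent from the test truth yields a column with no row.
Micro-accuracy is the pooled percent correct (size-weighted); macro-accuracy
is the unweighted mean of per-class accuracies; they coincide for balanced
classes. `cross_validate()` stratifies folds by class by default (dealt
greedily so per-class and total fold sizes each differ by ≤ 1); plain random
splitting is available (`stratified = FALSE`) since the source method states
only a random split. Each fold rebuilds the whole pipeline — feature space,
encoding, k selection, hyperparameter tuning — on the training part only.

`deletion_scan()` removes ⌈fraction·n⌉ features per round (so ten rounds
exhaust the set at the default 0.10) from either end of the concatenated
axis; `window_scan()` cross-validates 20 evenly spaced 112-base windows
(10% of the 1122-base universe). Both re-run the full CV per step; whether to
re-tune per step or reuse full-data settings is an open choice — re-tuning
per step is the default here because each scan point is an independent
experiment, and the pipeline's settings are logged per run. Windows without
features record NA accuracy. Common-region test samples with no feature
overlap are excluded from accuracy denominators but always reported —
silent exclusion would bias the comparison.

## The synthetic world

`synthetic_config()` defaults state the emulated world: 4 labels with the
forensic-table composition (0.378, 0.295, 0.172, 0.155), 23 haplogroups
partitioned among the classes with 85% of each class's mass on its own
haplogroup block (association strong but imperfect, as observed in real
haplogroup-vs-ancestry tables), motifs of 6 polymorphisms with expected
pairwise overlap 1, Poisson(2) private substitutions per sample, full
coverage, seed 1. Haplotypes are founder motif ∪ private mutations,
intersected with the sample's typed ranges. A single seed drives one RNG
stream in documented order (motifs, classes, haplogroups, privates,
coverage), so datasets are byte-reproducible.

Typed ranges come from a finite repertoire of primer schemes (5
forensic-like schemes all covering the cores 16024–16365 and 73–340; 4
HVR1-only and 2 HVR2-only schemes for the published-like model, drawn with
the stated 60% / 5% missing-region probabilities). Real coverage is
laboratory-dependent in exactly this blocky way, and repeated signatures are
what makes common-region caching worthwhile. One published-like scheme
(16090–16365) deliberately fails the 16024–16365 trim, as a fraction of real
literature profiles does.

`reference_like_class` empties one class's motifs, making it rCRS-like; with
a published-like test split this reproduces the reference-imputation bias
mechanism: under `rcrs`, HVR1-only test samples of *other* classes lose their
HVR2 evidence and drift toward the reference-like class, while the
common-region refit stays calibrated. The acceptance suite checks the
resulting ordering (reference-like predicted share: rcrs > common-region;
macro-accuracy: common-region highest).

What a green test does *not* establish: the generator has no coalescent
genealogy, no phylogenetically consistent mutation model, no hotspot rates,
no real haplogroup nomenclature, and its default difficulty is not claimed to
match the real databases' 80–90% regime. Green means the pipeline recovers
structure that is present by construction and respects the stated
invariants — not that real-data accuracies are reproduced.

## Tolerances and degenerate inputs

PCA orthogonality/diagonalization/reconstruction at 1e−8; Gaussian
posteriors normalize within 1e−10; SMO KKT gap 1e−3 with box-constraint slack
1e−9; proportions/mixing rows must sum to 1 within 1e−12. Zero-feature
training data (all-rCRS) warns and the pipeline falls back to a
majority-class baseline; empty trim results warn rather than error; IUPAC
ambiguity codes are rejected at parse time because silently coercing
heteroplasmies would corrupt the feature space. Deletions are accepted as
`16189-` or `16189DEL` and canonicalised to the former; how the source
databases spell deletions is not documented, so the grammar is this package's
documented choice.

## Known limitations

* The SVM solver uses first-order working-set selection; very ill-conditioned
  problems (extreme C with near-duplicate points) may hit the iteration cap —
  `converged` is recorded per pairwise machine.
* Probability-strategy rates are global; with heavily imbalanced training
  data the encoding inherits that imbalance (by design, documented above).
* `select_k`'s default grid tops out at 200; wider data should pass an
  explicit candidate grid.
* Micro/macro accuracy are the only built-in metrics; no posterior
  calibration for SVM votes is provided.
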