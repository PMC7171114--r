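---
title: "Predicting drug-target interactions with PSSM-DCT descriptors and Rotation Forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-target interactions with PSSM-DCT descriptors and Rotation Forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotadti)
```

## The problem

Experimentally mapping which small-molecule drugs bind which protein targets
is slow and expensive, so computational screening is used to rank candidate
drug-target pairs before anyone pipettes anything.  `rotadti` implements a
sequence-based pipeline for this task: it needs only a protein's sequence
profile and a drug's substructure fingerprint — no 3-D structures, no
docking — and learns from a bipartite network of known interactions.

The gold-standard benchmark networks this workflow is designed around
(enzymes, ion channels, GPCRs, nuclear receptors) are small and extremely
sparse: the GPCR network, for instance, has 223 drugs and 95 targets, hence
223 x 95 = 21185 candidate pairs, of which only 635 (about 3%) are known
interactions.

## The model

### Protein encoding: PSSM + 2-D DCT

Each target protein is represented by its position-specific scoring matrix
(PSSM), the L x 20 log-odds profile produced by iterative PSI-BLAST search
(typically 3 iterations at E-value 0.001 against SwissProt; running
PSI-BLAST itself is outside the package — `parse_ascii_pssm()` consumes its
ASCII output).  Row *i* scores the substitution of residue *i* by each of
the 20 amino acids, so the matrix carries per-position evolutionary
conservation that a raw sequence does not.

Because L varies across proteins, the profile is compressed to a
fixed-length vector with the orthonormal type-II two-dimensional discrete
cosine transform,

$$\mathrm{DCT}(i,j) = d_i d_j \sum_{x=0}^{M-1}\sum_{y=0}^{N-1} f(x,y)
\cos\frac{\pi(2x+1)i}{2M}\cos\frac{\pi(2y+1)j}{2N},$$

with $d_0=\sqrt{1/M}$, $d_i=\sqrt{2/M}$ for $i>0$ (likewise for columns).
The DCT packs most of the matrix energy into the low-frequency corner, so
the top-left block summarises the profile with minimal reconstruction error.
`extract_dct_descriptor()` keeps the 20 x 20 low-frequency block flattened
row-major: 400 coefficients.  We read "the first 400 coefficients" as this
block because the PSSM has exactly 20 columns, making 20 x 20 the unique
square low-frequency block of that size; a JPEG-style zigzag ordering of the
same block is available behind the `order` flag for anyone preferring a
strict frequency ordering, and changes nothing downstream (the tree ensemble
is permutation-invariant in its inputs).

Two further choices are deliberate:

* **Raw scores by default.** The integer log-odds are transformed as-is.  A
  per-element logistic squashing $1/(1+e^{-x})$ — common in this descriptor
  family — is available via `normalize = TRUE` but defaults off.
* **Short sequences.** Proteins shorter than 20 residues are zero-padded to
  20 rows before the transform.  This is a degenerate-input policy, not a
  modelling claim; benchmark proteins are far longer.

### Drug encoding: 881-bit substructure fingerprints

Drugs are encoded as the PubChem substructure fingerprint: 881 binary keys,
bit *k* set when the molecule contains substructure *k*.  Fingerprints are
consumed precomputed (`read_fingerprint_table()`), or decoded from PubChem's
base64 string form (`decode_pubchem_base64()`: 4-byte big-endian bit-length
prefix, then MSB-first bit packing).  Computing CACTVS keys from structures
is out of scope; any function producing 881 bits can be plugged in upstream.

A labelled pair is therefore a 400 + 881 = 1281-dimensional row: target
descriptor first, drug bits second (`assemble_feature_matrix()`).

### Balanced pair sampling

All known interactions are positives; every other candidate pair is
potentially negative.  `sample_balanced_pairs()` keeps all positives and
draws an equal number of negatives uniformly without replacement from the
full negative pool — "down-sampling" to an exactly 1:1 design.  Uniformity
is the least-assumptive reading of down-sampling; the false-negative risk of
treating unverified pairs as negative is accepted because verified
interactions are ~3% of the pair space.  Sampling happens **once, before**
cross-validation fold assignment, matching the workflow order of building a
sample set and then validating on it.  The alternative — resampling
negatives inside each fold — would make folds non-comparable across
configurations and is not implemented.

### Classifier: Rotation Forest

`fit_rotation_forest()` implements the Rotation Forest ensemble.  For each
of the L trees:

1. the 1281 features are split into K disjoint near-equal subsets by a
   shuffled round-robin (at the published operating point K = 21 the
   partition is exactly even: 61 features per subset);
2. for each subset, a class subset is drawn uniformly among the nonempty
   subsets of classes, 75% of those classes' rows are sampled, and PCA is
   fit on the subset's columns of that sample;
3. **all** principal axes (including near-zero-variance ones) form one
   diagonal block of a sparse d x d rotation matrix, whose block rows are
   then rearranged back to the original feature order;
4. an unpruned CART tree (Gini impurity, `rpart` with `cp = 0`,
   `minsplit = 2`, `minbucket = 1`) is fit on the rotated data.

The per-subset PCA axes make each tree see a differently rotated coordinate
frame, decorrelating the ensemble while every rotation remains orthonormal
(norm-preserving) — the property the tests assert to 1e-9.  Numerical
choices: eigenvector signs are fixed by making each component's
largest-magnitude entry positive (otherwise `eigen()`'s arbitrary signs
break reproducibility); a zero-variance subset gets an identity block; a
rank-deficient covariance still yields a full orthonormal eigenbasis, which
is used as-is.

Scores are mean tree posteriors (soft voting), with majority voting behind a
flag; the published algorithm does not constrain the combination rule, and
soft voting gives smoother ROC curves for ranking use.  Labels use a 0.5
threshold with ties mapped to the positive class.  The bootstrap fraction
(0.75) and the class-subset draw follow the originally published Rotation
Forest procedure.  With a fixed seed, fitting and prediction are
bit-reproducible; each tree consumes an independent substream derived from
the master seed.

## Evaluation

`kfold_cv()` runs stratified k-fold cross-validation (default k = 5).
Stratification keeps the 1:1 class balance in every fold, which matters for
the smallest benchmark (nuclear receptors: 180 balanced pairs); a flag
disables it.  Reported metrics are accuracy, sensitivity, precision, and
Matthews correlation coefficient from the confusion counts, plus AUC from
the trapezoidal ROC (equal to the tie-corrected rank statistic; the tests
verify this against exhaustive pairwise concordance).  Per-fold values are
summarised by mean and **sample** (n-1) standard deviation.  A metric whose
denominator is zero in some fold is reported as `NA` and excluded from that
metric's summary with a warning — never silently coerced to 0.

`grid_search()` maps cross-validated accuracy over a (K, L) grid with a
shared fold assignment so cells are comparable; ties resolve to the smallest
K, then the smallest L.  The published operating point K = 21, L = 42 is the
package default.

`compare_models()` implements the cross-model significance test family: the
first row of a models x datasets table is compared against the pooled
competitor mean per dataset, two-sided.  The default is a paired t-test,
with a Wilcoxon signed-rank alternative, since the exact test behind
published cross-model P-values of this kind is rarely stated; identical
performances short-circuit to p = 1, and constant nonzero differences are
rejected as degenerate rather than reported with an infinite statistic.

### PseAAC baseline

For feature-extraction comparisons, `pseaac_descriptor()` implements Chou's
pseudo amino acid composition: 20 amino-acid frequencies plus q
sequence-order correlation factors $\theta_j$, all normalised by
$\sum F_i + w\sum\theta_j$ so the (20+q)-vector is a partition (nonnegative,
sums to 1).  $\theta_j$ averages the squared differences of standardized
hydrophobicity, hydrophilicity and side-chain mass between residues j apart
— the standard correlation function, adopted here because variants of the
method rarely restate it.  Defaults w = 0.05, q = 10 are the conventional
choices; the three property tables ship with the package and are
standardized to zero mean and unit variance over the 20 residues before use.

## The synthetic-data generator

Reproducing published benchmark AUCs requires the benchmark download plus
PSI-BLAST against SwissProt for ~1000 proteins, neither of which belongs in
a test suite.  Instead `generate_synthetic()` builds complete miniature
studies with a *planted, tunable* signal, so the pipeline's ability to
recover a known signal is testable end to end:

* every drug and target gets a latent 8-dimensional embedding with
  independent normal entries of **mean 1** and unit variance.  The unit mean
  is deliberate: pair affinity is the scaled inner product
  $\langle u_d, v_t\rangle/\sqrt 8$, and with centred embeddings that signal
  is purely multiplicative — invisible to linear models and very hard for
  any learner at desk-scale n.  A unit mean gives each node an additive
  propensity component (some drugs bind much, some targets are hubs),
  mirroring the strong degree heterogeneity of real interaction networks
  while keeping a genuine interaction term;
* the `n_positives` pairs with the highest noisy affinity
  (`signal_strength` x affinity + standard normal noise) become the known
  interactions — the positive count is exact by construction, and
  `signal_strength = 0` makes labels pure chance;
* pseudo-PSSMs draw integer scores from a discretised normal (clipped to
  [-10, 12], a plausible log-odds range) and add a projection of the
  target's embedding to a fixed set of 10 columns, which the DCT's
  low-frequency row recovers as column-mean structure; fingerprints tilt the
  on-probability of a fixed set of 120 bits by a projection of the drug's
  embedding around a 10% base density.  The projections are shared across
  proteins (and across drugs) so the signal lands in comparable feature
  coordinates.

The tilt scales (2 score units; 2.5 logits) were calibrated once against a
ridge-logistic probe — strong signal recoverable (held-out AUC ~0.97 at
`signal_strength = 5`), no signal at chance — and then frozen; the
package's tests assert that held-out AUC is monotone in `signal_strength`
over {0, 1, 2, 5}.

What the generator does **not** emulate: realistic sequence evolution (the
sequences are i.i.d. residues; only the score matrix carries signal),
correlated substructure keys, benchmark score distributions, or
transductive structure (every synthetic pair's features are informative,
whereas real networks have cold-start drugs and targets).  Passing the
synthetic recovery tests therefore demonstrates that the pipeline's
plumbing, encodings and classifier can extract a planted signal of known
strength — not that real-data AUCs will match published values.

## Problem sizes used by the tests

The test suite and the acceptance script exercise the pipeline at sizes
chosen to make the statistical assertions meaningful while keeping a full
run comfortably on a laptop core: signal recovery uses a 100 x 80 network
with 400 positives (800 balanced pairs) at the published K = 21, L = 42
operating point; the chance-level check uses ten 40 x 30 studies with a
2/3-1/3 split, asserting on the mean AUC across seeds (per-seed AUC on ~80
test pairs has sampling noise of ~0.09, so a per-seed band would test the
noise, not the generator); dataset-construction arithmetic uses a full
GPCR-shaped 223 x 95 network.  Determinism is asserted byte-for-byte on
complete cross-validation runs.

## Known limitations

* The 881-key fingerprint is consumed, never computed: molecules must
  arrive pre-fingerprinted.
* Binary classification only; the interface would admit multiclass labels
  but nothing beyond two classes is tested.
* Negative "labels" are unverified non-interactions; a ranked prediction
  list (as `cmd_predict()` produces) is the honest output for prospective
  use, and top-ranked "negatives" are candidates, not errors.
* rpart grows trees on a model-frame copy of the rotated matrix, so memory
  scales with L x n x d during fitting at large n.
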