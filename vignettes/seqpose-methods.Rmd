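---
title: "Position-specific k-mer encoding and two-layer enhancer classification: methods"
author: "seqpose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Position-specific k-mer encoding and two-layer enhancer classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Enhancers are short genomic regions that bind transcription factors and
up-regulate target genes, often at a distance, and they come in grades:
some drive strong transcriptional activation, others weak. Sequence-based
enhancer prediction is usually framed on fixed-length (200 bp) fragments
with three labels — strong enhancer, weak enhancer, non-enhancer — and
decomposed into a cascade of two binary problems: *detection* (enhancer vs
non-enhancer, on everything) and *strength* (strong vs weak, on detected
enhancers only).

Most sequence classifiers in this area summarise a fragment by
composition statistics (k-mer frequencies, PseKNC and relatives), which
discard *where* in the fragment a k-mer occurs. The premise of this
package is the opposite: position identity is the feature. A fragment is
represented as an ordered vector of k-mer identities, one per sliding
window offset, so that "GC at offset 57" and "GC at offset 140" are
different features.

## The representation

**Dictionary.** Every k-mer observed in the training sequences (step-1
sliding window) receives a positive integer ID at first sighting,
scanning records in input order, each record left to right. k-mers are
never assigned meaning through their ID — the table is an arbitrary
injection, and a seeded shuffled assignment is available to demonstrate
that the choice does not matter. k-mers containing non-A/C/G/T characters
never enter the dictionary. A query k-mer absent from the dictionary maps
to ID 0, which has its own trainable embedding row downstream.

**Position-ID vectors.** A fragment of n bp yields n − k + 1 window
positions. In the default *duplex* layout the forward-track IDs are
followed by the IDs of the reverse complement read 5'→3', giving
2 (n − k + 1) features — 398 for 200 bp fragments at k = 2. Two readings
of the feature count were possible (a single track gives 199); the duplex
layout is this package's reconstruction, motivated by the double-stranded
nature of the molecule, and a `forward` mode is retained. Encoding a
training record against its own dictionary can never produce a 0 on
either track; 0 occurs only for query sequences or ambiguous bases.

## Position filtering by chi-squared screen

Each encoded column is a categorical variable (the k-mer identity at a
fixed offset, across samples). For one column with categories
$c = 1, \dots, C$ and binary labels, let $X$ be the sample × category
indicator and $Y$ the sample × class indicator. The screen forms

* observed counts $O = Y^\top X$ (class × category),
* expected counts $E = p_{class}^\top \cdot s$, where $p_{class}$ are the
  class proportions and $s$ the per-category totals,
* per-cell statistics $(O - E)^2 / E$.

Each category's statistic is the sum of its class cells and is referred
to the chi-square upper tail with df = classes − 1 (df = 1 for the binary
tasks, matching the behaviour of the scikit-learn feature-selection
routine this construction mirrors). The *position score* is the **sum**
of the category p-values. It is a ranking score, not a probability — it
lives in [0, C] and is large when every category at that position is
distributed independently of the label. The K positions with the largest
summed p-values (default K = 45, the tuned operating point for the
198+198-feature 2-mer layout) are removed — from every matrix in the
study, test sets included, so surviving columns stay aligned. Ties are
broken by removing the lower column index first, making masks nested in
K and byte-reproducible.

Categories are defined from the training matrix only; a test-time ID
unseen at a position plays no role in selection. Statistics are computed
in double precision throughout — printed precision elsewhere is display
formatting, not arithmetic.

## The classifier

Each cascade head is the same network:

1. **Embedding** — IDs 0..P to Q-dimensional vectors (default Q = 768,
   the token-embedding width popularised by BERT-base; a sweep over
   {12, 24, 48, 96, 192, 394, 768, 1536} is provided). Randomly
   initialised U(−0.05, 0.05) and trained.
2. **Bidirectional LSTM** — 64 units per direction (tunable grid
   {64, 128, 192}), per-timestep output width 128.
3. **Batch normalization** over the 128 per-timestep features.
4. **Additive attention** over timesteps:
   $score_t = v^\top \tanh(W h_t + b)$, $\alpha = \mathrm{softmax}(score)$,
   pooled output $\sum_t \alpha_t h_t$. The attention weights are
   nonnegative and sum to one per record. The literature description this
   reconstructs ("assign weight coefficients to features, then linearly
   combine") admits several parameterisations; additive attention is the
   simplest matching one, and the choice is recorded in the model
   manifest.
5. **Dropout** on the pooled vector (default 0.5; grid 0.1–0.7).
6. **Dense output** — one sigmoid unit for the binary heads (call = 1
   iff probability ≥ 0.5), three softmax units for the three-class
   variant (argmax).

"Two-layer" refers to the two-classifier cascade (detection head, then
strength head on detected enhancers), not to stacked recurrent layers;
each head has a single bidirectional recurrent layer. The cascade gating
is strict: a record the detection head rejects is a non-enhancer and the
strength head never determines its category.

### Training protocol

Adam (step 1e-3, β₁ 0.9, β₂ 0.999, ε 1e-7) on cross-entropy, minibatches
of 64 (grid 16–512), at most six epochs, everything — initialisation,
shuffling, dropout — driven by one integer seed (default 75). After every
epoch the validation accuracy is measured and the best epoch's weights
are retained; ties go to the *later* epoch (equally validated, further
trained — the first-best rule degenerates when a small validation set
saturates early). The loss and the optimizer internals are not stated in
the source description of this architecture; binary/categorical
cross-entropy and the Adam defaults above are the standard pairing for
sigmoid/softmax outputs and are flagged as reconstructions in the
manifest.

### Numerical choices

* **Batch-norm inference statistics are recalibrated, not averaged.**
  On a six-epoch schedule only a few dozen minibatch updates occur; a
  momentum running average of the batch statistics lags the weights so
  badly that held-out probabilities collapse toward 0.5. After each
  epoch the inference mean/variance are therefore re-estimated with a
  full pass over the training set at the current weights (variance
  floored at ε = 1e-3). This is deterministic and batch-size free.
* **Inference is invariant to batch partitioning** (recalibrated
  statistics, per-sample attention), and predictions from a reloaded
  model bundle are bit-identical.
* The embedding and the LSTM input projection are fused
  ($G = E\,W_x$ precomputed per direction, then row-gathered), which is
  algebraically identical to embed-then-project and dominates the cost
  savings that make CPU training practical; the backward pass is
  hand-derived and verified against finite differences in the test
  suite (relative error ~1e-6).
* Determinism is promised per environment per seed: identical
  configuration, seed and data reproduce the training log and
  predictions bitwise within one BLAS/OS environment, but not
  necessarily across environments.

## Evaluation machinery

The five metrics are written in the error-fraction notation used in this
literature, with S⁺/S⁻ the class sizes and S⁻₊/S⁺₋ the false
negatives/positives:

$$Sn = 1 - S^-_+/S^+,\quad Sp = 1 - S^+_-/S^-,\quad
Acc = 1 - (S^-_+ + S^+_-)/(S^+ + S^-)$$

$$MCC = \frac{1 - (S^-_+/S^+ + S^+_-/S^-)}
{\sqrt{(1 + (S^+_- - S^-_+)/S^+)(1 + (S^-_+ - S^+_-)/S^-)}}$$

These are algebraic rearrangements of the textbook confusion-matrix
formulas; the equivalence is *asserted by exhaustive enumeration* in the
test suite (all ~14k tables with cells ≤ 10), not assumed. Note the MCC
numerator sums the two error *rates*, not the errors over the pooled
total — the other flattening of the formula is not equivalent (it gives
0 instead of −1 for a perfectly wrong classifier). AUC is the
Mann-Whitney rank statistic (ties at 0.5 per tied pair), cross-checked
against an independent ROC implementation in the tests.

**Splits.** The protocol is: a seeded 10% of samples to the test set,
then 10% of the remainder to validation (floor rule at each step). The
published account does not say whether its splits were stratified;
here they are, with the global floor apportioned across classes by
largest remainder — which both stratifies and reproduces the documented
global sizes exactly (2968 → 296 test, 267 validation, 2405 train).
Folds for cross-validation are stratified round-robin deals. LOOCV
trains one model per sample (a stratified 10% of the remainder, at
least one record per class, serves as the epoch-selection validation
set) and supports a `max_n` stratified subsample for desk-scale runs.
The hyperparameter grid (3 LSTM sizes × 7 dropout ratios × 6 batch
sizes = 126 combinations) is evaluated by stratified 8-fold
cross-validation with accuracy as the selection target.

## The synthetic benchmark generator

Real enhancer benchmarks carry an unknown signal; the generator plants a
known one so every stage is testable offline. Background bases are i.i.d.
from a configurable composition (uniform by default); each motif in the
configuration overwrites the background at fixed offsets with a per-class
planting probability, expressing the gradient
p(strong) ≥ p(weak) ≥ p(background). Defaults mirror the published
benchmark's shape — 742 strong + 742 weak + 1484 non-enhancers of
200 bp — with two short motifs planted at probabilities 0.9 / 0.6 / 0.05.
Strong and weak classes differ *only* in planting probability, so the
strength task is learnable but intrinsically harder than detection,
mirroring what is observed on the real benchmark. `planted_truth()`
returns the encoded columns whose window overlaps a planted offset
(symmetric window-overlap rule, on both duplex tracks), the ground truth
for selection-recovery experiments.

What the generator does *not* emulate: the sequence statistics of real
enhancers (GC bias, chromatin-derived composition structure, motif
families with degenerate positions). Passing tests on planted data
demonstrate that the machinery — encoding, screening, training,
gating — works and recovers known signal; they say nothing about
accuracy on real genomic data, which depends on the external benchmark.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` run entirely on generated
data at desk scale, chosen as the smallest sizes at which each property
is meaningfully exercised: selection recovery uses 400 samples × 53
positions × 20 replicates; the full-architecture learning check uses
400 samples of 100 bp (198 duplex features, Q = 768) with a dedicated
80-sample validation split and a label-shuffled control; the end-to-end
pipeline run uses 600 samples of 200 bp (398 features, 45 removed). Unit
tests use miniature configurations (Q = 8, 4 LSTM units) with a larger
Adam step (0.01), since a handful of minibatch updates is otherwise too
few for even a separable toy task.

## Known limitations

* CPU training at full benchmark scale (2968 × 398 × Q = 768) is
  supported but slow (tens of minutes per head); LOOCV at full scale
  trains thousands of models and is flagged as a long-running mode.
* The attention form, loss, optimizer details and embedding
  initialisation are reconstructions of an under-specified description;
  all are recorded in the model manifest.
* Sequences are handled as flat fixed-length fragments: no genome
  coordinates, no retrieval from assemblies, no quality information.
* The chi-squared screen is the only selector implemented (no mutual
  information or wrapper selection), matching the method it
  re-implements.
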