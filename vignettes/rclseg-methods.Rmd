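---
title: "Segmenting serpin reactive center loops: models, data and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting serpin reactive center loops: models, data and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rclseg)
```

## The problem

Serpins share one archetypal fold, but the reactive center loop (RCL) —
the solvent-exposed stretch that determines which protease a serpin
inhibits — is highly variable in length (20–28 residues in annotated
UniProt entries) and composition. Because there is no conserved motif to
anchor on, position-matrix annotation fails, and the vast majority of
known serpins have no RCL annotation. `rclseg` treats the task as
per-residue binary segmentation: every residue is classified RCL /
non-RCL, and maximal positive runs become predicted spans.

The intended workflow is annotation *within* presumed serpins. The model
will happily fire on loop-like stretches in arbitrary proteins, so serpin
identification must come first, from standard domain/motif tools; this is
a deliberate non-goal of the package.

## Data representation

Sequences live in tibbles (`id`, `residues`, optional 1-based inclusive
`start`/`end` span). `make_labels()` converts them to fixed-length
per-residue label vectors with validity masks: sequences are truncated to
their N-terminal `l_fixed` residues or zero-padded, labels are 1 exactly
inside the annotated span, and the mask marks real residues. A record
whose whole span falls beyond the truncation point is dropped with a
warning — silently training on a positive sequence labelled all-negative
would poison the loss. Coordinates are 1-based inclusive everywhere
internally and in TSV/GFF3 output (the UniProt feature convention); BED
output converts to 0-based half-open on write.

Three encoders produce the `l_fixed x D` feature matrix: one-hot
(`D = 20`, channel order `ACDEFGHIKLMNPQRSTVWY`), BLOSUM62 rows (raw
integer scores from the published matrix, same channel order), and a
file-based adapter for externally pre-computed per-residue embeddings
(e.g. from a protein language model). Ambiguity letters (X, B, Z, U, O)
encode to all-zero rows rather than an extra channel, keeping `D`
identical across the residue encoders so every model is
encoding-agnostic; computing language-model embeddings is out of scope by
design — only the file contract is supported. The channel order is stored
in every checkpoint and asserted in tests, because a silent channel
permutation is the classic failure mode of this kind of pipeline.

## Architectures

All three models share one contract: `(batch, L, D)` features in,
`(batch, L, 2)` logits out (non-RCL, RCL), length-preserving, with
padding handled by the loss rather than the model.

* **CNN** — `depth` blocks of convolution (same-length padding) → batch
  normalisation → ReLU → dropout 0.3, widths doubling per block, then a
  pointwise projection. Its receptive field is deliberately local
  (`depth * (kernel_size - 1) / 2` residues per side); it is the baseline
  that long-range architectures are compared against.
* **Attention U-Net** — `depth` encoder levels of DoubleConv (twice
  conv → batch-norm → ReLU, dropout 0.25 after the second activation)
  with max-pooling (kernel 2, stride 2) halving the length per level; a
  DoubleConv bottleneck; and a decoder of transposed-convolution
  upsampling (kernel 2, stride 2), additive attention gating of the
  encoder skip (inner width half the skip width, per-position sigmoid
  gate), concatenation and DoubleConv. Input length must be divisible by
  `2^depth`; the forward pass refuses anything else by name. Pooling and
  transposed convolution are the conventional choices where only
  "downsampling/upsampling by 2" is fixed.
* **BiLSTM** — one LSTM per direction (forget-gate bias initialised to
  1), concatenated per-position hidden states, dropout 0.3, linear head.

The networks, their backpropagation and the Adam optimiser are
implemented natively in the package (R orchestration over BLAS matrix
products, with the memory-bound inner loops — offset-block convolution,
batch-norm, ReLU, pooling — in C++). Every backward pass is verified
against central finite differences in the test suite; that check is the
load-bearing correctness argument for the whole training stack.

## Training protocol

`train_config()` defaults encode the reference protocol: Adam at learning
rate 0.001, up to 50 epochs, early stopping when the residue-pooled
validation F1 has not strictly improved for 5 consecutive epochs (ties
count toward patience), batch size 32 (4 is recommended for wide external
embeddings), stratified 0.8:0.2 train/validation split. The loss is
softmax cross-entropy of the two logits averaged over unmasked positions
only — with two complementary classes this is exactly the masked binary
cross-entropy — and perturbing logits at masked positions provably leaves
the loss bit-identical. The returned model carries the best-epoch
weights, not the final ones. Validation F1 is residue-pooled
(micro-averaged); per-sequence averaging would be the other defensible
reading, and is noted but not implemented.

Two implementation details matter for stable convergence and are worth
stating because neither changes the protocol:

* **Prior head initialisation.** Loop residues are a few percent of all
  positions. With a zero-initialised head the first several epochs
  predict everything negative before the positive class "switches on".
  When the head bias is untouched (all zero), training initialises it to
  the class log-odds of the training labels, removing the dead phase.
  Warm-started models are never overwritten.
* **Batch-norm recalibration.** Dropout feeds the next convolution's
  batch-norm during training, inflating the activation variance that the
  running statistics record relative to the dropout-free evaluation
  distribution (the known dropout/batch-norm variance shift). Before each
  validation pass the running statistics are re-estimated as an exact
  average of batch statistics over up to 16 training batches with dropout
  disabled. Without this, evaluation-mode probabilities are
  systematically shrunk toward the majority class and the validation F1
  trace oscillates enough to trigger spurious early stopping.

No learning-rate schedule, weight decay, gradient clipping or class
reweighting is used; class imbalance (loops are roughly 2–7% of residues
in positives, 0% in negatives) is left to the loss as-is. All randomness
(initialisation, shuffling, dropout, data generation) flows through R's
RNG from explicit integer seeds; under single-threaded BLAS, runs are
bit-reproducible.

## Evaluation

Confusion counts are pooled over all unmasked positions of all sequences
(micro-averaging), then precision, recall, F1, MCC and accuracy are
computed with degenerate denominators mapped to 0. The per-sequence
*exact match rate* counts a sequence only if predicted labels equal true
labels at every real position — an off-by-one boundary residue fails the
sequence; negatives must be predicted all-zero. The per-residue decision
rule is argmax of the two logits with the 0.5 tie assigned to the
positive class (arbitrary, documented, fixed). Span extraction takes
maximal runs of positive labels with their mean positive-class
probability; `primary_span()` keeps the longest (earliest on ties),
reflecting that a serpin carries a single RCL.

## The synthetic planted-loop generator

Real training data for this problem is expert annotation of thousands of
UniProt serpins against predicted 3D structures; curating it is outside
the package. The generator reproduces the *statistical shape* of that
dataset so the full pipeline is exercisable and testable offline:

* positives: Gaussian lengths (default 400 ± 40), a scaffold background
  composition, three conserved motif strings planted at fixed relative
  positions (0.10, 0.35, 0.60) mimicking the shared fold, and exactly one
  loop of length uniform on [20, 28] placed near the 85% relative
  position with ±5% jitter (RCLs are C-terminal-proximal; the jitter
  prevents models from learning absolute position alone), at least 20
  residues from each terminus;
* negatives: i.i.d. residues from a proteome-like composition, lengths
  permutation-matched to the positives, no motifs, no loop.

The loop signal is carried entirely by composition: loop residues are
drawn from a distribution concentrated on A/G/S/T/P (total weight 0.92)
while the scaffold is depleted of those letters (total frequency ≈ 5%).
This design makes the negative control exact: setting
`loop_alphabet_bias = aa_composition("scaffold")` removes the signal
completely and a trained model's F1 collapses toward zero, demonstrating
that learning on the default task is driven by the planted signal rather
than leakage. A deterministic hinge motif flanking the loop was
considered and rejected: any loop-anchored landmark would keep loops
locatable even with a neutralised composition (predicting a fixed-length
window after the landmark already yields F1 ≈ 0.9), destroying the
negative control.

The `n_decoys` knob plants unannotated loop-composition segments away
from the true loop (and into negatives). With decoys, local composition
no longer identifies the annotated loop — position relative to the
scaffold motifs does — which turns the task into a long-range-context
probe separating the U-Net from the local CNN.

What the generator does *not* emulate: phylogenetic correlation between
sequences (real serpins are a single family with deep similarity
structure; synthetic sequences are exchangeable), realistic loop
composition strength, structure-derived annotation noise, and ambiguity
letters. Passing tests on synthetic data therefore demonstrate that the
machinery — encoders, models, masked training, metrics, span extraction —
works end to end and that the models can exploit both local and
long-range signal; they are not evidence about accuracy on real serpins.

An intrinsic property of the composition-only signal is boundary
ambiguity: a scaffold residue adjacent to the loop falls in the loop
alphabet with probability ≈ 5%, and a loop-edge residue looks
scaffold-like with probability 8%. Enumerating all (start, length) loop
placements under the true generative densities (the MAP decoder, an
oracle that knows the generator) yields an exact-match ceiling of about
0.73 on positive sequences — boundary-perfect prediction is impossible
for roughly a quarter of positives even with the generator's own
parameters in hand. Thresholding the true posterior marginals at 0.5
(the package's per-residue decision rule) gives essentially the same
number, so the rule itself costs nothing; the ambiguity is in the data. Residue-level metrics are essentially unaffected
(the ambiguity involves one or two residues per sequence), but
per-sequence exact-match rates on this generator must be read against
that ceiling, not against 1.0.

## Problem sizes used by the shipped checks

The test suite and the acceptance script exercise the pipeline at desk
scale, chosen so a complete run is reproducible on a single CPU core:
training pools of 400 positives + 400 negatives at `l_fixed = 512` with
100 + 100 held-out test sequences for the end-to-end recovery check (the
U-Net there uses `base_channels = 16`, `depth = 4`; the epoch cap is 12
in the test suite and 18 in the acceptance script, both within the
protocol's "up to 50"), and smaller pools (tens of sequences,
`l_fixed` 64–256) for unit, overfitting and contrast checks. The
architecture-contrast check uses `n_decoys = 2` with a weakened loop
bias so that the CNN's local view genuinely cannot resolve the task.

## Known limitations

* Training is single-core CPU; wall-clock scales linearly with
  `base_channels^2` and sequence count. The shipped configuration is
  desk-scale, far below the reference training scale for real serpin
  annotation.
* The exact-match metric is strict label-vector equality; no
  tolerance-window span matching is provided.
* Only binary (RCL / non-RCL) segmentation; no multi-loop or multi-class
  support.
* External embeddings are consumed from files; the package never runs a
  language model, and which hidden layer the embeddings come from is the
  caller's decision — the adapter is layer-agnostic.
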