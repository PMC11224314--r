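---
title: "TSCA-Net in R: model, training protocol, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TSCA-Net in R: model, training protocol, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tscanet)
```

# The decoding problem

A trial is a real matrix of spike-band activity, `T` time steps by `C`
recording channels (the source recordings are 201 x 192 from two
96-electrode arrays, already time-warp aligned upstream), labelled with
one of `N = 26` imagined lowercase letters. TSCA-Net classifies a trial by
extracting temporal features, spatial features, and — its distinctive
part — the cross-dependencies between the two axes, before pooling into a
softmax classifier.

# Architecture

Four modules operate on a trial `X` (`T x C`):

* **TF**: linear embedding of each time step's channel vector (`C -> d`,
  `d = 256` by default), batch normalization, a one-layer LSTM
  (`d -> d`), batch normalization, an optional position treatment, one
  multi-head self-attention block over the time axis (`T x (N_h d_v)` =
  `T x 2048` at defaults), and a two-layer MLP back to `T x d`.
* **SF**: the transposed trial (`C x T`), linear embedding of each
  channel's time course (`T -> d`), batch normalization, position
  treatment, self-attention over the channel axis, MLP -> `C x d`.
* **TSCross-SingleT**: the embedded raw channel sequence (`C x d`)
  queries the TF output (`T x d`) as key/value -> `C x d`; it expresses
  how much each channel attends to each time point.
  **TSCross-SingleC**: the embedded raw time sequence (`T x d`) queries
  the SF output -> `T x d`.
* **Classifier**: the stream outputs are concatenated along the sequence
  axis (`(C + T) x d` for the full model), average-pooled to `1 x d`,
  passed through `d -> d` (GELU) and `d -> N` layers, and softmaxed.

Attention is `SoftMax(Q K' / sqrt(d_k) + B) V` per head with
`d_q = d_k = d_v = 128` and 16 heads by default; per-head outputs are
concatenated and the block MLP (`2048 -> 256 -> 256`) maps back to the
model width (it plays the role of the output projection `W^o`). The
softmax subtracts the per-row maximum before exponentiating, so large
trainable bias entries cannot overflow.

## Position treatments

Four variants, matching the published position-embedding ablation:

* `relative` (default): a trainable table per head indexed by the
  query-key offset `i - j`; resolved into a Toeplitz score-bias matrix.
* `absolute`: a trainable per-position vector added to the sequence.
* `sincos`: the fixed interleaved sine/cosine schedule added to the
  sequence.
* `none`: no positional signal; attention is then permutation-equivariant,
  which the test suite exploits (channel-permutation equivariance of SF).

A relative offset between a channel index and a time index has no natural
meaning, so the cross-attention blocks default to no score bias; a config
switch (`crossPositionBias`) enables it for the square `T = C` case for
completeness. This was an open design point: the relative table is defined
by sequence offsets, which only exist within one axis.

# Training and evaluation protocol

Mean cross-entropy over trials, `L = -(1/N_t) sum_n log p_n(y_n)`, is
minimized with Adam (learning rate 3e-5, weight decay 1e-4 coupled into
the gradient, 400 epochs, batch size 8 — the published protocol; all four
are config fields). Batch normalization uses batch statistics over the
batch-and-length axis during training, with running moments (momentum
0.1) for evaluation, so evaluation is a deterministic pure function of
weights and input. The final short batch of an epoch is kept, not
dropped. There is no early stopping and no learning-rate schedule.

Evaluation is stratified five-fold cross-validation (a 4:1 train/test
ratio): within each class, index-sorted members are dealt round-robin
after a seeded shuffle, making the split a function only of the label
multiset and the seed; classes smaller than `k` trigger a warning and an
unstratified seeded split. Metrics come from the confusion matrix (rows =
true, columns = predicted): accuracy is `100 x trace / total`; per-class
precision `TP/(TP+FP)` and recall `TP/(TP+FN)` are percentages, F1 their
harmonic mean *taken directly on the percent scale* — the published
per-class F1 column reproduces only under this reading, confirming that a
trailing `x100%` in the printed F1 formula is typographical. Headline
precision/recall/F1 are unweighted macro averages: the published triple
(92.77 / 92.70 / 92.58) is inconsistent with pooled (micro) averaging,
whose precision, recall, and F1 all equal accuracy on a multiclass
confusion matrix. Classes with neither true nor predicted instances are
excluded from macro averages and flagged; zero-denominator per-class
values use a 0 sentinel with a `defined = FALSE` flag, never an error.
Cross-fold dispersion is the sample standard deviation (denominator
`k - 1`): the published 0.96 for folds {94.30, 92.56, 92.41, 91.77,
92.25} matches the sample formula, not the population one.

The "optimal model" per-class table corresponds to the best single fold
(94.30%); the package reports per-fold values and the mean, never
silently the best.

# Ablation machinery

`ablationGrid()` enumerates exactly the three published grids: seven
component rows (no TF-LSTM, no TF-Transformer, no SF, no TSCross, no
SingleC, no SingleT, full), four position kinds, and six heads x dims
combinations ({8, 16} x {64, 128, 256}, where dims is the per-head
q/k/v width). Routing under ablation follows the published table: with
both cross blocks disabled the classifier consumes TF and SF directly;
with one cross block disabled the remaining cross output alone is
classified; with SF disabled but SingleC enabled, SingleC's key/value
falls back to the embedded raw channel sequence. A variant whose toggles
leave the classifier with no input is recorded as an invalid row with the
validity message — not skipped — and disabling any component strictly
reduces the parameter count (parameters exist only for enabled
components).

# Design decisions where the architecture description is ambiguous

* **Input projections.** The layer table lists input `T x C` but a
  batch-norm output of `T x 256` with no explicit layer between; the only
  dimension-consistent reading is a trainable linear map `C -> 256`
  before the batch norm (and `T -> 256` for SF), which the LSTM's
  `inputdim = 256` corroborates. The cross blocks' raw query sequences
  reuse these same two projections (no separate maps, fewer parameters);
  they enter the cross blocks as plain embeddings, while the TF/SF
  streams apply their own batch norms.
* **Query/key roles in TSCross.** The layer table's textual labels
  ("time vectors as query") contradict its own printed output sizes
  (`C x 2048` for SingleT) and the classifier input sizes; the prose and
  the shapes agree with each other, so SingleT queries with channels and
  SingleC with time.
* **Block MLP sizing.** "2 FC layers [2048, 256]" is read as
  `2048 -> 256` with GELU followed by `256 -> 256`, mirroring the
  classifier's explicit `[in, out]` notation.
* **Residual connections.** A Transformer encoder conventionally has
  residuals, but a residual around the MSA alone is dimensionally
  impossible here (input `L x 256`, concat output `L x 2048`, no `W^o`).
  The package places one residual per encoder block from the block input
  to the MLP output (both `L x 256`), with `useResidual = FALSE` giving
  the strict layer-table reading. One encoder block per stream (the
  table's `x 1` multiplicity).
* **Nonlinearity.** None is named; GELU is used in the MLPs (standard for
  Transformer blocks), with default LSTM gate activations.
* **Batch-norm axis.** Normalization is per feature over the
  batch-and-length rows, the reading under which a batch of identical
  trials yields exactly zero per-feature mean (asserted in the tests).

# The autodiff engine and numerical choices

No R deep-learning backend is assumed: the package includes a dense-matrix
reverse-mode tape (`R/tape.R`) with exactly the operations the network
needs (matmul, slicing/concatenation, gathers for the relative-bias
tables, broadcasts, batch norm, row softmax, a fused
softmax-cross-entropy). Every operation's vector-Jacobian product is
verified against central finite differences in the test suite, and the
forward network agrees with independently coded plain-matrix attention
operations on shared weights. Other numerical choices: logs in the
probability-level loss are clamped at 1e-12; softmax subtracts row
maxima; Adam uses (0.9, 0.999, 1e-8) with bias correction; weight
initialization is Gaussian with s.d. `1/sqrt(fan-in)` (0.02 for position
parameters, zeros for biases, unit gain for batch-norm). Every random
draw flows through a seed derived from the recorded config seed, so
datasets are byte-identical and training runs weight-identical under the
same seed.

# The synthetic generator: what it emulates and what it does not

`generateDataset()` emulates trial-structured spike-band activity: each
class has a fixed template of smooth Gaussian bumps localized in a time
window and a channel band (smooth so that both the LSTM, which needs
temporal continuity, and channel attention, which needs spatial
structure, have signal to exploit); trials add a global temporal jitter
and i.i.d. Gaussian noise and are rectified at zero, mimicking
nonnegative band power. Defaults mirror the study conditions: 201 x 192
geometry, 26 balanced classes of 122 trials (about 3,172 total), four
bumps per class, amplitude 1, time width 8 steps, channel span 12,
jitter s.d. 2, noise s.d. 0.25. The generator does *not* claim
biophysical realism: no Poisson/refractory spiking statistics, no
electrode geometry, no cross-day nonstationarity, no class imbalance.
Consequently, passing tests demonstrate that the implementation learns
and evaluates correctly on separable class-templated data — not that the
architecture attains any particular accuracy on real recordings.

`separabilityReport()` summarizes within- and between-class trial
distances, and `nearestTemplateAccuracy()` is a brute-force
nearest-template baseline independent of the network, used as the
separability oracle in the tests.

# Problem sizes used in tests and the acceptance script

The suite exercises the full 201 x 192 x 26 geometry for shape and
probability contracts (all 7 + 4 + 6 ablation variants), and trains at a
reduced geometry chosen as the smallest that still exercises every
module: `T = 20`, `C = 8`, `N = 3`, `dModel = 32`, 2 heads, 20 trials
per class. For that geometry the high-SNR fixture uses three bumps per
class (in a 20 x 8 trial, four random bumps collide between classes often
enough to blur the templates), jitter s.d. 0.3 and noise s.d. 0.05, which
keeps the nearest-template oracle at 100% across seeds; the reduced model
reaches its training-accuracy gate within 50 epochs at learning rate 1e-3
(the published 3e-5 is tuned to the 9.4M-parameter full model and is
needlessly slow for the 31k-parameter reduced model). Cross-validation in the acceptance
script runs the same geometry with 30 epochs per fold.

# Known limitations

* Single encoder block per stream by design; no multi-layer stacks.
* No sequence-level (sentence) decoding, no comparison-model baselines,
  no t-SNE visualization — out of scope.
* The pure-R engine is CPU-bound: full-scale 400-epoch training of the
  default model is not practical here; the implementation is intended
  for correctness, inspection, and desk-scale experiments.
* Hyperparameters are taken from the published protocol; there is no
  nested cross-validation for selecting them.
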