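---
title: "Two-stream residual networks with channel attention for multimodal gesture recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stream residual networks with channel attention for multimodal gesture recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(emgfuse)
```

## The problem

Decoding hand gestures from surface electromyography (sEMG) drives
myoelectric prostheses, rehabilitation exoskeletons and gesture interfaces.
sEMG alone is noisy, non-stationary and mV-scale; modern multimodal
recordings therefore pair each EMG electrode with a tri-axial accelerometer,
so the decoder can combine the physiological signature of muscle activation
with the kinematic signature of hand motion. `emgfuse` implements a complete
decoding pipeline for recordings in the NinaPro DB2 layout — 12 EMG channels
at 2000 Hz plus 36 accelerometer channels, with per-sample gesture labels
(0 = rest, 1-49 = movements) and repetition indices (1-6) — and a synthetic
generator that emulates this layout so every stage can be exercised and
tested without external data.

## The pipeline

**Filtering.** Both streams pass a fourth-order Butterworth band-pass with a
10-500 Hz passband, the informative sEMG band. Filtering is zero-phase
(forward-backward) by default so the EMG and ACC streams stay phase-aligned;
a causal mode is available for real-time emulation. When a reduced sampling
rate makes the 500 Hz edge infeasible (Nyquist), the pipeline lowers the
upper edge to `0.45 * fs` and says so; the low-level `bandpass_filter()`
itself treats an edge at or above Nyquist as an error.

**Normalization.** Per-channel z-scores, `y = (x - mu) / sigma`, with `mu`
and `sigma` estimated on the *training* repetitions only and applied
unchanged to the test repetitions — no test-set statistics leak into the
transform. The population convention (divide by `n`) is used; at the tens of
thousands of training samples involved the difference from the sample
convention is negligible, and the choice is recorded in the `channel_stats`
object.

**Segmentation.** Sliding windows of `T` ms advanced by `S` ms convert to
samples as `L = T * F / 1000` and `Ld = S * F / 1000`; the defaults
`T = 200`, `S = 50` give 400-sample windows with 100-sample steps at
2000 Hz, inside the ~300 ms latency bound of interactive myocontrol. A
stream of `n` samples yields `floor((n - L) / Ld) + 1` windows. Windows are
labeled by majority vote over their per-sample labels, ties toward the
lower label; windows mixing rest with movement are dropped (a `strict`
policy drops any mixed window). Because the repetition-based split is
applied before segmentation and windows are cut within contiguous
same-partition runs, no window straddles the train/test boundary.

**The model.** One residual branch per modality. Each branch is a stem
convolution followed by residual stages (`y = relu(F(x) + shortcut(x))`,
where `F` is conv-BN-ReLU-conv-BN and the shortcut is the identity or a
strided 1x1 projection); the additive shortcut keeps the input gradient of
a block at identity when the residual path is null, which is what makes
deep stacks trainable, and is verified numerically in the tests. The full
preset follows the classical 18-layer layout (stages of widths
64/128/256/512, two blocks each; on a 224x224 probe the stages emit
56/28/14/7). After the stages, global average pooling collapses each
feature channel to one value; efficient channel attention (ECA) then
convolves the pooled channel vector with a single 1-D kernel of length
`k = |log2(C)/gamma + lambda/gamma|_odd` (gamma = 2, lambda = 1; C = 512
gives k = 5), squashes through a sigmoid, and rescales each channel. The
attended vectors of the two branches are concatenated and classified by a
dense head (one hidden layer, ReLU, dropout 0.5, softmax).

**Training.** One-hot cross-entropy (with a 1e-12 floor inside the
logarithm so saturated predictions cannot produce non-finite loss),
adaptive-moment optimization with decoupled weight decay 5e-4, 30 epochs of
batches of 256 at initial learning rate 1e-3. One tenth of the training
windows, stratified by class, is held out for validation; after any epoch
in which the validation loss fails to improve, the learning rate is
multiplied by 0.1 (patience 1, floor 1e-6), and the checkpoint with the
best validation accuracy is returned. The whole loop is driven by one seed.

**Evaluation.** Window-level accuracy per subject (`Acc` = correct /
total), an overall accuracy `OA` that is the *unweighted mean of
per-subject accuracies* (so subjects with more windows do not dominate),
and confusion matrices. The ablation harness re-runs the full
preprocess-train-test cycle per subject for any subset of
`{emg-only, acc-only, fused, fused-attention}` conditions and window
lengths (100/150/200/250 ms are the studied values).

## Design choices where the design was open

* **Annotation fields.** DB2 files carry both raw (`stimulus`/`repetition`)
  and movement-onset-corrected (`restimulus`/`rerepetition`) annotations.
  The reader prefers the corrected fields — the community convention for
  DB2 classification — and records the choice in the session object.
* **Rest handling.** The 49-class movement task is the default
  (`include_rest = FALSE`); the 50-class variant including rest windows is
  a flag away.
* **ECA kernel rule.** The nearest-odd form with ties broken downward is
  used (C = 64 gives 3.5, resolved to 3). The attention operates on the
  pooled length-C vector — attention after global average pooling — rather
  than re-weighting the spatial map, and the attended vector itself is the
  branch's fused-input representation.
* **Stem adaptation.** The classical 7x7-stride-2 stem assumes square
  images. Signal windows are 12 (or 36) electrode rows by hundreds of time
  samples, so for signal-shaped inputs the stem strides and pools along the
  time axis only (both axes once the electrode axis is at least 24 rows
  wide), preserving the electrode dimension; image-shaped probes (>= 64
  rows) use the original geometry, which is how the stage-size audit on a
  224x224 input reproduces 56/28/14/7.
* **Fusion operator.** Concatenation of the two attended vectors — the
  weakest assumption, preserving both branches' information — followed by
  one hidden dense layer (128 units for the full preset, 64 for small).
* **Batch normalization.** Training mode uses batch statistics; inference
  uses running averages with update momentum 0.5. The unusually high
  momentum is deliberate: at desk scale an epoch is only a handful of
  batches, and slower running averages would lag the trained weights so far
  that validation metrics (and hence the plateau schedule) would be driven
  by stale statistics rather than by learning progress.
* **Plateau monitor.** The protocol names "loss stops decreasing or
  accuracy stops increasing"; one monitor must be chosen — validation loss,
  configurable to accuracy.
* **Weight decay** is decoupled (applied directly to convolution and dense
  weights, not through the gradient); batch-norm parameters and biases are
  not decayed.
* **Small preset.** Two stages of widths 16/32 emitting a 32-vector; one
  residual block per stage, which keeps every structural element (stem,
  strided projection block, identity block, GAP, ECA) while making a full
  train/evaluate cycle a matter of minutes on one CPU.

## The synthetic generator

`synthetic_config()` lays out, per movement class, six repetitions of a
movement block followed by rest, exactly as the DB2 protocol does (5 s
movement + 3 s rest at 2000 Hz in the `"full"` preset). EMG during movement
is amplitude-modulated band-limited Gaussian noise — the standard
phenomenological model of sEMG — with a per-class, per-channel gain
pattern in which each class dominates a distinct channel triple. ACC during
movement is a class-specific sum of tones with per-channel frequencies in
12-40 Hz; the band sits *above* the 10 Hz high-pass edge specifically so
the accelerometer's class information survives the literal application of
the 10-500 Hz band-pass to both streams, and the tone amplitudes are sized
so active-block variance exceeds rest-block variance by at least 6 dB after
filtering. Everything is deterministic given the config seed and subject
id.

The `"desk"` preset reduces the rate to 500 Hz and the blocks to 2 s
movement + 1 s rest. Two seconds (rather than a minimal 1 s) is chosen so
each repetition yields 37 windows at 200 ms / 50 ms, which leaves the
repetition-based split with ~1070 training windows — enough for the
batch-256 protocol to take several optimizer steps per epoch. With these
sizes a full 30-epoch two-stream run takes roughly four minutes on one CPU.

In *split-information* mode the first half of the classes share a common
ACC pattern (separable only via EMG) and the second half share a common EMG
pattern (separable only via ACC). A single-stream model then faces a hard
information ceiling — with 8 classes, 4 fully separable plus 4
indistinguishable ones cap expected accuracy near 62.5% — while the fused
model can separate all classes. This is the designed benchmark behind the
fusion-advantage test: the margin is structural, not a tuning artifact.

What the generator does *not* emulate: physiological motor-unit
recruitment, electrode shift, fatigue drift, inter-subject variability, or
gross-movement accelerometer content below 10 Hz. Passing tests demonstrate
that the pipeline's contracts and the architecture's trainability hold on
data with the assumed statistical structure; they do not certify accuracy
levels on real recordings.

## Numerical notes

* Convolution is im2col + GEMM in compiled code; forward/backward kernels
  are verified against naive per-element loops to 1e-5 and against central
  finite differences.
* Cross-entropy floors predicted probabilities at 1e-12 inside the log.
* Batch-norm variance is computed with the population convention and floored
  at 0; epsilon 1e-5.
* Window/step conversions must land on whole samples; anything else is an
  error rather than a silent rounding.
* Degenerate inputs: streams shorter than one window give an *empty* window
  set with a warning (short rest runs are tolerated); zero-variance channels
  make normalization fail loudly, naming the channel; empty sessions,
  overlapping repetition sets and out-of-range labels are errors.
* Determinism: every stochastic step (weight init, shuffling, dropout,
  validation split, synthetic data) is derived from explicit seeds; two runs
  with the same config and seed produce identical histories and metric
  tables on a fixed BLAS/thread configuration.

## Problem sizes used by the test-suite and acceptance script

The shipped checks run the default desk-scale subject (8 classes x 6
repetitions, 500 Hz, 2 s + 1 s blocks; ~1.8k windows) for the end-to-end
recognition check, and a three-seed split-information ablation trained for
10 epochs with batch 128 — sizes chosen so the complete cycle stays within
a few minutes per run on a single CPU while leaving the qualitative
conclusions (trainability, fusion advantage) unambiguous.

## Known limitations

* The full ResNet-18 preset is provided and audited for shape correctness,
  but desk-scale training uses the small preset; reproducing full-scale DB2
  accuracies requires the real dataset and far more compute than a desk run.
* The MAT-file layer covers the numeric-matrix dialect the DB2 recordings
  use (plus character scalars), not cell arrays, structs or sparse
  matrices.
* Single-threaded determinism is the supported mode; multi-threaded BLAS
  may reorder floating-point reductions across machines.
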