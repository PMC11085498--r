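# emgfuse

Gesture recognition from synchronized surface electromyography (sEMG) and
accelerometer recordings, for researchers in myoelectric control and
biomedical signal processing. The package implements an end-to-end decoding
pipeline for multimodal recordings in the NinaPro DB2 layout (12 EMG
channels at 2000 Hz, 36 accelerometer channels, per-sample gesture labels
0–49 and repetition indices 1–6), together with a synthetic session
generator that emulates the recording protocol so the whole pipeline runs
and is tested without any external download.

## The method

Windows of both modalities are classified by a **two-stream residual
network with efficient channel attention (ECA)**:

* **Preprocessing** — fourth-order Butterworth band-pass, 10–500 Hz, applied
  to both streams; per-channel z-score `y = (x − μ)/σ` with μ, σ estimated
  on the training repetitions only; sliding-window segmentation with
  `L = T·F/1000`, `Ld = S·F/1000` (defaults `T` = 200 ms, `S` = 50 ms →
  400/100 samples at 2 kHz).
* **Model** — one residual branch per modality (`y = relu(F(x) + x)` blocks;
  the full preset follows the ResNet-18 layout, widths 64/128/256/512).
  After global average pooling `g(χ)_c = (1/WH)·Σ_ij χ_ijc`, channel
  attention weights `ω = σ(C1D_k(g(χ)))` rescale each channel, with the
  kernel length adapted to the channel count,
  `k = |log₂(C)/γ + λ/γ|_odd` (γ = 2, λ = 1; C = 512 → k = 5). The two
  attended vectors are concatenated and classified through a
  dropout-regularized dense head.
* **Training** — one-hot cross-entropy, Adam with decoupled weight decay
  5e-4, 30 epochs of batch 256 at initial learning rate 1e-3, learning rate
  ×0.1 after each validation-loss plateau (patience 1), best-validation
  checkpointing; fully seeded.
* **Evaluation** — window accuracy `Acc` per subject, overall accuracy
  `OA = (1/N)·Σ Acc` (unweighted across subjects), confusion matrices, and a
  single-stream vs fused ablation harness.

The data splits follow the repetition protocol: repetitions {1, 3, 4, 6}
train, {2, 5} test, with 1/10 of the training windows held out for
validation.

## Worked example

```r
library(emgfuse)

# a synthetic subject in the DB2 layout: 8 gesture classes x 6 repetitions,
# desk-scale preset (500 Hz, 2 s movement + 1 s rest per repetition)
cfg     <- synthetic_config("desk", seed = 42)
session <- generate_session(cfg, "S1")
session
#> <recording_session> subject S1: 144000 samples @ 500 Hz (288.0 s)
#>   emg 12 ch, acc 36 ch; 8 movement classes, repetitions 1-6; labels: corrected

# filter -> normalize (train statistics only) -> segment, repetition split
pp <- preprocess_session(session, window = window_spec(200, 50, 500))
pp$train$emg
#> <window_set> emg: 1184 windows of 12 channels x 100 samples, 8 classes

# two-stream residual network with ECA, desk-scale preset
spec <- two_stream_spec(c(12, 100, 1), c(36, 100, 1),
                        n_classes = 8, preset = "small")
fit  <- train_model(spec, pp$train, train_config(seed = 1))
ev   <- evaluate_model(fit$model, pp$test)
ev$accuracy
#> [1] 1
```

The trained two-stream model separates all eight synthetic gesture classes
on the held-out repetitions (592 test windows). On *split-information* data
— half the classes distinguishable only through EMG, half only through the
accelerometers — the ablation harness shows why fusion matters: each
single-stream model is capped near its 62.5 % information ceiling while the
fused model recovers essentially everything:

```r
cfg2 <- synthetic_config("desk", split_information = TRUE, seed = 42)
rep  <- run_ablation(list(generate_session(cfg2, "S1")),
                     conditions = c("emg-only", "acc-only", "fused"),
                     config = train_config(epochs = 10, batch_size = 128),
                     seeds = 1:3)
rep$ablation_table
#>   condition T_ms seed mean_accuracy
#> 1  acc-only  200    1     0.6317568
#> 2  emg-only  200    1     0.6368243
#> 3     fused  200    1     1.0000000
#> 4  acc-only  200    2     0.6266892
#> 5  emg-only  200    2     0.6233108
#> 6     fused  200    2     0.9966216
#> 7  acc-only  200    3     0.6250000
#> 8  emg-only  200    3     0.6283784
#> 9     fused  200    3     0.9695946
```

A command-line wrapper over the same pipeline lives in `inst/cli/emgfuse.R`
(`simulate`, `preprocess`, `train`, `evaluate`, `ablate` subcommands).

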