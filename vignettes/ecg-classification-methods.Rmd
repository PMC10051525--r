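---
title: "Methods: 1D convolutional ECG classification with EvoNorm and SE gates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 1D convolutional ECG classification with EvoNorm and SE gates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ecgnet)
```

## The problem

Electrocardiogram (ECG) interpretation involves two related classification
tasks at different time scales. At the *beat* level, each heartbeat —
windowed around its R peak and resampled to a fixed 187-sample vector — is
assigned either one of the five AAMI EC57 arrhythmia categories (N normal,
S supraventricular ectopic, V ventricular ectopic, F fusion, Q
paced/unclassifiable) or a binary normal/abnormal diagnosis
(myocardial-infarction screening). At the *rhythm* level, atrial
fibrillation (AF) is recognized from multi-second strips by its irregular
R-R intervals and absent P waves rather than by single-beat morphology.

`ecgnet` implements one network family for all three tasks, together with
the full surrounding pipeline: beat extraction from raw signals, an FIR
four-channel transform with sliding-window segmentation for the rhythm
task, class-imbalance handling, a gradient-clipped training protocol, and
confusion-matrix metrics. Because the real PhysioNet corpora (MIT-BIH
Arrhythmia, PTB Diagnostic, Challenge 2017) require downloads and
multi-hour training, the package also ships a synthetic ECG generator that
emulates all three input kinds with known ground truth; every stage is
testable offline at desk scale.

## The model

The network is a lightweight 1-D CNN (`model_config()`, `build_model()`):

```
input [L x C] -> Conv1D stem -> EvoNorm -> 4 x residual block -> flatten
             -> dense (ReLU) -> dense -> softmax / sigmoid
```

Each residual block has two paths whose outputs are merged by elementwise
multiplication:

* **Path A**: max pooling (size `pool_size`, default 2) followed by a
  kernel-1 Conv1D projection to the block's channel width.
* **Path B**: EvoNorm, dropout, a strided Conv1D (stride = `pool_size`,
  kernel `block_kernel`), then a squeeze-and-excitation gate.

Both paths emit `[floor(L / pool_size), filters_k]`; the convolution uses
total padding `kernel - stride`, which yields exactly `floor(L / stride)`
output samples for *any* input length, so the two paths always align. The
path-A projection uses kernel 1 so the alignment holds under any
`block_kernel`.

**EvoNorm** replaces the usual normalization + activation pair with a
single layer, in two variants:

* S0 (per-sample statistics, the default):
  `y = x * sigmoid(v x) / sqrt(GroupVar(x) + eps) * gamma + beta`, with the
  variance over time x channels-in-group per sample (`evo_groups = 8`).
* B0 (batch statistics):
  `y = x / max(sqrt(BatchVar + eps), v x + sqrt(InstVar + eps)) * gamma + beta`,
  with running batch variance (momentum 0.9) at inference.

S0 is the default because its statistics do not depend on the batch size,
which suits the small batches of desk-scale runs; B0 stays available behind
`evo_variant = "B0"`. One global variant is used at every normalization
site.

**Squeeze-and-excitation** computes per-channel gates: global mean over
time (squeeze), a two-layer bottleneck `C -> max(1, round(0.25 C)) -> C`
(ratio 0.25), and a sigmoid. The gate multiplies the path-B activations
channel-wise.

All forward *and backward* passes are implemented in the package (im2col
convolutions on BLAS matrix products, analytic gradients for every layer
including both EvoNorm variants). The backward passes are verified against
central finite differences in the test suite; EvoNorm-S0 is additionally
checked against an independent scalar-loop oracle.

### Architectural constants

The method pins the input geometry (187 x 1 beats; 3000 x 4 rhythm
segments), the SE ratio (0.25), and the three ablation switches (EvoNorm,
SE, gradient clipping). Filter counts, kernel sizes, dropout and head width
are not pinned anywhere, so the package declares explicit defaults and
exposes every one of them in `model_config()`:

| parameter | default | note |
|---|---|---|
| `stem_filters`, `stem_kernel` | 32, 5 | channel expansion of the input |
| `block_filters` | 64, 128, 192, 256 | one per residual block |
| `block_kernel` | 5 | path-B convolution |
| `pool_size` | 2 | temporal halving per block |
| `dropout` | 0.1 | path B only, training only |
| `head_hidden` | 64 | dense layer before the output |

"187 x 1" is treated as a fixed-length input assertion, not as image
resizing: `model_forward()` rejects inputs of any other shape.

## Losses

* Five-class task: categorical cross-entropy
  `CE = -log(exp(s_p) / sum_j exp(s_j))`, evaluated in log-sum-exp form.
* Binary diagnostic task: focal loss
  `FL = -alpha_t (1 - p_t)^gamma log(p_t)` with `alpha_t = 0.25`,
  `gamma = 2`, `p_t = p` for positives and `1 - p` otherwise.
* AF task: binary cross-entropy.

Probabilities are clamped to `[1e-7, 1 - 1e-7]`; batch reduction is the
mean. The single factor `alpha_t` multiplies the loss of *both* classes:
this keeps the exact identity `FL(gamma = 0, alpha_t = 1) = BCE`, which the
test suite asserts on random draws. (The common alternative of weighting
negatives by `1 - alpha_t` would break that identity; it can be emulated by
passing per-sample weights through the scalar API if ever needed.)

## Training protocol

`train_config()` encodes the published per-task settings:

| task preset | epochs | LR schedule | folds | loss |
|---|---|---|---|---|
| `mitbih` | 50 | 1e-3, x0.1 at epochs 20, 40 | 5 | CE |
| `ptb` | 150 | 1e-3, x0.1 at epochs 40, 120 | 10 | focal |
| `challenge2017` | 25 | 1e-3, plateau x0.9 | 75/10/15 split | BCE |
| `synthetic` | 30 | 1e-3, x0.1 at epoch 20 | 5 | CE |

Common machinery:

* **Adam** (beta defaults) with per-epoch seeded shuffling.
* **Gradient clipping by global norm**: the joint L2 norm over all
  parameter gradients is capped at 0.001; when it exceeds the threshold all
  gradients are rescaled so the post-clip norm is exactly 0.001. Clipping
  on the *global* norm (not per tensor) makes the step direction identical
  to a normalized-gradient step at this threshold. Because Adam normalizes
  by the running second moment, the tiny threshold does not stall learning.
  The `use_gc` switch disables it for ablation.
* **Oversampling**: minority classes are resampled with replacement to the
  majority count. The published protocol oversamples training *and*
  validation data; the package implements both but defaults
  `oversample_val = FALSE` so that model selection stays unbiased — set it
  to `TRUE` for the protocol-faithful variant. Test data are never
  resampled.
* **"Early stopping decay of 0.9"** (rhythm task) is ambiguous; it is
  implemented as reduce-on-plateau (factor 0.9, patience 2 epochs on
  validation accuracy) plus early stopping after 5 stalled epochs, each
  behind its own flag.
* **Checkpointing**: the best-validation-accuracy weights are returned when
  a validation set is supplied (the protocol leaves selection unstated).
* **Cross-validation**: `make_folds()` builds stratified folds (per-fold
  class counts within one of ideal); 5 folds for the arrhythmia task
  follows the experiment-setup text, although the independent-testing
  discussion also mentions 10-fold for the same data — the package exposes
  `folds` so either is one argument away. For the rhythm task,
  `split_holdout()` must be applied to *recordings* before segmentation so
  that no recording contributes segments to two sets.

Runs are bitwise reproducible for a fixed seed on single-threaded BLAS:
every stochastic element (weight init, shuffling, dropout, resampling)
draws from one seeded generator per call.

## Pre-processing

**Beat extraction** (`extract_beats()`) follows the common beat-table
recipe; the method cites it without restating the constants, so each one is
a named, overridable argument: resample to 125 Hz; cut into 10-s windows;
min-max normalize each window to [0, 1]; take local maxima with normalized
amplitude >= 0.9 as R-peak candidates under a 200-ms refractory gap (the
taller peak wins); set the nominal R-R to the window's median peak spacing;
keep `[peak, peak + 1.2 RR)` per peak, truncated or zero-padded to 187
samples. Windows with fewer than two peaks are skipped with a warning; a
flat signal therefore yields zero beats and no error. The refractory gap is
not part of the cited recipe; 200 ms prevents double-detection on wide QRS
complexes.

**Four-channel transform** (`fir_four_channel()`): zero-phase FIR band-pass
filtering (order 100, Hamming design, `signal::fir1()` +
`signal::filtfilt()`) over four sub-bands. The method names the transform
but not the bands; the defaults 0.5–5, 5–15, 15–40 and 40–100 Hz cover
P/T-wave, QRS and high-frequency content at 300 Hz sampling and are
explicit arguments.

**Segmentation** (`sliding_segments()`): length-3000 windows at offsets
`0, step, 2 step, ...`, giving `floor((n - window)/step) + 1` segments;
AF recordings use step 50 and non-AF step 500 at dataset-build time, which
rebalances the classes. Recordings shorter than one window are dropped with
a warning (whether the original study padded or dropped them is unstated).

Sample indices are 1-based throughout, the R convention; windows are
half-open in the sense that a window starting at index `s` covers
`s, ..., s + window - 1`.

## The synthetic generator

Beats are sums of five Gaussian bumps (P, Q, R, S, T) on a unit time axis —
the standard phantom-ECG construction — min-max rescaled to [0, 1] after
adding white noise. The five arrhythmia classes perturb a normal template
by fixed documented constants (`class_templates()`): S has an early P wave
and shortened pre-R interval; V has a widened QRS and no P wave; F blends N
and V; Q is flattened. The binary task's "abnormal" template has an
inverted T, deep Q and widened QRS (infarction-like). Recordings place
beats at R-R intervals drawn uniformly within a jitter band; rhythm strips
use near-constant R-R (coefficient of variation < 0.05) with P waves for
non-AF, and high-variability R-R (CV >= 0.2, rejection-sampled so every
strip certifies its class) with suppressed P waves and a small ~7 Hz
fibrillatory baseline for AF.

What this emulates — and what it does not: the generator reproduces the
*structural* properties the pipeline relies on (R-dominant morphology,
class-separable template differences, regular vs irregular rhythm), but not
clinical variability: no baseline wander, electrode artifacts, ectopy
within strips, inter-patient morphology drift, or realistic class overlap.
Passing tests therefore demonstrate that the machinery is correct and that
the training protocol converges, not that the published real-data accuracy
transfers; reproducing those numbers requires the PhysioNet corpora and
multi-hour training via the same API.

## Numerical choices

* Weight init: fan-in-scaled uniform `U(+-sqrt(6/fan_in))`, seeded.
* EvoNorm `eps = 1e-5`; probability clamp `1e-7`; group variances are the
  population form (mean of squares minus squared mean, floored at 0).
* Max pooling drops the remainder samples and routes gradients to the first
  argmax on ties.
* Zero-denominator metrics return 0 with a flag rather than an error, since
  small synthetic folds can miss a class.
* Divergence (non-finite loss) aborts training with a diagnostic rather
  than continuing silently; non-finite gradients likewise error inside
  `clip_gradients()`.

## Desk-scale problem sizes

The bundled checks and `scripts/acceptance.R` run, by design, at sizes a
laptop CPU handles in minutes: 500 training / 150 held-out five-class
beats for 30 epochs with the full default model; a 400-beat binary task for
20 epochs (milestones scaled to 8/16 accordingly); and 24 rhythm strips of
10–14 s whose segments train a narrower model (stem 8, blocks 16/24/32/48,
head 32) for 6 epochs — the full-width rhythm model is buildable and
tested for shape and gradients, but training it is left to real-data runs.
On these separable synthetic classes the full model reaches >= 95% training
and >= 80% held-out accuracy within its 30 epochs, and the four ablation
configurations (full, no-EVO, no-SE, no-GC) run to completion from one
configuration via `run_ablation()` or the `ablate` CLI command.

## Known limitations

* No multi-lead handling: Lead II (or the single provided channel) only.
* No denoising (powerline, baseline wander) before beat extraction.
* Binary WFDB annotation files (.atr) are not parsed; annotations are
  accepted as plain-text `sample,symbol` tables. Signal format 16 only.
* Multi-class focal loss and label smoothing are out of scope.
* Bitwise reproducibility assumes single-threaded BLAS; multi-threaded
  BLAS may reorder floating-point reductions.
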