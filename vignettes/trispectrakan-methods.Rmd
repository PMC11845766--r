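---
title: "Lung-sound classification with spectral fusion and Kolmogorov-Arnold networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(trispectrakan)
```

This vignette records how the pipeline is put together, which parameters
matter, where the design was genuinely open and what was decided, and
what the tests do and do not demonstrate.

## The problem

Adventitious lung sounds — crackles (short, explosive transients) and
wheezes (sustained tones of a few hundred Hz) — carry diagnostic
information about obstructive and infectious respiratory disease.
Annotated auscultation corpora such as ICBHI-2017 provide multi-cycle
recordings (10–90 s) with per-cycle start/end times, crackle/wheeze
flags, and a patient-level diagnosis over six classes: Bronchiectasis,
Bronchiolitis, COPD, Healthy, Pneumonia, URTI. The package classifies
individual respiratory cycles into these six classes.

## Preprocessing

Every recording is resampled to 22,050 Hz with a polyphase band-limited
FIR resampler (`signal::resample` behind `resample_audio()`); an
anti-aliasing filter is applied when downsampling, and sources recorded
at 4 kHz by digital stethoscopes are upsampled (content above 2 kHz
simply stays empty). Each annotated cycle is sliced out with 0-based,
half-open sample indexing (`[floor(start*rate), floor(end*rate))`), then
forced to exactly 6 s = 132,300 samples: shorter cycles are right-padded
with zeros (silence after the cycle), longer cycles keep their first
6 s. The 6-s window reflects that most respiratory cycles last about
that long; the first-6-s trim anchor keeps the inspiration onset, which
carries most of the cycle's clinical information. Amplitudes are the
wav integers normalized to [−1, 1]; there is no per-segment gain
normalization at this stage. One segment is produced per annotated cycle
(cycles are never concatenated into a shared window).

## Features

Three time–frequency representations are computed per segment, all from
the same STFT: 2,048-sample Hann window, hop 512, centered frames with
reflect padding. These settings are the unique common convention under
which a 6-s segment yields 1 + ⌊132300/512⌋ = 259 frames, which is the
time dimension the architecture expects.

* **Mel spectrogram (128 × 259)** — power spectrogram through a
  128-band triangular filterbank on the Slaney mel scale (linear below
  1 kHz, logarithmic above), area-normalized, 0–11,025 Hz, converted to
  decibels relative to the segment maximum with an 80 dB floor. A silent
  segment maps to a uniform matrix at the floor.
* **MFCC (20 × 259)** — orthonormal DCT-II of the log-mel spectrogram,
  first 20 coefficients. No delta features.
* **Chromagram (12 × 259)** — STFT power folded onto the 12 pitch
  classes (A4 = 440 Hz reference, C = bin 1), max-normalized per frame
  to [0, 1]; all-zero frames stay zero. For lung sounds the chroma folds
  wheeze fundamentals into a compact, octave-invariant signature.

Each matrix is z-scored (mean 0, sd 1 over the whole matrix) before
entering the model; this stabilizes training across heterogeneous
corpora whose absolute levels differ. The channel axis is appended last,
after normalization.

## Architecture

Three convolutional heads with identical layout but independent
parameters (no weight sharing) process the three matrices: 3×3
convolutions of 32 → 64 → 256 filters, each followed by batch
normalization and ReLU, 2×2 max pooling after the first two blocks,
global average pooling over the surviving time–frequency grid, and a
batch normalization of the resulting 256-dim embedding. One code path
serves input heights 12, 20 and 128 unchanged. The exact head internals
were an open design point; this layout reproduces the 256-dim embedding
contract for all three heads with a single implementation.

The embeddings are concatenated in fixed order (MFCC, chroma, mel) into
a 768-dim fusion vector, batch-normalized so activations sit inside the
spline grid range, and classified by a KAN of shape [768, 769, 6]. The
hidden width 769 is the selected value from the original tuning; it is
honored verbatim even though no explanation for the extra unit over the
768 fusion width is available.

### KAN layers

Each edge (i, j) carries a learnable univariate function

$$\varphi_{ij}(x) = w^{\mathrm{base}}_{ij}\,\mathrm{silu}(x) +
w^{\mathrm{spl}}_{ij} \sum_{m=1}^{G+k} c_{ijm} B_m(x),$$

with $B_m$ the degree-k B-splines on a uniform grid of G intervals over
[−1, 1], extended by k knots per side (Cox–de Boor recursion; the basis
is a partition of unity on the grid range and has compact support of
k + 1 intervals). Defaults are k = 3 (cubic; higher orders overfit
without accuracy gains in the original tuning) and G = 5 — the grid size
implied by the printed output-layer parameter count: with one base
weight and one scaler per edge and no bias, a layer holds
$n_\mathrm{in} n_\mathrm{out} (G + k + 2)$ parameters, and
769 · 6 · 10 = 46,140 forces G = 5 given k = 3.

Design points decided here:

* **Fixed grid.** The grid is never updated or extended during
  training; inputs are batch-normalized upstream, so activations stay
  near [−1, 1]. Out-of-range inputs evaluate through the extended knots
  without clamping (the basis sum simply drops below 1 outside the
  range); this is documented behaviour, not an error.
* **Initialization.** Base weights fan-in-scaled uniform, spline
  coefficients Gaussian noise (sd 0.1), scalers 1, all seeded.
* **Gradients.** Forward and backward passes are hand-written matrix
  expressions (basis values enter a single GEMM per layer); analytic
  gradients match central finite differences to better than 1e-4
  relative error in the tests.

### Baseline

The hybrid-CNN baseline shares the heads and fusion and classifies
through dense layers 768 → 750 → 250 → 75 → 25 → 6 with biases
(`dense_param_count(n_in, n_out) = n_in·n_out + n_out`), ReLU and
dropout (rate 0.3 — unspecified originally, fixed here and
configurable) between layers.

## Training protocol

Sparse categorical cross-entropy is minimized with Nadam (Adam with
Nesterov momentum, β₁ = 0.9, β₂ = 0.999) at initial learning rate
0.001, batch 32, up to 50 epochs. The learning rate is halved after 5
epochs without validation-loss improvement (floor 1e-5) and training
stops early after 10 stagnant epochs; the plateau/early-stop constants
are implementation choices — the mechanisms were prescribed, the
constants were not. All shuffling and dropout randomness derives from
the training seed, so a run is bit-reproducible on one CPU thread.

Two printed protocol statements — a 70:10:20 train/validation/test
ratio and an "80/20 via fivefold cross-validation" split — are
reconciled by stratified 5-fold partitions (80/20 outer) whose training
share is further split 87.5/12.5, giving 70/10/20 overall per fold; both
`stratified_split()` and `make_folds()` are exposed, splits are
stratified per class by largest remainder, and fold reports list
per-fold metrics alongside their mean (never a pooled-confusion
accuracy). The splitting unit is the **segment**, not the patient;
segments of one patient can land in different parts, which on real
corpora is a leakage risk. Group-by-patient splitting can be had by
splitting on patient labels and expanding to segments; the synthetic
acceptance runs use segment-level splits. No resampling or class
weights address imbalance; it is addressed only in reporting
(macro averages, per-class metrics).

Metrics follow the five standard formulas from one-vs-rest TP/TN/FP/FN
counts; zero denominators yield 0 with a warning. AUC is the
Mann–Whitney rank statistic (cross-checked against pROC in the tests).

## Numerical implementation

The network stack is implemented in the package itself with
hand-written backpropagation: no deep-learning framework is involved.
The convolutional heads run through fused single-precision C++ kernels
(im2col + BLAS sgemm, fused batch-norm/ReLU/pool) with a reusable
workspace; the KAN trunk runs in double precision in R. A
double-precision layer-by-layer reference path implements the same
operations independently and agrees with the fused path to ~1e-3 (the
float32 resolution at these batch sizes); tests compare the two routes
and check gradients of every layer type against finite differences.
Batch-norm running statistics use momentum 0.9; with mini-batches of 32
this means evaluation-mode behaviour converges to training-mode
behaviour after a few dozen steps, visible in the worked example as
validation accuracy catching up to training accuracy mid-run. One full
forward/backward pass on a batch of 32 takes a few seconds on one CPU
core (measured ~5 s on the build machine).

Ties at the prediction argmax break to the lowest class index.
Checkpoints are a flat binary of doubles plus a JSON header (variant,
seed, spline spec, class labels, tensor shapes, batch-norm running
statistics), so a saved model restores bit-identically.

## The synthetic corpus generator

`synth_corpus()` writes fully annotated corpora in the exact ICBHI
on-disk layout at a native 4 kHz (the digital-stethoscope rate), so the
pipeline's real resampling path is exercised. Breath cycles are
band-limited (100–1,800 Hz) noise with a class-specific spectral tilt
under a raised-cosine inhale/exhale envelope; crackles are ≤15 ms damped
sinusoid transients with Poisson counts; wheezes are sustained tones
plus one harmonic inside a class-specific frequency band, inserted with
a class-specific probability. Written annotations reflect exactly what
was inserted. All randomness flows from one master seed through
per-recording substreams derived by counter, so corpora are
byte-identical across regenerations.

The six default archetypes are **test fixtures, not clinical models**:
COPD is wheeze-dominated with prolonged expiration, Pneumonia and
Bronchiectasis crackle-dominated, Healthy a clean low-amplitude
envelope, Bronchiolitis and URTI intermediate mixtures with distinct
wheeze bands. Classes differ along several axes at once (crackle rate,
wheeze band, spectral tilt, cycle duration, level), which makes the
synthetic task deliberately learnable at small sample sizes. Passing
the end-to-end property (≥90% held-out accuracy after 20 epochs on a
~240-segment corpus) therefore shows that the architecture, gradients,
optimizer and protocol work as a system — it says nothing about
accuracy on real lung sounds, where class overlap, noise, recording
devices and patient-level variation dominate. The default corpus size
(2 patients per class × 2 recordings, 30–38 s each, ≈240 segments) is
the package's standard smoke-scale study; training it for 20 epochs
takes ≈8 minutes on one CPU core.

## Degenerate inputs and edge rules

* Empty signals, empty segments, non-positive rates: errors.
* Annotations overrunning the recording: clamped with a warning;
  annotations starting beyond the end: error.
* Silent segments: mel spectrogram uniformly at the −80 dB floor,
  frame-constant MFCCs, all-zero chroma; the feature extractor never
  emits NaN/Inf (silence, clipping and impulse inputs are tested).
* Orphan wavs, unreadable audio, unknown patients: skipped with a
  warning so partial corpora remain usable; an empty index is an error.
* Zero-denominator metrics: 0 with a warning.

## Known limitations

* The real-corpus performance figures reported for this architecture
  elsewhere require the original merged corpora and full-scale
  training; nothing in this package reproduces or asserts them. The
  package's empirical claims are exactly those its tests compute on
  synthetic data.
* Segment-level splitting leaks patient identity across splits (see
  above).
* The reader targets the ICBHI single-channel layout only; multichannel
  containers and bimodal (EIT) data are out of scope.
* Two printed reference values are internally inconsistent upstream
  (a dense-layer count that contradicts its own widths, and a hidden
  KAN layer count irreconcilable with any standard convention); the
  package implements the consistent conventions and documents the
  discrepancy rather than matching those two numbers.
* No noise reduction, voice-activity trimming, grid refinement,
  pruning, or symbolic spline regression.
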