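---
title: "Training and fine-tuning 12-lead ECG classifiers with ecgtune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training and fine-tuning 12-lead ECG classifiers with ecgtune}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ecgtune is a headless toolkit for classifying resting 12-lead
electrocardiograms with convolutional time-series networks. It covers the
full workflow — waveform ingestion from heterogeneous container formats,
signal normalization, model construction or import, a fixed one-command
training protocol, and a threshold-aware evaluation suite — and ships a
synthetic ECG generator with known ground truth so that every stage is
testable without access to clinical data. This vignette explains the models
and procedures, the parameters that matter, the numerical choices made where
the design was genuinely open, and what the synthetic tests do and do not
demonstrate.

## The normalization pipeline

Real-world ECG exports disagree about everything: container format, sampling
rate, lead count and order, duration, and amplitude coding. All inputs are
therefore funnelled through one fixed pipeline before they reach a model,
in this stage order:

1. **Fourier resampling** to a unified target rate, 100 Hz by default.
   The discrete spectrum is truncated (downsampling) or zero-padded
   (upsampling) to the new length `round(n * fs_out / fs_in)`; the Nyquist
   bin is folded or split so real signals stay exactly real. For
   band-limited signals this is an essentially exact operation — the test
   suite checks a pure tone against its closed form at 1e-6 — and it
   preserves per-lead RMS within 1% for in-band content. 100 Hz is the
   default because resting-ECG classification performance is known to be
   insensitive to downsampling in this range while the computational cost
   drops severalfold; the rate is configurable (`preprocess_config()`).
2. **Lead standardization** to the canonical ordered set I, II, III, aVR,
   aVL, aVF, V1–V6. Named leads are mapped case-insensitively onto their
   canonical slots; missing leads are filled with zeros; extra leads are
   dropped; unnamed leads are assigned canonical names positionally. Zeros
   rather than derived limb leads are used for missing channels: lead
   derivation is a modelling decision in its own right and is deliberately
   out of scope.
3. **Duration standardization** to 10 s: over-length recordings are cropped
   to the *first* target window and short ones zero-padded at the end. The
   crop anchor is the recording start — an arbitrary but documented choice;
   centre-cropping would be equally defensible.
4. **Gain standardization**: the signal stays in millivolt and an
   integer-coded view at 1000 ADU/mV is attached
   (`adu = round(signal_mV * 1000)`), so 1.0 mV codes as the integer 1000.

When a 2-D array arrives without orientation metadata, the axis of length
at most 16 is taken as the lead axis (resting ECGs never exceed 16 leads);
square arrays keep rows as leads. Containers that declare a gain have it
divided out on read, so every `ecg_record` is in mV. Missing sampling-rate
metadata is never guessed — the reader demands an explicit override.

## The classifier architectures

Two convolutional families operate on the standardized
`[batch x 12 x 1000]` tensor:

* **InceptionTime**: six inception modules, each combining a 1x1
  bottleneck to 32 channels, three parallel convolutions with kernels
  39/19/9, and a max-pool + 1x1 branch, concatenated to 128 channels with
  batch normalization and ReLU; residual shortcuts join every third module.
  A global average pool and a linear map produce the class logits.
* **XceptionTime**: four modules built from depthwise-separable
  convolutions (the same 39/19/9 kernel pyramid) with doubling filter
  counts — 64, 128, 256, 512 concatenated channels — and residual shortcuts
  every second module. The head average-pools the 512-channel map to 125
  time steps, reduces 512 → 256 → 128 with 1x1 convolution blocks, and a
  final 1x1 convolution plus global average pool yields the logits.

With the default hyperparameters these graphs hold roughly 401K
(XceptionTime) and 457–458K (InceptionTime) trainable parameters and cost
about 255 and 455 million multiply–accumulates for one forward pass on a
12 x 1000 input. `count_flops()` counts one fused multiply–add per
convolution or affine multiply-add and excludes pooling, normalization and
activation element operations — the convention under which these figures
are comparable across implementations. Where the architecture families
permit variants, the defaults were frozen so that both the parameter counts
and the operation counts land at these published magnitudes; in particular
the XceptionTime head pools to 125 steps (a uniform kernel-8 average pool
from 1000 samples) rather than a shorter map, and its final head stage is a
plain biased 1x1 convolution without a trailing normalization, which also
lets head replacement touch exactly one parameter group.

The classification head is always an identified, single affine map (the
final linear layer, or the final 1x1 convolution feeding the output).
`adapt_head()` replaces it — and nothing else, audited by per-group
checksums in the tests — with a freshly initialized map for a new label
set; `set_strategy()` toggles between head-only fine-tuning (backbone
frozen) and full training. Weight initialization is uniform with fan-in
scaling, driven by an explicit seed, so builds are bit-reproducible.

## Model interchange

Models are saved and loaded in the ONNX interchange format (Opset 20 and
below) with float32 weights and a dynamic batch dimension, so an exported
classifier runs at any batch size. The serializer is deterministic — no
timestamps — so exporting the same model twice, or re-exporting an
imported model, gives byte-identical files. The importer reconstructs a
fully trainable in-memory graph from the supported operator vocabulary
(Conv, BatchNormalization, Relu, MaxPool, AveragePool, GlobalAveragePool,
Gemm, Concat, Add, Flatten) and rejects anything else with an error naming
the operator; graphs declaring an Opset above 20 are refused outright. The
head of an imported graph is detected as the affine-family node (Gemm, or
Conv with kernel 1) closest to the graph output. Because the in-memory
engine itself computes in float32, an export–import round trip reproduces
the forward pass exactly; the acceptance suite still asserts the
contractual 1e-4 agreement over 100 random inputs.

## The training protocol

`fit()` runs one fixed protocol, chosen to be sensible without tuning:

* **Stratified 80/20 split.** Per class with `n_c` records the training
  side receives `round(0.8 * n_c)`, clamped to `[1, n_c - 1]`; classes with
  fewer than two records are an error. The split is deterministic given the
  master seed.
* **Class-weighted cross-entropy.** Both the training objective and the
  validation criterion weight each record by the inverse frequency of its
  class, `w_c = N / (K * n_c)`, computed on the training split; the
  per-record average of these weights is exactly 1, so loss magnitudes stay
  comparable across imbalance levels. "Weighted validation loss" means
  exactly this quantity on the evaluation split.
* **AdamW** (decoupled weight decay 0.01, betas 0.9/0.999) by default, with
  Adam and SGD-with-momentum as alternates, and a per-epoch exponential
  learning-rate decay with factor 0.9.
* **Learning-rate finder.** When no initial rate is given, an exponential
  sweep over about 100 mini-batch iterations from 1e-7 to 1 records an
  exponentially smoothed loss (smoothing factor 0.05); the chosen rate is
  the one at the smoothed-loss minimum divided by 10, clamped to
  [1e-6, 1e-1]. The sweep aborts once the smoothed loss exceeds four times
  its best value. Model and optimizer state are restored afterwards. The
  divide-by-ten rule is the standard conservative reading of the range
  test: the minimum itself sits at the edge of divergence.
* **Checkpointing and early stopping.** After each epoch the weighted
  validation loss is computed; the best checkpoint is kept and training
  stops after 10 epochs without improvement (the patience is a documented
  default — the protocol fixes the mechanism, not the number), or at 50
  epochs, whichever comes first.
* **Seeding.** One master seed deterministically derives the split,
  initialization, finder and per-epoch shuffling seeds, so a run is exactly
  reproducible on a fixed BLAS/thread configuration.

The returned report records the sample count, label distribution, base
model, per-epoch training and validation losses, the per-class F1 scores on
the evaluation split at the best epoch, the best epoch itself and the
chosen initial rate, and serializes to JSON plus a per-epoch CSV.

All tensor computation runs in float32 in compiled code: convolutions are
executed as shift-GEMM (a stride-1 same-padded convolution of kernel width
k is a sum of k plain GEMMs over shifted views), which keeps the whole
training loop within a factor of a few of BLAS peak on one CPU core.

## Evaluation

Predictions are softmax probabilities with an argmax decision; exact ties
resolve to the lowest class index. The report contains the confusion matrix
(rows = truth), per-class precision/recall/F1, weighted and macro F1
(per-class F1 defines 0/0 as 0; support-0 classes are excluded from the
weighted mean), accuracy, the multiclass Brier score (mean over records of
the summed squared error between the probability row and the one-hot
truth — conventions differ, this one is documented), top-label expected
calibration error with 10 equal-width confidence bins, per-class Fmax
threshold suggestions (exhaustive sweep over the class's observed
probabilities plus 0 and 1, ties to the lowest threshold, zero-positive
classes flagged), per-class ROC curves with trapezoidal AUC, and optional
95% bootstrap confidence intervals (percentile method, 1000 record-level
resamples, undefined resamples redrawn up to 10 times). Every one of these
is checked against an independent brute-force implementation on random
small instances in the test suite.

## Label harmonization

Cross-dataset evaluation needs labels on a common vocabulary. Built-in maps
cover the diagnostic superclasses (ICD-10 prefixes `I11`, `I51.7` → HYP;
`I21`, `I22` → MI; `I44` → CD), anterior vs inferior infarction (`I21.0` →
AMI, `I21.1` → IMI), left vs right bundle branch block (`I44.7` → LBBB,
`I45.1` → RBBB), and statement-level merges in which complete and
incomplete block variants count as their superclass (CLBBB → LBBB; CRBBB,
IRBBB → RBBB) and PhysioNet-style statements fold into conduction
disturbance or ST/T-change categories. Prefix rules match longest-first; a
record whose codes match two *different* target classes is excluded as
ambiguous rather than assigned arbitrarily (overridable). Per-patient
deduplication keeps the earliest record by acquisition time (ties broken by
record path, with a documented fallback to record order when timestamps are
absent), so no patient appears on both sides of a split.

## R-peak detection and beat analysis

A Pan–Tompkins-style detector backs the beat-level views: band-pass 5–15 Hz
(second-order Butterworth, zero-phase), differentiation, squaring, a 150 ms
moving-window integration, and an adaptive signal/noise threshold with a
200 ms refractory period; detections are refined to the local maximum of
the band-passed signal. Beat extraction windows 250 ms before to 400 ms
after each R peak (incomplete edge windows dropped); the median beat is the
pointwise per-lead median, robust to a minority of outlier beats. The
R-aligned transform resamples every RR interval linearly to the median RR
length — linear rather than spline interpolation, a simplicity choice that
is exact for the piecewise-smooth signals involved. Full fiducial-point
delineation (P/T onsets and offsets, QT measurement) is out of scope.

## The synthetic generator, and what passing tests mean

`generate_ecg()` builds each beat as a sum of Gaussian bumps (P, Q, R, S,
T) at fixed offsets around the R peak, projects the template onto the 12
leads with a fixed amplitude vector, and adds sinusoidal baseline wander
(0.1 mV at 0.25 Hz, random phase per lead) and white noise (0.05 mV). A
class is a morphology modifier: the defaults are a normal template, a
widened-QRS class (width multiplier 2.4, reduced R amplitude — a bundle
branch block caricature) and an ST-shift class (+0.25 mV between the S and
T waves — an ischaemia caricature). Heart rate is uniform in 50–100 bpm per
record with 5% RR jitter; the first beat sits at a fixed 0.3 s offset so
beat counts per rate are exact. All randomness hangs off one seed, and the
planted beat times are returned, which makes detector scoring exact rather
than approximate.

These defaults were chosen once to represent clean, clearly separable
recordings: effect sizes well above the noise floor, no pathological
rhythms, no electrode artefacts. The end-to-end test — training XceptionTime
from scratch on 300 such records and reaching a weighted F1 of at least 0.9
on the held-out split within 50 epochs — therefore demonstrates that the
whole chain (generation, writing and re-reading mixed container formats,
normalization, the training protocol, checkpointing, evaluation) is wired
correctly and can drive a modern architecture to convergence. It does *not*
demonstrate clinical-grade performance: real ECGs carry label noise,
inter-patient morphology variance, artefacts and rhythm pathology that the
generator deliberately omits, and published cross-dataset scores on real
cohorts are far below the synthetic ceiling.

## Numerical choices and degenerate inputs

* Resampling output length uses round-half-away-from-zero, fixing the
  off-by-one ambiguity; fewer than two samples is an error, not a guess.
* DAT containers quantize at the declared gain; a round trip is exact to
  half a quantization step (0.0005 mV at 1000 ADU/mV).
* Flat or too-short signals, empty beat stacks and sub-3-peak alignments
  raise typed errors (`NoBeatsDetected`) instead of returning empty
  structures.
* Batch normalization uses per-batch statistics in training and running
  statistics (momentum 0.1, unbiased variance) in inference; its epsilon is
  1e-5.
* The executor's finite-difference gradient check in the tests tolerates
  the kinks that max-pooling and ReLU place in the loss surface; agreement
  is verified at the few-percent level in float32 and was verified at 1e-5
  in a double-precision reference of the same formulas.
* Test and acceptance problem sizes — 300-record training runs, 100-input
  round-trip audits, 200-instance oracle sweeps — were sized so the whole
  suite completes in well under half an hour on a single CPU core while
  still exercising the full-size 12 x 1000 architectures.

## Known limitations

Single-label multiclass with softmax is the only objective exercised by the
tests (a sigmoid multilabel mode exists behind a flag in the loss design
but is unvalidated). The ONNX importer covers the operator vocabulary the
package itself emits — it is an interchange contract, not a general
converter; models with auxiliary non-waveform inputs must have those inputs
bound to defaults before import. DICOM and MATLAB containers are read, not
written. No GPU or multi-device path exists; the compiled core is
single-threaded apart from BLAS.
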