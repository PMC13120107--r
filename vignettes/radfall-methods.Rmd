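---
title: "Methods: the radfall pipeline, its numerics, and its synthetic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the radfall pipeline, its numerics, and its synthetic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(radfall)
```

`radfall` models a radar fall-detection system that was designed for a
small FPGA: a fixed-point STFT front end producing binary micro-Doppler
spectrograms, and a fully binarized CNN running in integer arithmetic.
This vignette explains the model, the numerical decisions behind the
bit-exact datapath, the training procedure, and what the synthetic radar
generator does and does not emulate — so that the reader knows precisely
what a passing test suite demonstrates.

## 1. The preprocessing datapath

One classification event is 1600 complex baseband samples (I + jQ). With
128-sample Hamming windows at 50% overlap this yields exactly 24 analysis
windows (`128 + 23 * 64 = 1600`), and the 128-point FFT of each window
contributes one 24-bit column to the 24 x 24 binary spectrogram.

The datapath is modeled at the level of the hardware's arithmetic:

* **Number format.** All datapath values are signed fixed point Q(16,11):
  16-bit two's-complement words with 11 fractional bits, real value =
  raw / 2^11, representable range [-16, 16). The choice of 11 fractional
  bits balances quantization noise against saturation headroom — with
  fewer integer bits the FFT's uncompensated growth saturates, with fewer
  fractional bits rounding noise dominates. `sqnr_db()` exposes the
  signal-to-quantization-noise measure used to make such comparisons.
* **Rounding.** The datapath truncates toward negative infinity (an
  arithmetic right shift), matching how a hardware multiplier discards low
  bits. ROM constants (Hamming window at Q(16,15), twiddle factors at
  Q(16,14)) are rounded to nearest once, at table-build time, as
  precomputed tables are in practice. Rounding mode is selectable in
  `quantize()`.
* **Overflow.** Every construction, product realignment, and butterfly
  add/subtract saturates to the word range rather than wrapping. Wraparound
  would silently corrupt large magnitudes — exactly the spectrogram bits
  that carry the fall signature — so saturation is the only defensible
  policy for this datapath.
* **FFT structure.** Decimation-in-time radix-2, bit-reversed input, seven
  stages for 128 points, no per-stage scaling. Headroom comes from the four
  integer bits of Q(16,11) plus input scaling; the synthetic generator's
  amplitudes are chosen so windowed spectra stay in range.
* **Magnitude.** `|Re| + |Im|` instead of the Euclidean magnitude. The
  approximation is never below the true magnitude and never above
  sqrt(2) times it; the test suite asserts this envelope elementwise on
  random inputs that stay inside the representable range (beyond full
  scale the saturation stage, not the approximation, bounds the output).
* **Band selection.** Of the 128 Doppler bins, the central 24 are kept:
  Doppler indices -12..+11, i.e. natural-order FFT bins 117..128 then
  1..12, most negative Doppler first. The source design fixes
  only the count; the symmetric-about-DC layout with the extra bin on the
  negative side is this package's convention, isolated in
  `center_bin_indices()` and recorded in the `binary_spectrogram` object
  (rows = Doppler, columns = time).
* **Binarization.** A single fixed integer threshold of 1140 raw units
  (about 0.557 real) applied to every bin, with an inclusive `>=` at the
  boundary. The threshold is the folded form of a scalar batch
  normalization learned over the whole spectrogram; the inclusive
  comparison follows the convention sign(0) = +1. The comparison happens
  in raw integer units, as a hardware comparator would.

At the defaults, a 0.8 s event therefore spans 24 x 64 ms windows hopping
by 32 ms, and the kept band covers ±187.5 Hz, i.e. roughly ±1.17 m/s of
radial velocity at 24.125 GHz. A fall's 2–3 m/s peak sweeps *through* this
band as a broadband transient; slow daily activities stay near the center
rows. That contrast is what the classifier learns.

## 2. The binarized network

The architecture family is fixed by its published parameter counts: the
first convolution is 5x5, later ones 3x3, all valid padding and stride 1,
a 2x2/stride-2 pool after every conv block, batch norm (two parameters per
channel) on every layer except the final fully connected one, and no bias
terms anywhere. This geometry is the unique member of the natural
configuration family `{kernel in {3,5,7}} x {same, valid} x {1,2,4 BN
params} x {bias on/off}` that reproduces all nine published totals; the
test suite re-verifies that uniqueness by brute-force enumeration, and
`count_parameters()` implements the closed form.

Inference is integer end to end (`bcnn_infer()`):

* a +-1 dot product over fan-in N equals 2p - N where p is the popcount of
  the XNOR of the bit patterns; `binary_conv2d()` computes exactly this,
  and a dense floating-point convolution of the decoded tensors is its
  test oracle, required to match bit for bit;
* batch norm + sign folds to one integer compare per channel. With real
  threshold T = mu - (beta/gamma) sqrt(sigma^2 + eps) and achievable
  pre-activations sharing N's parity, the decision "sign(gamma)(x - T) >=
  0" is exactly "p >= ceiling((T+N)/2)" for positive gamma and
  "p <= floor((T+N)/2)" for negative gamma. Thresholds that fall outside
  [0, N+1] are re-expressed as the equivalent always-on/always-off
  threshold so the stored integer stays in range without changing any
  achievable decision (`fold_popcount_threshold()`);
* max pooling over {-1,+1} is logical OR over bits (`or_maxpool()`);
* the final layer has no batch norm; its two raw integer scores are the
  classifier output, and a tie resolves to **non-fall**. The tie direction
  is this package's choice (the source design is silent); minimizing false
  alarms is the conservative reading for an alerting system.
* the flattening order between the last conv block and the first fully
  connected layer is channel-major, then row-major within a channel. Any
  fixed order would work; this one is frozen and recorded in the ROM
  export descriptor so software and a hardware implementation agree.

## 3. Training

Binarized networks cannot be trained by plain gradient descent — sign() has
zero gradient almost everywhere — so `bcnn_train()` uses the
straight-through estimator: latent real weights in [-1, 1] are binarized by
sign on the forward pass; gradients pass through the sign unchanged inside
the clip range and are zeroed outside, and latent weights are re-clipped
after each Adam step. The binary activation likewise passes gradients
through a hard-tanh window (|BN output| <= 1). These estimator details
follow the established binarized-network training literature; the source
design names the approach but not the internals.

The recipe: cross-entropy loss, Adam, batch size 32, 200 epochs by
default, learning rate stepped through 0.005 / 0.001 / 0.0005 / 0.0001 /
0.00005 / 0.00001 at epochs 0 / 60 / 100 / 120 / 140 / 160, dataset
shuffled once under the config seed, 80/20 train/test split. Batch norm
runs in float during training with running statistics (momentum 0.1);
after training the fold to integer thresholds is exact, and
`predict_prefold()` (the pre-fold float model) must agree with
`bcnn_infer()` (the folded integer model) on every sample — the suite
asserts zero mismatches, mirroring the exact-equivalence property of the
fold itself.

Training operates on the binary spectrograms produced by the fixed
front-end threshold; learning the input threshold jointly is not
implemented. The package trains the binary fall/non-fall task directly,
which is the deployed decision.

## 4. The synthetic radar generator

The acquisition campaign behind the original system is not public, so
`generate_dataset()` provides a physically-motivated stand-in. Each of the
twelve activity classes is a point-scatterer kinematic template: one to two
scatterers (torso, limb) with piecewise radial-velocity profiles v(t) in
m/s, a direction set, and an amplitude. The baseband signal is

    s(t) = sum_i a_i exp( j (4 pi / lambda) r_i(t) ) + n(t),

with r_i the integral of the projected velocity and n(t) complex Gaussian
noise at a configurable SNR (default 20 dB). Defaults were chosen once to
be realistic for the scene (and then left alone):

* falls peak at 1.8–2.8 m/s torso speed within 0.6 s, with a faster,
  weaker limb scatterer — the impulsive signature radar studies report;
* walking is periodic (0.5 / 0.9 m/s torso with gait modulation, plus an
  arm scatterer for fast walking); postural transitions (squat, sit,
  stand, lie) are smooth sub-1 m/s pulses;
* the ADC rate (2000 Hz) and event timing are generator parameters, not
  pipeline constants: the original acquisition's rate is unpublished, and
  the value only rescales the Doppler-bin-to-velocity map;
* `synthesize_activity()` projects velocity with the exact cosine of the
  requested direction — lateral motion at 90 degrees produces near-zero
  Doppler, as geometry dictates. The *dataset generator*, by contrast,
  draws a per-sample aspect jitter of up to ±25 degrees and floors the
  projection at the template's vertical-motion fraction, because a real
  fall is never purely transverse: the body also drops toward the floor,
  and the radar (mounted at 1.1 m) sees that component at any aspect.
  Without this, nominally lateral falls would be invisible by
  construction, which no real radar dataset shows;
* scatterer amplitudes are expressed in the real units of the Q(16,11)
  datapath and were calibrated once, against the fixed threshold of 1140,
  so that typical spectrogram magnitudes straddle the threshold; they are
  frozen in `sim_config()` defaults. Without that calibration the
  spectrograms would be degenerately all-zero or all-one and every
  downstream claim would be vacuous;
* synthetic subjects 1–5 are assigned cyclically with per-subject velocity
  multipliers (0.9–1.1), giving leave-one-subject-out folds mild but real
  heterogeneity.

The default per-class counts reproduce the published campaign's class
proportions (2570 frames, e.g. twice as many lateral standing falls as
forward ones); `synthetic_corpus()` draws a balanced 40-per-class,
480-frame corpus at seed 0, which is the size used throughout the test
suite and examples — large enough for stable accuracy estimates, small
enough that the whole suite trains a network from scratch in minutes.

**What the generator does not emulate** — and therefore what passing tests
do *not* show about real data: electromagnetic scattering and body shape,
antenna patterns, multipath and clutter, RF interference, range migration
(a CW radar has no range axis), sensor nonidealities (phase noise, DC
offset, IQ imbalance), and genuinely diverse human kinematics. The
92.7% held-out accuracy printed in the README is a property of this
synthetic corpus, not a reproduction of the published 96.1% on the real
campaign; the package's claim is that the *pipeline* — datapath, fold,
training loop, evaluation protocol — behaves exactly as specified, with
the corpus serving as a controlled, separable workload (a row-energy
logistic baseline also separates it, which the suite checks as a control).

## 5. Numerical edge cases and conventions

* Out-of-range values saturate on construction everywhere; nothing raises
  on overflow. Errors are reserved for structural violations (shape
  mismatches, invalid formats, empty or single-class datasets, Nyquist
  violations in the generator, malformed files — the latter reported with
  the offending line).
* `quantize()`'s truncation is floor(), i.e. toward negative infinity,
  consistent with an arithmetic right shift of two's-complement raws.
* Pooling tie-breaks (training-time gradient routing) go to the top-left
  element; forward results are tie-independent since OR is associative.
* The spectrogram's DC row is row 13 of 24 (0-based 12); the mapping is
  frozen in `center_bin_indices()`.
* Random state: `bcnn_train()`, `generate_dataset()` and
  `synthesize_activity()` seed locally and restore the caller's RNG state
  on exit, so library calls never perturb a session's reproducibility.
* Fixed- vs float-datapath disagreement is confined to threshold-crossing
  bins; on the seed-0 corpus fewer than 5% of spectrogram bits differ, and
  the suite asserts that bound on a subsample (60 of 480 frames).

## 6. Problem sizes used by the test suite

The suite trains the deployed architecture (conv 32,32,32; fc 32,2) for 60
epochs on the 480-frame seed-0 corpus — the point on the
accuracy-versus-time curve where the binary test accuracy comfortably
clears 0.90 while a from-scratch run of the whole suite stays in the
minutes range. Cross-validation tests use a reduced 48-frame two-class
subset with a small (conv 4; fc 2) network: they verify protocol
correctness (stratification, subject-grouped folds, metric aggregation),
not peak accuracy. The million-draw batch-norm fold check and the
100-instance oracle-equivalence suites run at full size, as they are fast.

## 7. Known limitations

* Single-scalar preprocessing batch norm (one global threshold), matching
  the deployed design; per-bin thresholds are not implemented.
* No multi-bit quantization, pruning, or distillation; the model family is
  strictly 1-bit.
* The float training loop is plain R with BLAS matrix products; it is
  sized for the desk-scale corpora above, not for large-scale training.
* A fixed binarization threshold limits robustness to distance and
  environment changes — adaptive thresholding or AGC would be the natural
  extension, as would FMCW sensing for range information.
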