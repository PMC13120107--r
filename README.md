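# radfall

Radar-based fall detection with a binarized convolutional neural network,
modeled bit-exactly down to the fixed-point arithmetic of its hardware
implementation.

## The problem

Falls among elderly people living alone demand continuous indoor
monitoring, and continuous-wave (CW) Doppler radar is an attractive sensor
for it: unlike cameras it preserves privacy and works in the dark, and
unlike wearables it needs no user compliance. A CW radar observes a falling
body as a short, impulsive micro-Doppler signature — the torso and limbs
briefly sweep through radial velocities of 2–3 m/s — while everyday
activities (walking, sitting, squatting, lying down) produce slower or
periodic signatures. Running the classifier on a low-power edge device,
however, rules out floating-point deep networks; the design modeled here
uses a fixed-point STFT front end and a fully binarized network whose
inference is nothing but XNOR, popcount, integer compare and OR.

`radfall` is a behavioral model of that system for people who want to
study, verify or extend it in software: every intermediate of the hardware
datapath is reproduced bit-exactly, and a seeded synthetic radar generator
stands in for the (non-public) acquisition campaign so the whole pipeline
runs self-contained.

## The model

**Front end (preprocessing unit).** A classification event is 1600 complex
baseband samples x[n]. The short-time Fourier transform

    X(m, k) = sum_n x[n] w[n - m] e^(-i 2 pi k n / N),   N = 128

uses a Hamming window w of length 128 with 50% overlap, giving 24 analysis
windows. The FFT is a radix-2, 7-stage fixed-point transform in Q(16,11)
(16-bit words, 11 fractional bits) with saturating arithmetic and quantized
twiddle/window ROMs. Magnitudes use the square-root-free approximation

    |X| ~ |Re X| + |Im X|,

which lies within [1, sqrt(2)] times the true magnitude. Only the central
24 Doppler bins (-12..+11) are kept, and each is compared against a fixed
integer threshold of 1140 raw units — the folded form of a learned batch
normalization followed by sign, using

    sign(BN(x)) = +1  iff  sign(gamma) * (x - T) >= 0,
    T = mu - (beta / gamma) * sqrt(sigma^2 + eps).

The result is a 24 x 24 single-bit spectrogram per event.

**Classifier (neural network unit).** A binarized CNN: weights and
activations are constrained to {+1, -1} and stored as bits. Convolutions
(first 5x5, later 3x3, valid padding) become XNOR + popcount — the +-1 dot
product over fan-in N is 2p - N for agreement count p — batch norm + sign
becomes an integer popcount-threshold compare per channel, and 2x2
max-pooling becomes logical OR. The deployed architecture
(conv 32,32,32; fc 32,2) has 20,576 parameters and packs into 2.5 KB.
Training uses latent real weights with straight-through-estimator
gradients, Adam, cross-entropy, and a stepped learning-rate schedule; after
training, batch norm is folded into integer thresholds with exact
functional equivalence.

**Synthetic data.** Twelve activity classes (five fall, seven non-fall) are
emulated as point-scatterer CW baseband signals: class-specific radial
velocity profiles, direction sets {0, +-90, 180} degrees with aspect
jitter, 24.125 GHz carrier, additive complex Gaussian noise, and synthetic
subject identities for leave-one-subject-out evaluation. Everything is
deterministic under a seed.

## Worked example

```r
library(radfall)

spec <- network_spec(c(32, 32, 32), c(32, 2))   # the selected architecture
spec
#> <network_spec: conv 32,32,32 | fc 32,2 | 20,576 parameters>
model_size_bytes(spec)
#> [1] 2572

ds    <- synthetic_corpus(n_per_class = 40, seed = 0)  # 480 frames
specs <- preprocess_frames(ds)                  # fixed-point PPU datapath
model <- bcnn_train(specs, ds$labels, spec,
                    train_config(epochs = 60, seed = 1))
model$meta$test_accuracy
#> [1] 0.927

out <- bcnn_infer(model, specs[, , 1])          # integer-only inference
out$class; out$scores
#> [1] "fall"
#>    fall nonfall
#>       0      -2
```

The 480-frame corpus is generated at seed 0, preprocessed through the
bit-exact Q(16,11) front end, and the binarized network is trained for 60
epochs on a shuffled 80/20 split. The folded integer model classifies the
held-out 96 frames at 92.7% accuracy; the two scores are raw popcount-
domain integers from the final layer, and ties resolve to non-fall.

A command-line surface over the same functions lives at
`inst/scripts/radfall_cli.R` (subcommands `simulate`, `preprocess`,
`train`, `infer`, `count-params`, `export-rom`, `evaluate`, `run-all`).

## Scope

The package models the numerical behavior of the system, not its physical
realization: RTL, AXI bus transactions, memory timing, FPGA resource and
power figures are out of scope, as is range processing (CW radar has no
range axis). The synthetic generator is a labeled stand-in for real
measurements, not an electromagnetic simulation; see the methods vignette
(`vignettes/radfall-methods.Rmd`) for what it does and does not emulate.
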