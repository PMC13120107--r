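Package: radfall
Title: Binarized-CNN Radar Fall Detection with a Bit-Exact Fixed-Point STFT Front End
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Behavioral model of a continuous-wave radar fall-detection
    pipeline built for low-power hardware. Provides signed Q-format
    fixed-point arithmetic with saturation, a bit-exact 128-point radix-2
    fixed-point FFT, Hamming-windowed STFT preprocessing that produces 24x24
    binary micro-Doppler spectrograms via approximate magnitude and threshold
    binarization, a binarized convolutional neural network (XNOR/popcount
    inference, OR-pooling, batch-norm folding to integer popcount
    thresholds), straight-through-estimator training, k-fold and
    leave-one-subject-out evaluation, a seeded synthetic CW-radar baseband
    generator emulating twelve fall and non-fall activities, and text-based
    interchange formats (I/Q CSV, PBM spectrograms, JSON model descriptors,
    hex ROM images).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
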