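fmt11 <- qformat(16, 11)

test_that("fixed-point FFT handles impulse and zero inputs exactly", {
  x <- fixed_array(c(2048, rep(0, 127)), fmt11, raw_im = rep(0, 128))
  y <- fft_fixed(x)
  expect_true(all(y$raw == 2048))    # DFT of a delta is flat
  expect_true(all(y$raw_im == 0))
  z <- fixed_array(rep(0, 128), fmt11, raw_im = rep(0, 128))
  yz <- fft_fixed(z)
  expect_true(all(yz$raw == 0) && all(yz$raw_im == 0))
  expect_error(fft_fixed(fixed_array(rep(0, 100), fmt11,
                                     raw_im = rep(0, 100))),
               "power of two")
})

test_that("fixed-point FFT tracks the float DFT above 40 dB SQNR", {
  set.seed(21)
  for (rep_i in 1:5) {
    z <- complex(real = runif(128, -0.5, 0.5),
                 imaginary = runif(128, -0.5, 0.5))
    x <- quantize(z, fmt11)
    got <- dequantize(fft_fixed(x))
    ref <- stats::fft(dequantize(x))   # float-precision oracle
    expect_gt(sqnr_db(c(Re(ref), Im(ref)), c(Re(got), Im(got))), 40)
  }
})

test_that("Hamming ROM matches the cosine formula and is symmetric", {
  h <- hamming_rom(128)
  w_real <- 0.54 - 0.46 * cos(2 * pi * (0:127) / 127)
  expect_lt(abs(dequantize(h)[1] - 0.08), 2^-15)
  expect_true(all(abs(dequantize(h) - w_real) < 2^-15))
  expect_identical(h$raw, rev(h$raw))              # w[k] == w[n-1-k]
  expect_identical(h$raw[64], h$raw[65])           # equal central pair
  expect_error(hamming_rom(1), "n must be >= 2")
})

test_that("approximate magnitude is |Re|+|Im| and within the sqrt(2) envelope", {
  m <- magnitude_approx(fixed_array(6144, fmt11, raw_im = 8192))  # 3 + 4i
  expect_equal(m$raw, 14336)                       # 7.0, exact gives 5.0
  mr <- magnitude_approx(fixed_array(-4096, fmt11, raw_im = 0))
  expect_equal(mr$raw, 4096)                       # reduces to |x|
  set.seed(5)
  z <- complex(real = runif(300, -7, 7), imaginary = runif(300, -7, 7))
  q <- quantize(z, fmt11)
  approx <- dequantize(magnitude_approx(q))
  exact <- Mod(dequantize(q))                      # sqrt(re^2 + im^2) oracle
  nz <- exact > 0
  ratio <- approx[nz] / exact[nz]
  expect_true(all(ratio >= 1 - 1e-12 & ratio <= sqrt(2) + 1e-12))
})

test_that("central-bin selection keeps Doppler -12..+11 in order", {
  ramp <- fixed_array(0:127, qformat(16, 4))
  kept <- select_center_bins(ramp, 24)
  expect_equal(kept$raw, c(116:127, 0:11))         # natural-order indices
  # n_keep = n reduces to a full fftshift
  full <- select_center_bins(ramp, 128)
  expect_equal(full$raw, c(64:127, 0:63))
  # DC-only spectrum: bin 0 lands at centered position 13 (0-based 12)
  onehot <- fixed_array(c(100, rep(0, 127)), fmt11)
  kept1 <- select_center_bins(onehot, 24)
  expect_identical(which(kept1$raw != 0), 13L)
  expect_error(select_center_bins(ramp, 23), "even")
  expect_error(center_bin_indices(128, 130), "exceeds")
})

test_that("binarization is inclusive at the threshold", {
  expect_identical(binarize_column(fixed_array(1140, fmt11), 1140), 1L)
  expect_identical(binarize_column(fixed_array(1139, fmt11), 1140), 0L)
  expect_identical(binarize_column(fixed_array(rep(0, 24), fmt11), 1140),
                   rep(0L, 24))
})

test_that("batch-norm fold produces the closed-form threshold", {
  eps <- 1e-5
  f1 <- fold_bn_to_threshold(1, 0, 0, 1 - eps, eps)
  expect_equal(f1$threshold, 0)
  expect_equal(f1$gamma_sign, 1)
  f2 <- fold_bn_to_threshold(2, 1, 3, 4 - eps, eps)
  expect_equal(f2$threshold, 2)                    # 3 - (1/2)*2
  expect_error(fold_bn_to_threshold(0, 1, 0, 1), "gamma")
})

test_that("thresholding is exactly equivalent to batch norm plus sign", {
  set.seed(31)
  n <- 20000
  x <- runif(n, -20, 20)
  gamma <- runif(n, -3, 3); gamma[abs(gamma) < 1e-3] <- 1
  beta <- runif(n, -2, 2); mu <- runif(n, -5, 5); s2 <- runif(n, 0, 9)
  f <- fold_bn_to_threshold(gamma, beta, mu, s2)
  thresholded <- ifelse(f$gamma_sign * (x - f$threshold) >= 0, 1, -1)
  expect_identical(thresholded, oracle_bn_sign(x, gamma, beta, mu, s2))
})

test_that("spectrogram pipeline maps tones to the right Doppler rows", {
  cfg <- stft_config()
  zero <- radar_frame(complex(real = rep(0, 1600), imaginary = rep(0, 1600)))
  expect_true(all(stft_binary_spectrogram(zero, cfg)$bits == 0))

  # tone at Doppler bin +5: row 18 (= 13 + 5) all ones, rows >= 2 away clear
  sp_pos <- stft_binary_spectrogram(tone_frame(5, 0.1), cfg)
  expect_true(all(sp_pos$bits[18, ] == 1))
  far <- setdiff(1:24, 16:20)
  expect_true(all(sp_pos$bits[far, ] == 0))

  # mirrored tone flips to row 8 (= 13 - 5)
  sp_neg <- stft_binary_spectrogram(tone_frame(-5, 0.1), cfg)
  expect_true(all(sp_neg$bits[8, ] == 1))
  expect_true(all(sp_neg$bits[setdiff(1:24, 6:10), ] == 0))

  expect_error(stft_binary_spectrogram(tone_frame(5, 0.1, n = 1000), cfg),
               "geometry")
})

test_that("spectrograms are deterministic and monotone in amplitude", {
  fr <- tone_frame(3, 0.05)
  s1 <- stft_binary_spectrogram(fr)
  s2 <- stft_binary_spectrogram(fr)
  expect_identical(s1$bits, s2$bits)
  # doubling the amplitude can only add bits (no saturation at these levels)
  s_big <- stft_binary_spectrogram(tone_frame(3, 0.1))
  expect_true(all(s_big$bits >= s1$bits))
})

test_that("fixed and float datapaths agree on most spectrogram bits", {
  cp <- corpus_480()
  idx <- seq(1, 480, by = 8)                       # 60-frame subsample
  n_diff <- 0L
  for (i in idx) {
    fx <- cp$specs[, , i]
    fl <- stft_binary_spectrogram(cp$ds$frames[[i]],
                                  arithmetic = "float")$bits
    n_diff <- n_diff + sum(fx != fl)
  }
  expect_lt(n_diff / (length(idx) * 576), 0.05)
})
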