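# Independent reference implementations used as oracles, plus a session
# cache for the expensive shared fixtures (the seed-0 corpus and the
# trained model).

# dense float convolution of +-1 decoded tensors (nested loops, no im2col)
oracle_conv_pm1 <- function(input_bits, weight_bits) {
  pm <- function(b) 2 * b - 1
  if (is.matrix(input_bits)) dim(input_bits) <- c(dim(input_bits), 1L)
  x <- pm(input_bits)
  w <- pm(weight_bits)
  k <- dim(w)[1]
  ho <- dim(x)[1] - k + 1L
  wo <- dim(x)[2] - k + 1L
  out <- array(0, dim = c(ho, wo, dim(w)[4]))
  for (co in seq_len(dim(w)[4])) {
    for (i in seq_len(ho)) {
      for (j in seq_len(wo)) {
        out[i, j, co] <- sum(x[i:(i + k - 1), j:(j + k - 1), ] * w[, , , co])
      }
    }
  }
  out
}

# float max pooling of a +-1 decoded bit tensor, 2x2 stride 2
oracle_maxpool_pm1 <- function(bits) {
  if (is.matrix(bits)) dim(bits) <- c(dim(bits), 1L)
  x <- 2 * bits - 1
  d <- dim(x)
  ho <- d[1] %/% 2L; wo <- d[2] %/% 2L
  out <- array(0, dim = c(ho, wo, d[3]))
  for (c in seq_len(d[3])) {
    for (i in seq_len(ho)) {
      for (j in seq_len(wo)) {
        out[i, j, c] <- max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c])
      }
    }
  }
  out
}

# batch norm followed by sign, elementwise (the unfolded reference)
oracle_bn_sign <- function(x, gamma, beta, mu, sigma2, eps = 1e-5) {
  y <- gamma * (x - mu) / sqrt(sigma2 + eps) + beta
  ifelse(y >= 0, 1, -1)
}

# float-precision spectrogram magnitudes (exact magnitude, no binarization)
oracle_float_magnitudes <- function(samples, cfg = stft_config()) {
  n <- cfg$window_len
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  out <- matrix(0, nrow = n, ncol = cfg$n_columns)
  for (m in seq_len(cfg$n_columns)) {
    seg <- samples[((m - 1) * cfg$hop + 1):((m - 1) * cfg$hop + n)]
    out[, m] <- Mod(stats::fft(seg * w))
  }
  out
}

# a pure complex tone at a given Doppler bin (bin in cycles per 128 samples)
tone_frame <- function(bin, amplitude, n = 1600, fs = 2000) {
  tt <- 0:(n - 1)
  radar_frame(amplitude * exp(2i * pi * bin * tt / 128), sample_rate_hz = fs)
}

# ---- shared fixture cache --------------------------------------------------

.radfall_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.radfall_cache[[key]])) .radfall_cache[[key]] <- expr
  .radfall_cache[[key]]
}

# the standard 480-frame seed-0 corpus, preprocessed through the fixed
# datapath
corpus_480 <- function() {
  cached("corpus480", {
    ds <- synthetic_corpus(n_per_class = 40L, seed = 0L)
    list(ds = ds, specs = preprocess_frames(ds$frames),
         labels = ds$labels, subjects = ds$subject_id)
  })
}

# Network 8 trained for 60 epochs on the seed-0 corpus
model_net8_60 <- function() {
  cached("model60", {
    cp <- corpus_480()
    bcnn_train(cp$specs, cp$labels, network_spec(c(32, 32, 32), c(32, 2)),
               train_config(epochs = 60L, seed = 1L))
  })
}

# small random model for a given spec (random bits, random folded BN)
random_model <- function(spec, seed = 1) {
  set.seed(seed)
  weights <- list(); bn <- list()
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    wdim <- if (ly$type == "conv") c(ly$kernel, ly$kernel, ly$c_in, ly$c_out)
            else c(ly$f_in, ly$f_out)
    weights[[i]] <- array(rbinom(prod(wdim), 1, 0.5), dim = wdim)
    if (ly$bn) {
      nch <- if (ly$type == "conv") ly$c_out else ly$f_out
      n_fan <- if (ly$type == "conv") ly$kernel^2 * ly$c_in else ly$f_in
      bn[[i]] <- list(gamma_sign = sample(c(-1, 1), nch, replace = TRUE),
                      popcount_threshold = sample(0:(n_fan + 1), nch,
                                                  replace = TRUE))
    } else bn[i] <- list(NULL)
  }
  bcnn_model(spec, weights, bn)
}
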