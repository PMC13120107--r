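#' STFT preprocessing configuration
#'
#' Geometry and numeric constants of the spectrogram front end: 128-sample
#' Hamming windows, 50% overlap (hop 64), 128-point fixed-point FFT at
#' Q(16,11), the central 24 Doppler bins kept, and threshold binarization at
#' a fixed raw threshold of 1140 (about 0.557 in real units at Q(16,11)),
#' the value folded from the learned preprocessing batch-norm.
#'
#' @param window_len samples per analysis window.
#' @param hop window advance in samples (`window_len / 2` for 50% overlap).
#' @param n_columns number of STFT columns per classification event.
#' @param n_kept_bins number of central Doppler bins kept (even).
#' @param fmt datapath [qformat].
#' @param threshold_raw binarization threshold in raw integer units of `fmt`.
#' @return an object of class `stft_config`.
#' @export
stft_config <- function(window_len = 128L, hop = 64L, n_columns = 24L,
                        n_kept_bins = 24L, fmt = qformat(16L, 11L),
                        threshold_raw = 1140L) {
  stopifnot(inherits(fmt, "qformat"))
  if (hop != window_len %/% 2L) stop("hop must be window_len/2 (50% overlap)")
  if (n_kept_bins > window_len) stop("cannot keep more bins than FFT points")
  structure(list(window_len = as.integer(window_len),
                 fft_points = as.integer(window_len),
                 hop = as.integer(hop),
                 n_columns = as.integer(n_columns),
                 n_kept_bins = as.integer(n_kept_bins),
                 fmt = fmt,
                 threshold_raw = as.numeric(threshold_raw)),
            class = "stft_config")
}

#' Samples per classification event under a config
#' @param cfg an [stft_config].
#' @return integer frame length (1600 for the defaults).
#' @export
frame_length <- function(cfg = stft_config()) {
  cfg$window_len + (cfg$n_columns - 1L) * cfg$hop
}

#' One raw radar classification event
#'
#' A complex baseband (I + jQ) sample stream covering one classification
#' event: 1600 samples under the default geometry (24 windows of 128 with
#' hop 64).
#'
#' @param samples complex vector of baseband samples.
#' @param sample_rate_hz ADC sample rate (generator metadata).
#' @param label optional activity code `"a"`..`"l"`.
#' @param subject_id optional integer subject identifier (for LOSO splits).
#' @return an object of class `radar_frame`.
#' @export
radar_frame <- function(samples, sample_rate_hz = 2000, label = NULL,
                        subject_id = NULL) {
  if (!is.complex(samples)) stop("samples must be complex (I + jQ)")
  structure(list(samples = samples, sample_rate_hz = sample_rate_hz,
                 label = label, subject_id = subject_id),
            class = "radar_frame")
}

#' @export
print.radar_frame <- function(x, ...) {
  cat(sprintf("<radar_frame: %d samples @ %g Hz%s%s>\n", length(x$samples),
              x$sample_rate_hz,
              if (!is.null(x$label)) paste0(", label ", x$label) else "",
              if (!is.null(x$subject_id)) paste0(", subject ", x$subject_id)
              else ""))
  invisible(x)
}

#' Quantized Hamming window ROM
#'
#' Symmetric Hamming coefficients `w[k] = 0.54 - 0.46*cos(2*pi*k/(n-1))`,
#' `k = 0..n-1`, quantized to a ROM format. Stored at Q(16,15) by default
#' (the coefficients lie in `[0.08, 1)`), rounded to nearest as ROM
#' constants are.
#'
#' @param n window length (>= 2).
#' @param fmt ROM [qformat].
#' @return real [fixed_array] of length `n`.
#' @export
hamming_rom <- function(n = 128L, fmt = qformat(16L, 15L)) {
  n <- as.integer(n)
  if (n < 2L) stop("hamming_rom: n must be >= 2")
  k <- 0:(n - 1L)
  w <- 0.54 - 0.46 * cos(2 * pi * k / (n - 1L))
  quantize(w, fmt, rounding = "round_half_up")
}

#' Absolute-value magnitude approximation
#'
#' Replaces `sqrt(Re^2 + Im^2)` by `|Re| + |Im|`, the square-root-free
#' approximation used in the hardware binarization block. The result always
#' lies in `[1, sqrt(2)]` times the exact magnitude. Output saturates to the
#' input format.
#'
#' @param spectrum complex [fixed_array].
#' @return real [fixed_array] of approximate magnitudes.
#' @examples
#' m <- magnitude_approx(quantize(complex(real = 3, imaginary = 4) / 8,
#'                                qformat(16, 11)))
#' dequantize(m) * 8  # 7, where the exact magnitude is 5
#' @export
magnitude_approx <- function(spectrum) {
  stopifnot(inherits(spectrum, "fixed_array"))
  if (!spectrum$is_complex) stop("magnitude_approx expects complex input")
  fixed_array(saturate_raw(abs(spectrum$raw) + abs(spectrum$raw_im),
                           spectrum$fmt),
              spectrum$fmt)
}

#' Indices of the central Doppler bins of a natural-order spectrum
#'
#' For an `n`-point FFT in natural order (bin 1 = DC), returns the 1-based
#' indices of the `n_keep` bins centered on DC, most negative Doppler first:
#' frequencies `-n_keep/2 .. n_keep/2 - 1` cycles. For `n = 128`,
#' `n_keep = 24` this is FFT bins 117..128 followed by 1..12 (Doppler
#' -12..+11), so DC lands at output position 13.
#'
#' @param n spectrum length.
#' @param n_keep even number of bins to keep, `<= n`.
#' @return integer vector of length `n_keep`.
#' @export
center_bin_indices <- function(n = 128L, n_keep = 24L) {
  n <- as.integer(n); n_keep <- as.integer(n_keep)
  if (n_keep %% 2L != 0L) stop("n_keep must be even")
  if (n_keep > n) stop("n_keep exceeds spectrum length")
  c((n - n_keep %/% 2L + 1L):n, 1:(n_keep %/% 2L))
}

#' Select the central Doppler bins of a spectrum
#'
#' @param spectrum a [fixed_array] of length `n` in natural FFT order.
#' @param n_keep even number of central bins to keep.
#' @return a [fixed_array] of length `n_keep`, most negative Doppler first.
#' @export
select_center_bins <- function(spectrum, n_keep = 24L) {
  stopifnot(inherits(spectrum, "fixed_array"))
  idx <- center_bin_indices(length(spectrum), n_keep)
  fixed_array(spectrum$raw[idx], spectrum$fmt,
              raw_im = if (spectrum$is_complex) spectrum$raw_im[idx])
}

#' Threshold binarization of a magnitude column
#'
#' Bit = 1 iff the raw magnitude is `>= threshold_raw` (inclusive, matching
#' the sign-of-batch-norm convention where the boundary maps to +1 for
#' positive gamma); 0 otherwise. Comparison is in raw integer units.
#'
#' @param magnitudes real [fixed_array] (or raw numeric vector).
#' @param threshold_raw integer threshold in raw units.
#' @return integer 0/1 vector.
#' @export
binarize_column <- function(magnitudes, threshold_raw = 1140L) {
  raw <- if (inherits(magnitudes, "fixed_array")) magnitudes$raw
         else magnitudes
  as.integer(raw >= threshold_raw)
}

#' Fold batch normalization plus sign into a threshold
#'
#' Batch norm followed by the sign function is exactly a threshold
#' comparison: `sign(BN(x)) = +1` iff `sign(gamma) * (x - T) >= 0` with
#' `T = mu - (beta / gamma) * sqrt(sigma2 + eps)`. The fold is exact — for
#' every input the thresholded output equals the sign of the batch-norm
#' output, with no element-wise mismatch.
#'
#' @param gamma,beta learned batch-norm scale and shift (`gamma != 0`).
#' @param mu,sigma2 running mean and variance.
#' @param eps numerical-stability constant (default `1e-5`).
#' @return list with `threshold` (real T) and `gamma_sign` (+1 or -1).
#' @export
fold_bn_to_threshold <- function(gamma, beta, mu, sigma2, eps = 1e-5) {
  if (any(gamma == 0)) stop("fold_bn_to_threshold: gamma must be nonzero")
  if (any(sigma2 < 0)) stop("fold_bn_to_threshold: sigma2 must be >= 0")
  list(threshold = mu - (beta / gamma) * sqrt(sigma2 + eps),
       gamma_sign = ifelse(gamma > 0, 1, -1))
}

#' Binary micro-Doppler spectrogram
#'
#' 24 x 24 single-bit time-frequency map: rows are Doppler bins (row 1 =
#' most negative Doppler after centering), columns are STFT window index in
#' increasing time.
#'
#' @param bits integer 0/1 matrix, Doppler x time.
#' @return an object of class `binary_spectrogram`.
#' @export
binary_spectrogram <- function(bits) {
  bits <- as.matrix(bits)
  if (!all(bits %in% c(0L, 1L))) stop("spectrogram bits must be 0/1")
  storage.mode(bits) <- "integer"
  structure(list(bits = bits,
                 row_order = "doppler: most negative first",
                 col_order = "time: window index increasing"),
            class = "binary_spectrogram")
}

#' @export
print.binary_spectrogram <- function(x, ...) {
  cat(sprintf("<binary_spectrogram %dx%d (Doppler x time), %d bits set>\n",
              nrow(x$bits), ncol(x$bits), sum(x$bits)))
  invisible(x)
}

#' Full STFT preprocessing: raw frame to binary spectrogram
#'
#' The behavioral model of the preprocessing unit. For each of the
#' `n_columns` windows: take the next `window_len` samples (50% overlap),
#' quantize to the datapath format, multiply by the Hamming ROM, run the
#' fixed-point FFT, form approximate magnitudes, keep the central
#' `n_kept_bins` Doppler bins, and compare against the fixed raw threshold.
#' Column `m` of the output holds window `m`'s bits. Fully deterministic.
#'
#' With `arithmetic = "float"` the same dataflow runs in double precision
#' with the exact magnitude replaced by the same `|Re| + |Im|` approximation,
#' the reference the fixed datapath is compared against in validation.
#'
#' @param frame a [radar_frame] (or complex vector) matching the config
#'   geometry.
#' @param cfg an [stft_config].
#' @param arithmetic `"fixed"` (bit-exact datapath) or `"float"` (double
#'   precision reference).
#' @return a [binary_spectrogram].
#' @export
stft_binary_spectrogram <- function(frame, cfg = stft_config(),
                                    arithmetic = c("fixed", "float")) {
  arithmetic <- match.arg(arithmetic)
  samples <- if (inherits(frame, "radar_frame")) frame$samples else frame
  if (!is.complex(samples)) stop("frame samples must be complex")
  need <- frame_length(cfg)
  if (length(samples) != need) {
    stop("frame length ", length(samples), " does not match config geometry (",
         need, " samples)")
  }
  n <- cfg$window_len
  bits <- matrix(0L, nrow = cfg$n_kept_bins, ncol = cfg$n_columns)
  thr_real <- cfg$threshold_raw / 2^cfg$fmt$frac_bits

  if (arithmetic == "fixed") {
    rom <- hamming_rom(n)
    tw <- twiddle_rom(n)
    for (m in seq_len(cfg$n_columns)) {
      seg <- samples[((m - 1L) * cfg$hop + 1L):((m - 1L) * cfg$hop + n)]
      x <- quantize(seg, cfg$fmt)
      wr <- fixed_mul(fixed_array(x$raw, cfg$fmt), rom, cfg$fmt)
      wi <- fixed_mul(fixed_array(x$raw_im, cfg$fmt), rom, cfg$fmt)
      spec <- fft_fixed(fixed_array(wr$raw, cfg$fmt, raw_im = wi$raw), tw)
      mag <- magnitude_approx(spec)
      kept <- select_center_bins(mag, cfg$n_kept_bins)
      bits[, m] <- binarize_column(kept, cfg$threshold_raw)
    }
  } else {
    w <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))
    idx <- center_bin_indices(n, cfg$n_kept_bins)
    for (m in seq_len(cfg$n_columns)) {
      seg <- samples[((m - 1L) * cfg$hop + 1L):((m - 1L) * cfg$hop + n)]
      spec <- stats::fft(seg * w)
      mag <- abs(Re(spec)) + abs(Im(spec))
      bits[, m] <- as.integer(mag[idx] >= thr_real)
    }
  }
  binary_spectrogram(bits)
}
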