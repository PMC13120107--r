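#' Quantized twiddle-factor lookup table
#'
#' Twiddle factors `W_N^k = exp(-2*pi*1i*k/N)`, `k = 0 .. N/2 - 1`, quantized
#' to a Q-format ROM. Stored at Q(16,14) by default so the full `[-1, 1]`
#' range is representable with 14 fractional bits; ROM constants are rounded
#' to nearest (half up), as precomputed tables are.
#'
#' @param n FFT length (power of two).
#' @param fmt ROM [qformat]; default `Q(16,14)`.
#' @return complex [fixed_array] of length `n/2`.
#' @export
twiddle_rom <- function(n = 128L, fmt = qformat(16L, 14L)) {
  if (n < 2L || bitwAnd(n, n - 1L) != 0L) stop("n must be a power of two >= 2")
  k <- 0:(n / 2L - 1L)
  w <- exp(-2i * pi * k / n)
  quantize(w, fmt, rounding = "round_half_up")
}

bit_reverse_perm <- function(n) {
  bits <- as.integer(round(log2(n)))
  idx <- 0:(n - 1L)
  rev <- integer(n)
  for (b in seq_len(bits)) {
    rev <- bitwOr(bitwShiftL(rev, 1L), bitwAnd(idx, 1L))
    idx <- bitwShiftR(idx, 1L)
  }
  rev + 1L
}

# Complex multiply of data (fmt) by twiddle (tw_fmt): full-precision integer
# products, floor shift back to fmt, saturate. Vectorized over elements.
cmul_twiddle <- function(dr, di, twr, twi, tw_frac, fmt) {
  re <- floor((dr * twr - di * twi) / 2^tw_frac)
  im <- floor((dr * twi + di * twr) / 2^tw_frac)
  list(re = saturate_raw(re, fmt), im = saturate_raw(im, fmt))
}

#' Bit-exact fixed-point radix-2 FFT
#'
#' In-order DFT of a complex fixed-point input computed by a
#' decimation-in-time radix-2 flow graph: bit-reversed input ordering and
#' `log2(n)` butterfly stages (7 stages for the 128-point transform used
#' here). Twiddle products are full-precision then floor-truncated back to
#' the data format; every addition and subtraction saturates to the data
#' format. No per-stage scaling is applied: headroom must come from the
#' format's integer bits and input scaling. Deterministic.
#'
#' @param segment complex [fixed_array], length a power of two (128 in the
#'   radar pipeline).
#' @param twiddles optional precomputed [twiddle_rom] for the segment length.
#' @return complex [fixed_array], same format and length, in natural
#'   frequency order.
#' @export
fft_fixed <- function(segment, twiddles = NULL) {
  stopifnot(inherits(segment, "fixed_array"))
  if (!segment$is_complex) stop("fft_fixed expects a complex fixed_array")
  n <- length(segment)
  if (n < 2L || bitwAnd(n, n - 1L) != 0L) {
    stop("fft_fixed: length must be a power of two, got ", n)
  }
  fmt <- segment$fmt
  if (is.null(twiddles)) twiddles <- twiddle_rom(n)
  if (length(twiddles) != n / 2L) stop("twiddle ROM length mismatch")
  tw_frac <- twiddles$fmt$frac_bits

  perm <- bit_reverse_perm(n)
  xr <- segment$raw[perm]
  xi <- segment$raw_im[perm]

  stages <- as.integer(round(log2(n)))
  for (s in seq_len(stages)) {
    m <- 2L^s
    half <- m %/% 2L
    i0 <- 0:(n - 1L)
    top <- i0[(i0 %% m) < half]               # top wing of each butterfly
    bot <- top + half
    k <- (top %% half) * (n %/% m)            # twiddle index per butterfly
    ti <- top + 1L; bi <- bot + 1L
    p <- cmul_twiddle(xr[bi], xi[bi], twiddles$raw[k + 1L],
                      twiddles$raw_im[k + 1L], tw_frac, fmt)
    tr <- xr[ti]; tii <- xi[ti]
    xr[ti] <- saturate_raw(tr + p$re, fmt)
    xi[ti] <- saturate_raw(tii + p$im, fmt)
    xr[bi] <- saturate_raw(tr - p$re, fmt)
    xi[bi] <- saturate_raw(tii - p$im, fmt)
  }
  fixed_array(xr, fmt, raw_im = xi)
}
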