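#' Signed fixed-point Q-format descriptor
#'
#' A `qformat` describes a signed two's-complement fixed-point representation
#' Q(W,F): `word_bits` total bits of which `frac_bits` are fractional. The
#' real value of a stored integer `raw` is `raw / 2^frac_bits`; the
#' representable raw range is `[-2^(W-1), 2^(W-1) - 1]`.
#'
#' @param word_bits total word width in bits (16 throughout this pipeline).
#' @param frac_bits number of fractional bits; must satisfy
#'   `0 < frac_bits < word_bits`.
#' @return an object of class `qformat`.
#' @examples
#' qformat(16, 11)
#' parse_qformat("Q(16,11)")
#' @export
qformat <- function(word_bits = 16L, frac_bits = 11L) {
  word_bits <- as.integer(word_bits)
  frac_bits <- as.integer(frac_bits)
  if (length(word_bits) != 1L || length(frac_bits) != 1L ||
      is.na(word_bits) || is.na(frac_bits)) {
    stop("word_bits and frac_bits must be single integers")
  }
  if (!(frac_bits > 0L && frac_bits < word_bits)) {
    stop("invalid qformat: need 0 < frac_bits < word_bits, got Q(",
         word_bits, ",", frac_bits, ")")
  }
  structure(list(word_bits = word_bits, frac_bits = frac_bits),
            class = "qformat")
}

#' @rdname qformat
#' @param x a string such as `"Q(16,11)"` (comma or dot separator).
#' @export
parse_qformat <- function(x) {
  m <- regmatches(x, regexec("^Q\\((\\d+)[,.](\\d+)\\)$", x))[[1]]
  if (length(m) != 3L) stop("cannot parse qformat string: ", x)
  qformat(as.integer(m[2]), as.integer(m[3]))
}

#' @export
format.qformat <- function(x, ...) {
  sprintf("Q(%d,%d)", x$word_bits, x$frac_bits)
}

#' @export
print.qformat <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

raw_min <- function(fmt) -(2^(fmt$word_bits - 1L))
raw_max <- function(fmt) 2^(fmt$word_bits - 1L) - 1

#' Saturate raw integer values into a Q-format range
#'
#' @param raw numeric vector of integer-valued raws.
#' @param fmt a [qformat].
#' @return raws clamped to `[-2^(W-1), 2^(W-1)-1]`.
#' @keywords internal
saturate_raw <- function(raw, fmt) {
  pmin(pmax(raw, raw_min(fmt)), raw_max(fmt))
}

#' Fixed-point array
#'
#' Container for fixed-point data: integer-valued raw storage plus its
#' [qformat]. Complex data carry separate real and imaginary raw arrays.
#' Raw values are saturated into the format's range at construction; out-of-
#' range inputs clamp, they never error (hardware saturation semantics).
#'
#' @param raw integer-valued numeric vector/array (real part if complex).
#' @param fmt a [qformat].
#' @param raw_im imaginary raw part, or `NULL` for real data.
#' @return an object of class `fixed_array`.
#' @export
fixed_array <- function(raw, fmt, raw_im = NULL) {
  stopifnot(inherits(fmt, "qformat"))
  raw <- saturate_raw(round(raw), fmt)
  if (!is.null(raw_im)) {
    if (length(raw_im) != length(raw)) stop("real/imaginary length mismatch")
    raw_im <- saturate_raw(round(raw_im), fmt)
  }
  structure(list(raw = raw, raw_im = raw_im, fmt = fmt,
                 is_complex = !is.null(raw_im)),
            class = "fixed_array")
}

#' @export
length.fixed_array <- function(x) length(x$raw)

#' @export
print.fixed_array <- function(x, ...) {
  cat(sprintf("<fixed_array %s, %s, length %d>\n", format(x$fmt),
              if (x$is_complex) "complex" else "real", length(x$raw)))
  utils::str(x$raw)
  invisible(x)
}

#' Quantize real values to fixed point
#'
#' Scales by `2^frac_bits`, applies the rounding rule, and saturates into the
#' representable range. `truncate` is floor (round toward negative infinity,
#' i.e. an arithmetic right shift); `round_half_up` rounds halves away from
#' minus infinity. Out-of-range values saturate silently.
#'
#' @param values real numeric (or complex) vector.
#' @param fmt a [qformat].
#' @param rounding `"truncate"` (default) or `"round_half_up"`.
#' @return a [fixed_array].
#' @examples
#' quantize(1.0, qformat(16, 11))$raw   # 2048
#' quantize(100, qformat(16, 11))$raw   # 32767 (saturates)
#' @export
quantize <- function(values, fmt, rounding = c("truncate", "round_half_up")) {
  rounding <- match.arg(rounding)
  rnd <- switch(rounding,
                truncate = floor,
                round_half_up = function(x) floor(x + 0.5))
  if (is.complex(values)) {
    fixed_array(saturate_raw(rnd(Re(values) * 2^fmt$frac_bits), fmt), fmt,
                raw_im = saturate_raw(rnd(Im(values) * 2^fmt$frac_bits), fmt))
  } else {
    fixed_array(saturate_raw(rnd(values * 2^fmt$frac_bits), fmt), fmt)
  }
}

#' Recover real values from a fixed-point array
#'
#' @param x a [fixed_array].
#' @return numeric (or complex) vector `raw / 2^frac_bits`.
#' @export
dequantize <- function(x) {
  stopifnot(inherits(x, "fixed_array"))
  s <- 2^x$fmt$frac_bits
  if (x$is_complex) complex(real = x$raw / s, imaginary = x$raw_im / s)
  else x$raw / s
}

#' Fixed-point multiply with declared output format
#'
#' Computes the full-precision integer product, then arithmetic-right-shifts
#' (floor) to the declared output format and saturates, mirroring a hardware
#' multiplier followed by a truncating realignment stage.
#'
#' @param a,b real [fixed_array]s of equal length.
#' @param out_fmt output [qformat]; defaults to `a`'s format.
#' @return a [fixed_array] in `out_fmt`.
#' @export
fixed_mul <- function(a, b, out_fmt = a$fmt) {
  stopifnot(inherits(a, "fixed_array"), inherits(b, "fixed_array"))
  if (length(a) != length(b)) {
    stop("fixed_mul: length mismatch (", length(a), " vs ", length(b), ")")
  }
  if (a$is_complex || b$is_complex) {
    stop("fixed_mul handles real arrays; complex products live in fft_fixed")
  }
  shift <- a$fmt$frac_bits + b$fmt$frac_bits - out_fmt$frac_bits
  prod <- a$raw * b$raw
  raw <- if (shift >= 0) floor(prod / 2^shift) else prod * 2^(-shift)
  fixed_array(saturate_raw(raw, out_fmt), out_fmt)
}

#' Signal-to-quantization-noise ratio in dB
#'
#' `10 * log10(sum(ref^2) / sum((ref - quantized)^2))`: power of the
#' reference over the power of the quantization error.
#'
#' @param reference real reference signal (float precision).
#' @param quantized its quantized/dequantized counterpart, same length.
#' @return SQNR in dB.
#' @examples
#' sqnr_db(c(1, 1), c(0.9, 1.1))  # 20 dB
#' @export
sqnr_db <- function(reference, quantized) {
  if (length(reference) != length(quantized)) stop("sqnr_db: length mismatch")
  ps <- sum(reference^2)
  if (ps == 0) stop("sqnr_db: reference has zero energy")
  pn <- sum((reference - quantized)^2)
  if (pn == 0) stop("sqnr_db: zero quantization noise (signals identical)")
  10 * log10(ps / pn)
}
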