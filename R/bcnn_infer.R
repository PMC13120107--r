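#' @title XNOR/popcount binarized convolution
#'
#' @description Valid, stride-1 convolution of a binary input tensor with
#' binary weights, computed in the popcount domain exactly as the hardware
#' does: for each output position the agreement count
#' `p = popcount(XNOR(patch, kernel))` over the `N = k^2 * C_in` fan-in
#' bits, then the pre-activation `2p - N`. This equals the float convolution
#' of the bit-decoded (bit 1 -> +1, bit 0 -> -1) tensors exactly.
#'
#' @details Input tensors use dimension order `H x W x C`; weights
#' `k x k x C_in x C_out` with the same patch ordering as the internal
#' im2col lowering (row offset fastest, then column offset, then input
#' channel). Cross-correlation orientation (no kernel flip), the convention
#' of CNN accelerators.
#'
#' @param input 0/1 array `H x W x C_in` (a matrix is taken as `C_in = 1`).
#' @param weights 0/1 array `k x k x C_in x C_out`.
#' @return integer array `(H-k+1) x (W-k+1) x C_out` of pre-activations in
#'   `[-N, N]`.
#' @export
binary_conv2d <- function(input, weights) {
  if (is.matrix(input)) dim(input) <- c(dim(input), 1L)
  if (length(dim(input)) != 3L) stop("input must be H x W x C")
  if (length(dim(weights)) != 4L) stop("weights must be k x k x C_in x C_out")
  dh <- dim(input); dw <- dim(weights)
  k <- dw[1]
  if (dw[2] != k) stop("kernels must be square")
  if (dw[3] != dh[3]) {
    stop("channel mismatch: input has ", dh[3], ", weights expect ", dw[3])
  }
  if (dh[1] < k || dh[2] < k) stop("input smaller than kernel")
  if (!all(input %in% c(0L, 1L)) || !all(weights %in% c(0L, 1L))) {
    stop("binary_conv2d operates on 0/1 bits")
  }
  n_fan <- k * k * dh[3]
  ho <- dh[1] - k + 1L; wo <- dh[2] - k + 1L
  cols <- im2col(input, k)                        # [k^2*C_in, ho*wo], bits
  wmat <- matrix(as.numeric(weights), nrow = n_fan) # [k^2*C_in, C_out], bits
  # agreement count: bits equal <=> both 1 or both 0
  p <- crossprod(cols, wmat) + crossprod(1 - cols, 1 - wmat)
  preact <- array(as.integer(2 * p - n_fan), dim = c(ho, wo, dw[4]))
  preact
}

# Lower an H x W x C array to patch columns for k x k valid windows.
# Column for output (i, j) holds entries (i+dr, j+dc, c) with dr fastest,
# then dc, then c — matching as.vector() of a k x k x C weight kernel.
im2col <- function(input, k) {
  d <- dim(input)
  ho <- d[1] - k + 1L; wo <- d[2] - k + 1L
  idx <- im2col_indices(d[1], d[2], d[3], k)
  matrix(as.numeric(input)[idx], nrow = k * k * d[3], ncol = ho * wo)
}

im2col_indices <- function(h, w, ch, k) {
  ho <- h - k + 1L; wo <- w - k + 1L
  dr <- rep(0:(k - 1L), times = k * ch)
  dc <- rep(rep(0:(k - 1L), each = k), times = ch)
  cc <- rep(0:(ch - 1L), each = k * k)
  base <- cc * h * w + dc * h + dr + 1L               # patch at (1,1)
  oi <- rep(0:(ho - 1L), times = wo)
  oj <- rep(0:(wo - 1L), each = ho)
  off <- oj * h + oi                                  # column-major offsets
  outer(base, off, `+`)                               # [k^2*ch, ho*wo]
}

#' Threshold activation in the popcount domain
#'
#' The folded replacement for batch norm + sign: with per-channel fan-in
#' `N`, popcount threshold `t` and activation threshold `T_a = 2t - N`, the
#' output bit is 1 iff `gamma_sign * (preact - T_a) >= 0` (inclusive at the
#' boundary, matching sign(0) = +1). All-integer; exactly equivalent to
#' computing batch norm in float and taking the sign, for the parameters
#' the threshold was folded from.
#'
#' @param preact integer array `H x W x C` (or matrix `units x 1`) of
#'   pre-activations `2p - N`.
#' @param gamma_sign +1/-1 per channel.
#' @param popcount_threshold integer per channel, in `[0, N + 1]`.
#' @param n_fan fan-in N of the layer.
#' @return 0/1 integer array, same shape as `preact`.
#' @export
threshold_activate <- function(preact, gamma_sign, popcount_threshold, n_fan) {
  d <- dim(preact)
  # vectors (fully connected pre-activations) are one unit per channel
  nch <- if (is.null(d)) length(preact) else d[length(d)]
  if (length(gamma_sign) == 1L) gamma_sign <- rep(gamma_sign, nch)
  if (length(popcount_threshold) == 1L) {
    popcount_threshold <- rep(popcount_threshold, nch)
  }
  stopifnot(length(gamma_sign) == nch, length(popcount_threshold) == nch)
  t_act <- 2 * popcount_threshold - n_fan
  per_ch <- if (is.null(d)) 1L else prod(d) / nch
  gs <- rep(gamma_sign, each = per_ch)
  ta <- rep(t_act, each = per_ch)
  bits <- as.integer(gs * (as.vector(preact) - ta) >= 0)
  if (!is.null(d)) dim(bits) <- d
  bits
}

#' OR pooling of a binary feature map
#'
#' 2x2 stride-2 max pooling specialised to single-bit maps: the maximum of
#' `{-1, +1}` values is +1 iff any bit in the window is 1, so pooling is a
#' logical OR. Odd trailing rows/columns are dropped (floor semantics).
#'
#' @param bits 0/1 array `H x W x C` or matrix.
#' @return pooled 0/1 array `floor(H/2) x floor(W/2) x C`.
#' @export
or_maxpool <- function(bits) {
  was_mat <- is.matrix(bits)
  if (was_mat) dim(bits) <- c(dim(bits), 1L)
  d <- dim(bits)
  ho <- d[1] %/% 2L; wo <- d[2] %/% 2L
  a <- bits[seq_len(2L * ho), seq_len(2L * wo), , drop = FALSE]
  out <- pmax(a[seq(1, 2 * ho, 2), seq(1, 2 * wo, 2), , drop = FALSE],
              a[seq(2, 2 * ho, 2), seq(1, 2 * wo, 2), , drop = FALSE],
              a[seq(1, 2 * ho, 2), seq(2, 2 * wo, 2), , drop = FALSE],
              a[seq(2, 2 * ho, 2), seq(2, 2 * wo, 2), , drop = FALSE])
  storage.mode(out) <- "integer"
  if (was_mat) dim(out) <- c(ho, wo)
  out
}

# Flatten H x W x C to the fully connected ordering: channel-major, then
# row-major within a channel (column index fastest). Frozen so the ROM
# export and the hardware agree.
flatten_chw <- function(x) {
  as.vector(aperm(x, c(2L, 1L, 3L)))
}

#' Run binarized inference on a spectrogram
#'
#' Bit-exact model of the neural network unit: for each conv block an
#' XNOR/popcount convolution, threshold activation and OR pool; then the
#' fully connected layers (hidden FC with threshold activation, final FC
#' producing two raw integer scores with no batch norm). Arithmetic is
#' integer end to end. The predicted class is the argmax of the scores; a
#' tie resolves to non-fall (the conservative, false-alarm-minimising
#' choice).
#'
#' @param model a [bcnn_model].
#' @param spectrogram a [binary_spectrogram] or 0/1 matrix matching the
#'   model's input size.
#' @return list with `class` (`"fall"` or `"nonfall"`), `scores` (named
#'   integer pair, order `fall`, `nonfall`).
#' @export
bcnn_infer <- function(model, spectrogram) {
  stopifnot(inherits(model, "bcnn_model"))
  bits <- if (inherits(spectrogram, "binary_spectrogram")) spectrogram$bits
          else spectrogram
  insz <- model$spec$input_size
  if (!all(dim(bits) == c(insz, insz))) {
    stop("spectrogram must be ", insz, "x", insz)
  }
  x <- array(as.integer(bits), dim = c(insz, insz, 1L))
  li <- 0L
  for (ly in model$spec$layers) {
    li <- li + 1L
    wb <- model$weights[[li]]
    if (ly$type == "conv") {
      pre <- binary_conv2d(x, wb)
      act <- threshold_activate(pre, model$bn[[li]]$gamma_sign,
                                model$bn[[li]]$popcount_threshold,
                                ly$kernel^2 * ly$c_in)
      x <- or_maxpool(act)
    } else {
      v <- if (length(dim(x)) == 3L) flatten_chw(x) else as.vector(x)
      n_fan <- ly$f_in
      # FC as kernel-1 popcount: agreement count p, score 2p - N
      wmat <- matrix(as.numeric(wb), nrow = n_fan)     # [f_in, f_out] bits
      vb <- as.numeric(v)
      p <- as.vector(vb %*% wmat + (1 - vb) %*% (1 - wmat))
      pre <- as.integer(2 * p - n_fan)
      if (ly$bn) {
        x <- threshold_activate(pre, model$bn[[li]]$gamma_sign,
                                model$bn[[li]]$popcount_threshold, n_fan)
      } else {
        scores <- pre
      }
    }
  }
  names(scores) <- c("fall", "nonfall")
  cls <- if (scores["fall"] > scores["nonfall"]) "fall" else "nonfall"
  list(class = cls, scores = scores)
}

#' Binarized network model container
#'
#' The deployable artifact: per-layer binary weight bits (1 bit per weight,
#' bit 1 decoding to +1 and bit 0 to -1) plus, for every layer except the
#' final fully connected one, per-channel folded batch-norm parameters —
#' a gamma sign and an integer popcount threshold.
#'
#' @param spec a [network_spec].
#' @param weights list of 0/1 arrays, one per layer: conv layers
#'   `k x k x C_in x C_out`, FC layers `F_in x F_out`.
#' @param bn list parallel to `weights`: for layers with batch norm, a list
#'   with `gamma_sign` and `popcount_threshold` vectors (length = channels
#'   or units); `NULL` for the final layer.
#' @param meta optional list of training metadata (seed, epochs, split).
#' @return an object of class `bcnn_model`.
#' @export
bcnn_model <- function(spec, weights, bn, meta = list()) {
  stopifnot(inherits(spec, "network_spec"))
  if (length(weights) != length(spec$layers)) stop("one weight array per layer")
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    expect <- if (ly$type == "conv") c(ly$kernel, ly$kernel, ly$c_in, ly$c_out)
              else c(ly$f_in, ly$f_out)
    if (!identical(as.integer(dim(weights[[i]])), as.integer(expect))) {
      stop("layer ", i, ": weight shape ", paste(dim(weights[[i]]),
           collapse = "x"), " does not match spec ",
           paste(expect, collapse = "x"))
    }
    if (!all(weights[[i]] %in% c(0L, 1L))) stop("weights must be 0/1 bits")
    if (ly$bn) {
      n_fan <- if (ly$type == "conv") ly$kernel^2 * ly$c_in else ly$f_in
      thr <- bn[[i]]$popcount_threshold
      if (any(thr < 0 | thr > n_fan + 1)) {
        stop("layer ", i, ": popcount thresholds outside [0, fan-in + 1]")
      }
    }
  }
  structure(list(spec = spec, weights = weights, bn = bn, meta = meta),
            class = "bcnn_model")
}

#' @export
print.bcnn_model <- function(x, ...) {
  cat(sprintf("<bcnn_model: conv %s | fc %s | %d parameters, %d weight bits>\n",
              paste(x$spec$conv_channels, collapse = ","),
              paste(x$spec$fc_sizes, collapse = ","),
              count_parameters(x$spec), count_weight_bits(x$spec)))
  invisible(x)
}
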