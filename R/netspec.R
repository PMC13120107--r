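#' Binarized-CNN architecture specification
#'
#' Describes the family of compact binarized networks evaluated for the fall
#' classifier: 2 or 3 convolutional blocks followed by 1 or 2 fully
#' connected layers ending in the 2-way fall / non-fall output. Fixed
#' geometry: 1 x 24 x 24 binary input, first conv kernel 5x5, later conv
#' kernels 3x3, valid padding, stride 1, a 2x2/stride-2 pool after every
#' conv block, batch norm (2 parameters per channel) on every layer except
#' the final fully connected one, and no bias terms anywhere.
#'
#' @param conv_channels integer vector of output channels per conv block
#'   (length 2 or 3).
#' @param fc_sizes integer vector of fully connected layer sizes, ending
#'   in 2 (length 1 or 2).
#' @param input_size spatial side of the square single-channel input.
#' @param first_kernel,later_kernel conv kernel sides.
#' @return an object of class `network_spec` with per-layer geometry in
#'   `$layers`.
#' @examples
#' network_spec(c(32, 32, 32), c(32, 2))  # the selected architecture
#' @export
network_spec <- function(conv_channels, fc_sizes, input_size = 24L,
                         first_kernel = 5L, later_kernel = 3L) {
  conv_channels <- as.integer(conv_channels)
  fc_sizes <- as.integer(fc_sizes)
  if (length(fc_sizes) < 1L || fc_sizes[length(fc_sizes)] != 2L) {
    stop("fc_sizes must end in 2 (fall / non-fall)")
  }
  layers <- list()
  size <- as.integer(input_size)
  c_in <- 1L
  for (i in seq_along(conv_channels)) {
    k <- if (i == 1L) as.integer(first_kernel) else as.integer(later_kernel)
    size <- size - k + 1L                      # valid convolution
    if (size < 1L) stop("spatial size collapsed at conv layer ", i)
    size <- size %/% 2L                        # 2x2 stride-2 pool
    if (size < 1L) stop("spatial size collapsed at pool after conv ", i)
    layers[[length(layers) + 1L]] <- list(
      type = "conv", kernel = k, c_in = c_in, c_out = conv_channels[i],
      out_size = size, bn = TRUE)
    c_in <- conv_channels[i]
  }
  f_in <- c_in * size * size
  for (j in seq_along(fc_sizes)) {
    final <- j == length(fc_sizes)
    layers[[length(layers) + 1L]] <- list(
      type = "fc", f_in = f_in, f_out = fc_sizes[j], bn = !final)
    f_in <- fc_sizes[j]
  }
  structure(list(conv_channels = conv_channels, fc_sizes = fc_sizes,
                 input_size = as.integer(input_size), layers = layers),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec: conv %s | fc %s | %s parameters>\n",
              paste(x$conv_channels, collapse = ","),
              paste(x$fc_sizes, collapse = ","),
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Exact parameter count of a network specification
#'
#' Sums, over conv layers, `k^2 * C_in * C_out` binary weights plus 2
#' batch-norm parameters per output channel; over fully connected layers,
#' `F_in * F_out` binary weights plus 2 batch-norm parameters per unit on
#' every layer except the final one. No layer has biases.
#'
#' @param spec a [network_spec].
#' @return integer total parameter count.
#' @examples
#' count_parameters(network_spec(c(32, 32, 32), c(32, 2)))  # 20576
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  total <- 0
  for (ly in spec$layers) {
    if (ly$type == "conv") {
      total <- total + ly$kernel^2 * ly$c_in * ly$c_out +
        (if (ly$bn) 2 * ly$c_out else 0)
    } else {
      total <- total + ly$f_in * ly$f_out + (if (ly$bn) 2 * ly$f_out else 0)
    }
  }
  as.integer(total)
}

#' Number of binary weights (excluding batch-norm parameters)
#' @param spec a [network_spec].
#' @return integer count of 1-bit weights.
#' @export
count_weight_bits <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  total <- 0
  for (ly in spec$layers) {
    total <- total + if (ly$type == "conv") ly$kernel^2 * ly$c_in * ly$c_out
                     else ly$f_in * ly$f_out
  }
  as.integer(total)
}

#' Packed model size in bytes at 1 bit per parameter
#'
#' `ceiling(count / 8)` bytes: every parameter of the deployed model — the
#' binary weights and the per-channel folded thresholds counted at the same
#' budget the network comparison uses — stored at one bit each.
#'
#' @param spec a [network_spec].
#' @return integer byte count.
#' @export
model_size_bytes <- function(spec) {
  as.integer(ceiling(count_parameters(spec) / 8))
}

#' The nine benchmarked architectures
#'
#' The conv-channel and fully-connected layouts of the nine networks in the
#' architecture comparison, in their published order; network 8
#' (conv 32,32,32; fc 32,2) is the one selected for deployment.
#'
#' @return named list of [network_spec]s `net1`..`net9`.
#' @export
benchmark_networks <- function() {
  defs <- list(
    net1 = list(c(32, 32),      c(2)),
    net2 = list(c(32, 32),      c(32, 2)),
    net3 = list(c(64, 64),      c(2)),
    net4 = list(c(64, 64),      c(32, 2)),
    net5 = list(c(16, 16, 16),  c(2)),
    net6 = list(c(16, 32, 64),  c(2)),
    net7 = list(c(32, 32, 32),  c(2)),
    net8 = list(c(32, 32, 32),  c(32, 2)),
    net9 = list(c(32, 64, 128), c(2))
  )
  lapply(defs, function(d) network_spec(d[[1]], d[[2]]))
}
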