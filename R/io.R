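#' Write / read a raw frame as CSV with JSON sidecar
#'
#' The CSV has columns `I`, `Q` (one row per baseband sample); the sidecar
#' `<path>.json` records `sample_rate_hz`, `label` and `subject_id`.
#' Round-trips bit-exactly at full double precision.
#'
#' @param frame a [radar_frame].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_frame_csv <- function(frame, path) {
  stopifnot(inherits(frame, "radar_frame"))
  df <- data.frame(I = Re(frame$samples), Q = Im(frame$samples))
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  meta <- list(sample_rate_hz = frame$sample_rate_hz)
  if (!is.null(frame$label)) meta$label <- frame$label
  if (!is.null(frame$subject_id)) meta$subject_id <- frame$subject_id
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_frame_csv
#' @export
read_frame_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("I", "Q") %in% names(df))) {
    stop("malformed frame CSV ", path, ": need columns I, Q")
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)
          else list(sample_rate_hz = 2000)
  radar_frame(complex(real = df$I, imaginary = df$Q),
              sample_rate_hz = meta$sample_rate_hz,
              label = meta$label, subject_id = meta$subject_id)
}

#' Write / read a binary spectrogram as plain PBM (P1)
#'
#' Portable bitmap, plain text variant: bit-exact interchange for the
#' 24 x 24 single-bit maps. PBM's 1 is conventionally black; bits are
#' stored as-is (spectrogram 1 -> PBM 1).
#'
#' @param spec a [binary_spectrogram].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrogram_pbm <- function(spec, path) {
  stopifnot(inherits(spec, "binary_spectrogram"))
  b <- spec$bits
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P1", paste(ncol(b), nrow(b)),
               apply(b, 1, paste, collapse = " ")),
             con, sep = "\n")
  invisible(path)
}

#' @rdname write_spectrogram_pbm
#' @export
read_spectrogram_pbm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) < 2L || trimws(lines[1]) != "P1") {
    stop("not a plain PBM (P1) file: ", path, " (line 1)")
  }
  dims <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  if (length(dims) != 2L || anyNA(dims)) {
    stop("malformed PBM dimensions in ", path, " (line 2)")
  }
  tokens <- unlist(strsplit(paste(lines[-(1:2)], collapse = " "), ""))
  tokens <- tokens[tokens %in% c("0", "1")]
  if (length(tokens) != dims[1] * dims[2]) {
    stop("PBM ", path, ": expected ", dims[1] * dims[2], " bits, found ",
         length(tokens))
  }
  binary_spectrogram(matrix(as.integer(tokens), nrow = dims[2],
                            ncol = dims[1], byrow = TRUE))
}

# ---- ROM hex export --------------------------------------------------------

# pack a 0/1 vector into 16-bit words, MSB first; pad with zeros
pack_bits16 <- function(bits) {
  n_words <- ceiling(length(bits) / 16)
  bits <- c(bits, rep(0L, n_words * 16 - length(bits)))
  m <- matrix(bits, nrow = 16)
  as.integer(colSums(m * 2^(15:0)))
}

unpack_bits16 <- function(words, n_bits) {
  bits <- integer(length(words) * 16L)
  for (i in seq_along(words)) {
    w <- words[i]
    bits[((i - 1L) * 16L + 1L):(i * 16L)] <-
      bitwAnd(bitwShiftR(w, 15:0), 1L)
  }
  bits[seq_len(n_bits)]
}

#' Export a model as hex-text ROM images
#'
#' Mirrors the accelerator's internal ROM layout: per layer, a
#' `layerN_weights.hex` file (binary weights packed MSB-first into 16-bit
#' words, one 4-digit uppercase hex word per line, LF line endings) and,
#' for layers with folded batch norm, a `layerN_bn.hex` file with one
#' 16-bit word per channel — bit 15 set iff gamma is negative, bits 14..0
#' the integer popcount threshold. A `model.json` descriptor records the
#' architecture, layer ordering, flattening convention and training
#' metadata. Byte-stable across platforms.
#'
#' @param model a [bcnn_model].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_rom <- function(model, dir) {
  stopifnot(inherits(model, "bcnn_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- model$spec
  desc <- list(
    conv_channels = spec$conv_channels,
    fc_sizes = spec$fc_sizes,
    input_size = spec$input_size,
    weight_bit_order = "as.vector of k x k x C_in x C_out (conv) / F_in x F_out (fc), MSB-first in 16-bit words",
    fc_flatten = "channel-major, then row-major spatial (column fastest)",
    bn_word = "bit15 = gamma negative, bits14..0 = popcount threshold",
    parameters = count_parameters(spec),
    weight_bits = count_weight_bits(spec),
    meta = model$meta[setdiff(names(model$meta),
                              c("float_state", "train_idx", "test_idx"))]
  )
  jsonlite::write_json(desc, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (i in seq_along(spec$layers)) {
    words <- pack_bits16(as.vector(model$weights[[i]]))
    writeLines(sprintf("%04X", words),
               file.path(dir, sprintf("layer%d_weights.hex", i)), sep = "\n")
    if (spec$layers[[i]]$bn) {
      bnw <- ifelse(model$bn[[i]]$gamma_sign < 0, 32768L, 0L) +
        model$bn[[i]]$popcount_threshold
      writeLines(sprintf("%04X", bnw),
                 file.path(dir, sprintf("layer%d_bn.hex", i)), sep = "\n")
    }
  }
  invisible(dir)
}

#' Read a model back from its ROM export
#'
#' Inverse of [export_rom]: reconstructs the [bcnn_model] (weights and
#' folded thresholds) bit-exactly from the hex images and descriptor.
#' Training-time float state is not part of the ROM and is not recovered.
#'
#' @param dir directory written by [export_rom].
#' @return a [bcnn_model].
#' @export
read_rom <- function(dir) {
  desc <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  spec <- network_spec(desc$conv_channels, desc$fc_sizes,
                       input_size = desc$input_size)
  weights <- vector("list", length(spec$layers))
  bn <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    wdim <- if (ly$type == "conv") c(ly$kernel, ly$kernel, ly$c_in, ly$c_out)
            else c(ly$f_in, ly$f_out)
    words <- read_hex_words(file.path(dir, sprintf("layer%d_weights.hex", i)),
                            ceiling(prod(wdim) / 16))
    weights[[i]] <- array(unpack_bits16(words, prod(wdim)), dim = wdim)
    if (ly$bn) {
      nch <- if (ly$type == "conv") ly$c_out else ly$f_out
      bnw <- read_hex_words(file.path(dir, sprintf("layer%d_bn.hex", i)), nch)
      bn[[i]] <- list(gamma_sign = ifelse(bitwAnd(bnw, 32768L) > 0L, -1, 1),
                      popcount_threshold = bitwAnd(bnw, 32767L))
    }
  }
  meta <- if (!is.null(desc$meta)) as.list(desc$meta) else list()
  bcnn_model(spec, weights, bn, meta)
}

read_hex_words <- function(path, n_expected) {
  lines <- readLines(path)
  bad <- which(!grepl("^[0-9A-Fa-f]{4}$", lines))
  if (length(bad) > 0L) {
    stop("malformed hex word in ", path, " at line ", bad[1])
  }
  if (length(lines) != n_expected) {
    stop(path, ": expected ", n_expected, " words, found ", length(lines),
         " (truncated or padded file?)")
  }
  strtoi(lines, 16L)
}
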