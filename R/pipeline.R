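#' End-to-end pipeline configuration
#'
#' Bundles every stage's configuration plus output paths into one
#' round-trippable object (JSON or YAML on disk).
#'
#' @param sim a [sim_config].
#' @param stft an [stft_config].
#' @param net a [network_spec].
#' @param train a [train_config].
#' @param out_dir output directory for artifacts and the report.
#' @return an object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(n_per_class = 40L),
                       stft = stft_config(),
                       net = network_spec(c(32, 32, 32), c(32, 2)),
                       train = train_config(epochs = 60L),
                       out_dir = tempfile("radfall_run_")) {
  structure(list(sim = sim, stft = stft, net = net, train = train,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the complete pipeline: simulate, preprocess, train, evaluate, export
#'
#' Executes the stages in the same dataflow order as the target system
#' (raw baseband -> preprocessing unit -> binary spectrogram -> network ->
#' class): generates the synthetic corpus, preprocesses every frame through
#' the fixed-point datapath, trains the binarized network, evaluates on the
#' held-out split, and exports the ROM images. Writes a JSON report with
#' accuracies, the parameter count, packed model size, and an MD5 digest of
#' every stage artifact so a rerun can be verified stage by stage.
#'
#' @param cfg a [run_config].
#' @param verbose print stage progress.
#' @return the report, invisibly (also written to
#'   `file.path(cfg$out_dir, "report.json")`).
#' @export
run_pipeline <- function(cfg = run_config(), verbose = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)

  say("stage 1/5: simulate (seed ", cfg$sim$seed, ")")
  ds <- generate_dataset(cfg$sim)
  manifest_path <- file.path(cfg$out_dir, "manifest.csv")
  utils::write.csv(ds$manifest, manifest_path, row.names = FALSE)

  say("stage 2/5: preprocess (", length(ds$frames), " frames, ",
      format(cfg$stft$fmt), ", threshold ", cfg$stft$threshold_raw, ")")
  specs <- preprocess_frames(ds$frames, cfg$stft)
  spec_path <- file.path(cfg$out_dir, "spectrograms.pbm")
  write_spectrogram_pbm(
    binary_spectrogram(matrix(aperm(specs, c(1, 3, 2)),
                              nrow = dim(specs)[1] * dim(specs)[3])),
    spec_path)

  say("stage 3/5: train (", cfg$train$epochs, " epochs)")
  model <- bcnn_train(specs, ds$labels, cfg$net, cfg$train)

  say("stage 4/5: evaluate")
  acc_train <- model$meta$train_accuracy
  acc_test <- model$meta$test_accuracy

  say("stage 5/5: export ROM")
  rom_dir <- file.path(cfg$out_dir, "rom")
  export_rom(model, rom_dir)

  rom_files <- sort(list.files(rom_dir, full.names = TRUE))
  report <- list(
    seed = cfg$sim$seed,
    n_frames = length(ds$frames),
    qformat = format(cfg$stft$fmt),
    threshold_raw = cfg$stft$threshold_raw,
    network = list(conv = cfg$net$conv_channels, fc = cfg$net$fc_sizes),
    parameter_count = count_parameters(cfg$net),
    weight_bits = count_weight_bits(cfg$net),
    packed_weight_bytes = as.integer(ceiling(count_weight_bits(cfg$net) / 8)),
    model_size_bytes = model_size_bytes(cfg$net),
    train_accuracy = acc_train,
    test_accuracy = acc_test,
    digests = c(
      stats::setNames(as.vector(tools::md5sum(manifest_path)), "manifest"),
      stats::setNames(as.vector(tools::md5sum(spec_path)), "spectrograms"),
      stats::setNames(as.vector(tools::md5sum(rom_files)),
                      basename(rom_files))
    )
  )
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
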