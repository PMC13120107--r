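#' Stratified k-fold cross-validation of the binarized classifier
#'
#' Splits the dataset into `k` stratified folds (class proportions
#' preserved per fold), trains a fresh model on each training split with
#' the full recipe of [bcnn_train] except that no inner holdout is taken
#' (`split = 1`), and evaluates on the held-out fold. Returns per-fold
#' accuracies with their mean and standard deviation.
#'
#' @param spectrograms 0/1 array `24 x 24 x n`.
#' @param labels activity codes `"a"`..`"l"` or `"fall"` / `"nonfall"`.
#' @param spec a [network_spec].
#' @param cfg a [train_config]; its seed drives fold assignment and every
#'   fold's training.
#' @param k number of folds (`>= 2`, `<= n`).
#' @return list with `fold_accuracy`, `mean`, `sd`.
#' @export
evaluate_kfold <- function(spectrograms, labels, spec, cfg = train_config(),
                           k = 5L) {
  labels <- as.character(labels)
  if (all(labels %in% letters[1:12])) bl <- binary_label(labels)
  else bl <- labels
  n <- dim(spectrograms)[3]
  if (k < 2L) stop("k must be >= 2")
  if (n < k) stop("dataset smaller than k")

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  set.seed(cfg$seed)
  fold <- integer(n)
  for (cl in unique(labels)) {
    ii <- sample(which(labels == cl))
    fold[ii] <- rep_len(seq_len(k), length(ii))
  }
  run_folds(spectrograms, bl, spec, cfg, fold, k)
}

#' Leave-one-subject-out cross-validation
#'
#' Folds partition the dataset by subject: each fold holds out every
#' recording of one subject, testing cross-person generalization.
#'
#' @param subject_id integer/character subject identifier per sample.
#' @inheritParams evaluate_kfold
#' @return list with `fold_accuracy` (named by subject), `mean`, `sd`.
#' @export
evaluate_loso <- function(spectrograms, labels, subject_id, spec,
                          cfg = train_config()) {
  if (is.null(subject_id) || anyNA(subject_id)) {
    stop("LOSO evaluation requires a subject_id for every sample")
  }
  labels <- as.character(labels)
  if (all(labels %in% letters[1:12])) labels <- binary_label(labels)
  subjects <- sort(unique(subject_id))
  fold <- match(subject_id, subjects)
  res <- run_folds(spectrograms, labels, spec, cfg, fold, length(subjects))
  names(res$fold_accuracy) <- as.character(subjects)
  res
}

run_folds <- function(spectrograms, bl, spec, cfg, fold, k) {
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    cfg_f <- cfg
    cfg_f$split <- 1
    model <- bcnn_train(spectrograms[, , tr, drop = FALSE], bl[tr],
                        spec, cfg_f)
    pred <- bcnn_predict(model, spectrograms[, , te, drop = FALSE])
    acc[f] <- mean(pred == bl[te])
  }
  list(fold_accuracy = acc, mean = mean(acc), sd = stats::sd(acc))
}
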