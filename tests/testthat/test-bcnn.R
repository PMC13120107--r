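test_that("the stated kernel geometry is the unique one matching all totals", {
  published <- c(11168, 26656, 40768, 71616, 5136, 23792, 19488, 20576, 93664)
  nets <- benchmark_networks()
  expect_identical(vapply(nets, count_parameters, integer(1),
                          USE.NAMES = FALSE), as.integer(published))

  # brute-force enumeration over the natural configuration family: the
  # (first 5x5, later 3x3, valid, 2 BN params, no bias) geometry must be
  # the only member reproducing every published total
  layouts <- list(list(c(32, 32), c(2)), list(c(32, 32), c(32, 2)),
                  list(c(64, 64), c(2)), list(c(64, 64), c(32, 2)),
                  list(c(16, 16, 16), c(2)), list(c(16, 32, 64), c(2)),
                  list(c(32, 32, 32), c(2)), list(c(32, 32, 32), c(32, 2)),
                  list(c(32, 64, 128), c(2)))
  count_variant <- function(lay, k1, k2, same_pad, bn_per, bias) {
    size <- 24; c_in <- 1; total <- 0
    for (i in seq_along(lay[[1]])) {
      k <- if (i == 1) k1 else k2
      if (!same_pad) size <- size - k + 1
      if (size < 1) return(NA_real_)
      size <- size %/% 2
      if (size < 1) return(NA_real_)
      co <- lay[[1]][i]
      total <- total + k^2 * c_in * co + bn_per * co + bias * co
      c_in <- co
    }
    f_in <- c_in * size * size
    for (j in seq_along(lay[[2]])) {
      fo <- lay[[2]][j]
      final <- j == length(lay[[2]])
      total <- total + f_in * fo + (!final) * bn_per * fo + bias * fo
      f_in <- fo
    }
    total
  }
  matches <- 0L
  for (k1 in c(3, 5, 7)) for (k2 in c(3, 5, 7)) {
    for (same_pad in c(FALSE, TRUE)) for (bn_per in c(1, 2, 4)) {
      for (bias in c(0, 1)) {
        tot <- vapply(layouts, count_variant, numeric(1),
                      k1, k2, same_pad, bn_per, bias)
        if (!anyNA(tot) && all(tot == published)) {
          matches <- matches + 1L
          expect_identical(c(k1, k2, same_pad, bn_per, bias),
                           c(5, 3, FALSE, 2, 0))
        }
      }
    }
  }
  expect_identical(matches, 1L)
})

test_that("parameter counting handles degenerate and invalid geometries", {
  tiny <- network_spec(integer(0), c(2), input_size = 1)
  expect_identical(count_parameters(tiny), 2L)     # 1x2 weights, no BN
  expect_error(network_spec(c(8, 8, 8, 8), c(2)), "collapsed")
  expect_error(network_spec(c(8), c(3)), "end in 2")
  # packed size arithmetic
  net8 <- network_spec(c(32, 32, 32), c(32, 2))
  expect_identical(model_size_bytes(net8),
                   as.integer(ceiling(count_parameters(net8) / 8)))
})

test_that("XNOR/popcount convolution equals the dense float +-1 oracle", {
  # perfect agreement / disagreement corners
  ones <- array(1L, dim = c(5, 5, 1))
  w1 <- array(1L, dim = c(3, 3, 1, 1))
  expect_true(all(binary_conv2d(ones, w1) == 9))
  w0 <- array(0L, dim = c(3, 3, 1, 1))
  expect_true(all(binary_conv2d(ones, w0) == -9))

  set.seed(42)
  for (rep_i in 1:50) {
    k <- sample(c(3, 5), 1)
    ci <- sample(c(1, 3, 8), 1)
    co <- sample(1:4, 1)
    h <- sample(k:(k + 5), 1); w <- sample(k:(k + 5), 1)
    inp <- array(rbinom(h * w * ci, 1, 0.5), dim = c(h, w, ci))
    wt <- array(rbinom(k * k * ci * co, 1, 0.5), dim = c(k, k, ci, co))
    expect_identical(as.numeric(binary_conv2d(inp, wt)),
                     as.numeric(oracle_conv_pm1(inp, wt)))
  }
  expect_error(binary_conv2d(ones, array(1L, dim = c(3, 3, 2, 1))),
               "channel mismatch")
})

test_that("threshold activation matches batch-norm-plus-sign after folding", {
  # boundary inclusivity: preact exactly at T_a with positive gamma -> 1
  expect_identical(threshold_activate(c(-9L, -7L), 1, 1, 9), c(0L, 1L))
  # negative gamma flips every decision strictly away from the boundary
  set.seed(8)
  pre <- as.integer(2 * sample(0:9, 50, TRUE) - 9)
  up <- threshold_activate(pre, 1, 4, 9)
  dn <- threshold_activate(pre, -1, 4, 9)
  off <- pre != (2 * 4 - 9)
  expect_true(all((up + dn)[off] == 1))

  # random BN parameters, folded by the package, against the float oracle
  for (rep_i in 1:60) {
    n_fan <- sample(c(9, 25, 288), 1)
    nch <- sample(1:8, 1)
    gamma <- runif(nch, -2, 2); gamma[abs(gamma) < 0.01] <- 0.5
    beta <- runif(nch, -2, 2)
    mu <- runif(nch, -n_fan / 4, n_fan / 4)
    s2 <- runif(nch, 0.1, n_fan)
    fold <- fold_popcount_threshold(gamma, beta, mu, s2, n_fan)
    p <- matrix(sample(0:n_fan, 20 * nch, TRUE), 20, nch)
    pre <- array(as.integer(2 * p - n_fan), dim = c(20, 1, nch))
    got <- threshold_activate(pre, fold$gamma_sign, fold$popcount_threshold,
                              n_fan)
    ref <- array(0L, dim = dim(pre))
    for (c in seq_len(nch)) {
      ref[, , c] <- as.integer(oracle_bn_sign(pre[, , c], gamma[c], beta[c],
                                              mu[c], s2[c]) > 0)
    }
    expect_identical(got, ref)
  }
})

test_that("folding is idempotent and clamps unreachable thresholds", {
  f1 <- fold_popcount_threshold(1, 0, 0, 1, 9)
  f2 <- fold_popcount_threshold(1, 0, 0, 1, 9)
  expect_identical(f1, f2)
  # gamma > 0, threshold far below range -> always on
  expect_identical(fold_popcount_threshold(1, 100, 0, 1, 9)$popcount_threshold,
                   0L)
  # gamma > 0, threshold far above range -> always off
  expect_identical(fold_popcount_threshold(1, -100, 0, 1, 9)$popcount_threshold,
                   10L)
})

test_that("OR pooling equals float max pooling of the +-1 decoding", {
  z <- array(0L, dim = c(4, 4, 1))
  expect_true(all(or_maxpool(z) == 0))
  one <- z; one[2, 3, 1] <- 1L
  expect_identical(as.vector(or_maxpool(one)), c(0L, 0L, 1L, 0L))
  set.seed(13)
  for (rep_i in 1:40) {
    h <- sample(c(4, 6, 8, 9), 1); w <- sample(c(4, 6, 8, 9), 1)
    ch <- sample(1:5, 1)
    b <- array(rbinom(h * w * ch, 1, 0.3), dim = c(h, w, ch))
    got <- 2 * or_maxpool(b) - 1
    ref <- oracle_maxpool_pm1(b)
    expect_identical(as.numeric(got), as.numeric(ref))
  }
})

test_that("integer inference matches a dense float network layer by layer", {
  set.seed(99)
  for (rep_i in 1:12) {
    spec <- network_spec(sample(c(4, 8), 2, TRUE), c(2))
    model <- random_model(spec, seed = rep_i)
    bits <- matrix(rbinom(576, 1, 0.4), 24, 24)
    got <- bcnn_infer(model, bits)

    # float reference: dense conv, float threshold compare, float max pool
    x <- array(bits, dim = c(24, 24, 1))
    for (i in seq_along(spec$layers)) {
      ly <- spec$layers[[i]]
      if (ly$type == "conv") {
        pre <- oracle_conv_pm1(x, model$weights[[i]])
        n_fan <- ly$kernel^2 * ly$c_in
        ta <- 2 * model$bn[[i]]$popcount_threshold - n_fan
        act <- array(0L, dim = dim(pre))
        for (c in seq_len(ly$c_out)) {
          act[, , c] <- as.integer(model$bn[[i]]$gamma_sign[c] *
                                     (pre[, , c] - ta[c]) >= 0)
        }
        x <- array(as.integer(oracle_maxpool_pm1(act) > 0),
                   dim = c(dim(act)[1] %/% 2, dim(act)[2] %/% 2, ly$c_out))
      } else {
        v <- 2 * as.vector(aperm(x, c(2, 1, 3))) - 1
        wpm <- 2 * matrix(model$weights[[i]], nrow = ly$f_in) - 1
        scores_ref <- as.vector(t(wpm) %*% v)
      }
    }
    expect_identical(as.integer(got$scores), as.integer(scores_ref))
    expect_identical(got$class,
                     if (scores_ref[1] > scores_ref[2]) "fall" else "nonfall")
  }
})

test_that("inference tie-breaks to non-fall and final weights antisymmetric", {
  spec <- network_spec(c(4), c(2))
  model <- random_model(spec, seed = 3)
  # equal columns in the final FC force a tie
  model$weights[[2]][, 2] <- model$weights[[2]][, 1]
  bits <- matrix(rbinom(576, 1, 0.5), 24, 24)
  out <- bcnn_infer(model, bits)
  expect_identical(out$scores[["fall"]], out$scores[["nonfall"]])
  expect_identical(out$class, "nonfall")
  # flipping every final-layer bit swaps the scores
  m2 <- random_model(spec, seed = 4)
  o1 <- bcnn_infer(m2, bits)
  m2$weights[[2]] <- 1L - m2$weights[[2]]
  o2 <- bcnn_infer(m2, bits)
  expect_identical(unname(o1$scores), -unname(o2$scores))
})

test_that("training memorizes a tiny separable dataset and validates input", {
  set.seed(17)
  # four XOR-structured patterns: class by quadrant parity
  mk <- function(q) {
    m <- matrix(0L, 24, 24)
    if (q %in% c(1, 4)) m[1:12, 1:12] <- 1L
    if (q %in% c(2, 4)) m[13:24, 13:24] <- 1L
    m
  }
  specs <- array(0L, dim = c(24, 24, 8))
  for (i in 1:8) specs[, , i] <- mk((i - 1) %% 4 + 1)
  labels <- rep(c("fall", "nonfall", "nonfall", "fall"), 2)
  cfg <- train_config(epochs = 40, batch_size = 4, split = 1, seed = 2)
  model <- bcnn_train(specs, labels, network_spec(c(4), c(2)), cfg)
  expect_equal(model$meta$train_accuracy, 1)

  expect_error(bcnn_train(specs, rep("fall", 8), network_spec(c(4), c(2)),
                          cfg), "both classes")
  expect_error(bcnn_train(specs, rep("x", 8), network_spec(c(4), c(2)), cfg),
               "labels")
})

test_that("cross-validation returns per-fold metrics and LOSO needs subjects", {
  set.seed(23)
  cp <- corpus_480()
  idx <- c(1:24, 201:224)       # classes a (fall) and f (non-fall), 48 frames
  specs <- cp$specs[, , idx]
  labels <- cp$labels[idx]
  cfg <- train_config(epochs = 6, seed = 2)
  res <- evaluate_kfold(specs, labels, network_spec(c(4), c(2)), cfg, k = 4)
  expect_length(res$fold_accuracy, 4)
  expect_true(all(res$fold_accuracy >= 0 & res$fold_accuracy <= 1))
  expect_equal(res$mean, mean(res$fold_accuracy))
  expect_equal(res$sd, sd(res$fold_accuracy))
  expect_error(evaluate_kfold(specs, labels, network_spec(c(4), c(2)), cfg,
                              k = 1), "k must be")
  expect_error(evaluate_loso(specs, labels, NULL, network_spec(c(4), c(2)),
                             cfg), "subject_id")
  res_loso <- evaluate_loso(specs, labels, cp$subjects[idx],
                            network_spec(c(4), c(2)), cfg)
  expect_length(res_loso$fold_accuracy, length(unique(cp$subjects[idx])))
})
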