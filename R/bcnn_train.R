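#' Training configuration for the binarized network
#'
#' The training recipe: cross-entropy loss, Adam, batch size 32, 200 epochs,
#' and a stepwise learning-rate schedule of 0.005, 0.001, 0.0005, 0.0001,
#' 0.00005 and 0.00001 starting at epochs 0, 60, 100, 120, 140 and 160.
#' The dataset is shuffled, then split 80/20 into train and test.
#'
#' @param epochs number of training epochs.
#' @param batch_size minibatch size.
#' @param lr_schedule two-column matrix-like list of `(epoch, rate)` steps;
#'   epochs strictly increasing, rates strictly decreasing.
#' @param split training fraction of the shuffled dataset.
#' @param seed RNG seed for shuffling, weight init and batching.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, batch_size = 32L,
                         lr_schedule = list(c(0, 0.005), c(60, 0.001),
                                            c(100, 0.0005), c(120, 1e-4),
                                            c(140, 5e-5), c(160, 1e-5)),
                         split = 0.8, seed = 1L) {
  ep <- vapply(lr_schedule, `[`, numeric(1), 1L)
  lr <- vapply(lr_schedule, `[`, numeric(1), 2L)
  if (any(diff(ep) <= 0)) stop("schedule epochs must be strictly increasing")
  if (any(diff(lr) >= 0)) stop("schedule rates must be strictly decreasing")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_epochs = ep, lr_rates = lr,
                 split = split, seed = as.integer(seed)),
            class = "train_config")
}

lr_at <- function(cfg, epoch) {
  cfg$lr_rates[max(which(cfg$lr_epochs <= epoch))]
}

BN_EPS <- 1e-5

# ---- latent-weight network state ------------------------------------------

init_train_state <- function(spec) {
  st <- list(layers = vector("list", length(spec$layers)))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    wdim <- if (ly$type == "conv") c(ly$kernel, ly$kernel, ly$c_in, ly$c_out)
            else c(ly$f_in, ly$f_out)
    w <- array(stats::runif(prod(wdim), -1, 1), dim = wdim)
    lst <- list(w = w, mw = array(0, wdim), vw = array(0, wdim))
    if (ly$bn) {
      nch <- if (ly$type == "conv") ly$c_out else ly$f_out
      lst$gamma <- rep(1, nch); lst$beta <- rep(0, nch)
      lst$run_mean <- rep(0, nch); lst$run_var <- rep(1, nch)
      lst$mg <- rep(0, nch); lst$vg <- rep(0, nch)
      lst$mb <- rep(0, nch); lst$vb <- rep(0, nch)
    }
    st$layers[[i]] <- lst
  }
  st$t <- 0L
  st
}

sign_pm1 <- function(x) ifelse(x >= 0, 1, -1)

# conv forward on +-1 activations, batched: x [H,W,C,B], wb [k,k,Cin,Cout]
conv_fwd <- function(x, wb, idx) {
  d <- dim(x); k <- dim(wb)[1]; cout <- dim(wb)[4]
  ho <- d[1] - k + 1L; wo <- d[2] - k + 1L
  xmat <- matrix(x, nrow = d[1] * d[2] * d[3], ncol = d[4])
  cols <- xmat[as.vector(idx), , drop = FALSE]     # [fan*P, B]
  dim(cols) <- c(nrow(idx), ncol(idx) * d[4])      # [fan, P*B]
  wmat <- matrix(wb, nrow = nrow(idx))             # [fan, Cout]
  out <- crossprod(wmat, cols)                     # [Cout, P*B]
  dim(out) <- c(cout, ho, wo, d[4])
  list(pre = aperm(out, c(2, 3, 1, 4)), cols = cols)
}

conv_bwd <- function(dpre, cols, wb, idx, xdim, need_dx = TRUE) {
  k <- dim(wb)[1]; fan <- nrow(idx)
  dmat <- aperm(dpre, c(3, 1, 2, 4))               # [Cout, Ho, Wo, B]
  dim(dmat) <- c(dim(dpre)[3], ncol(idx) * xdim[4])
  wmat <- matrix(wb, nrow = fan)
  dw <- array(tcrossprod(cols, dmat), dim = dim(wb))
  dx <- NULL
  if (need_dx) {
    dcols <- wmat %*% dmat                         # [fan, P*B]
    dim(dcols) <- c(fan * ncol(idx), xdim[4])
    g <- as.vector(idx)
    r <- rowsum(dcols, group = g)
    dxm <- matrix(0, prod(xdim[1:3]), xdim[4])
    dxm[as.integer(rownames(r)), ] <- r
    dx <- array(dxm, dim = xdim)
  }
  list(dw = dw, dx = dx)
}

# batch norm over channels: x [H,W,C,B] (or [F,B] for FC with per-unit norm)
bn_fwd_train <- function(x, gamma, beta) {
  d <- dim(x)
  if (length(d) == 4L) {
    xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  } else {
    xm <- t(x)                                     # [B, F]
  }
  mu <- colMeans(xm)
  v <- colMeans(xm * xm) - mu * mu                 # biased batch variance
  inv <- 1 / sqrt(v + BN_EPS)
  xhat <- sweep(sweep(xm, 2, mu), 2, inv, `*`)
  ym <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  y <- if (length(d) == 4L) aperm(array(ym, dim = d[c(1, 2, 4, 3)]),
                                  c(1, 2, 4, 3))
       else t(ym)
  list(y = y, xhat = xhat, inv = inv, mu = mu, var = v)
}

bn_bwd <- function(dy, cache, gamma, xdim) {
  if (length(xdim) == 4L) {
    dym <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = xdim[3])
  } else {
    dym <- t(dy)
  }
  m <- nrow(dym)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  t1 <- sweep(dym, 2, dbeta / m)
  t2 <- sweep(cache$xhat, 2, dgamma / m, `*`)
  dxm <- sweep(t1 - t2, 2, gamma * cache$inv, `*`)
  dx <- if (length(xdim) == 4L) aperm(array(dxm, dim = xdim[c(1, 2, 4, 3)]),
                                      c(1, 2, 4, 3))
        else t(dxm)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

bn_fwd_eval <- function(x, lst) {
  d <- dim(x)
  inv <- 1 / sqrt(lst$run_var + BN_EPS)
  if (length(d) == 4L) {
    per <- d[1] * d[2]
    g <- rep(lst$gamma * inv, each = per)
    b <- rep(lst$beta - lst$gamma * inv * lst$run_mean, each = per)
    arr <- array(rep(g, d[4]) * as.vector(x) + rep(b, d[4]), dim = d)
    arr
  } else {
    (lst$gamma * inv) * x + (lst$beta - lst$gamma * inv * lst$run_mean)
  }
}

# 2x2/2 max pool on +-1 maps with first-max (top-left first) tie break
pool_fwd <- function(x) {
  d <- dim(x)
  ho <- d[1] %/% 2L; wo <- d[2] %/% 2L
  ri <- seq_len(2L * ho); ci <- seq_len(2L * wo)
  a <- x[ri, ci, , , drop = FALSE]
  s <- list(a[seq(1, 2 * ho, 2), seq(1, 2 * wo, 2), , , drop = FALSE],
            a[seq(2, 2 * ho, 2), seq(1, 2 * wo, 2), , , drop = FALSE],
            a[seq(1, 2 * ho, 2), seq(2, 2 * wo, 2), , , drop = FALSE],
            a[seq(2, 2 * ho, 2), seq(2, 2 * wo, 2), , , drop = FALSE])
  cand <- cbind(as.vector(s[[1]]), as.vector(s[[2]]),
                as.vector(s[[3]]), as.vector(s[[4]]))
  wm <- max.col(cand, ties.method = "first")
  out <- array(cand[cbind(seq_len(nrow(cand)), wm)], dim = c(ho, wo, d[3], d[4]))
  list(y = out, argmax = wm, xdim = d)
}

pool_bwd <- function(dy, cache) {
  d <- cache$xdim
  ho <- dim(dy)[1]; wo <- dim(dy)[2]
  dx <- array(0, dim = d)
  dyv <- as.vector(dy)
  rows <- list(seq(1, 2 * ho, 2), seq(2, 2 * ho, 2))
  cols <- list(seq(1, 2 * wo, 2), seq(2, 2 * wo, 2))
  slice_rc <- list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
  for (j in 1:4) {
    mask <- cache$argmax == j
    if (!any(mask)) next
    g <- array(dyv * mask, dim = dim(dy))
    rc <- slice_rc[[j]]
    dx[rows[[rc[1]]], cols[[rc[2]]], , ] <-
      dx[rows[[rc[1]]], cols[[rc[2]]], , , drop = FALSE] + g
  }
  dx
}

adam_step <- function(par, grad, m, v, lr, t, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  m <- b1 * m + (1 - b1) * grad
  v <- b2 * v + (1 - b2) * grad * grad
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  list(par = par - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

# full forward + backward on one minibatch; returns loss and updates state
train_batch <- function(st, spec, xb, yb, lr, idx_list) {
  nl <- length(spec$layers)
  caches <- vector("list", nl)
  x <- xb
  for (i in seq_len(nl)) {
    ly <- spec$layers[[i]]
    lst <- st$layers[[i]]
    wb <- sign_pm1(lst$w)
    if (ly$type == "conv") {
      cf <- conv_fwd(x, wb, idx_list[[i]])
      bn <- bn_fwd_train(cf$pre, lst$gamma, lst$beta)
      a <- sign_pm1(bn$y)
      pf <- pool_fwd(a)
      caches[[i]] <- list(xdim = dim(x), cols = cf$cols, bn = bn,
                          ste_mask = abs(bn$y) <= 1, pool = pf, wb = wb)
      x <- pf$y
    } else {
      v <- if (length(dim(x)) == 4L) {
        apply(x, 4, flatten_chw)                   # [Fin, B]
      } else x
      wmat <- matrix(wb, nrow = ly$f_in)
      z <- crossprod(wmat, v)                      # [Fout, B]
      if (ly$bn) {
        bn <- bn_fwd_train(z, lst$gamma, lst$beta)
        a <- sign_pm1(bn$y)
        caches[[i]] <- list(v = v, bn = bn, ste_mask = abs(bn$y) <= 1,
                            wb = wb, xdim4 = dim(x))
        x <- a
      } else {
        caches[[i]] <- list(v = v, wb = wb, xdim4 = dim(x))
        x <- z
      }
    }
    # update running stats
    if (ly$bn) {
      st$layers[[i]]$run_mean <- 0.9 * st$layers[[i]]$run_mean +
        0.1 * caches[[i]]$bn$mu
      st$layers[[i]]$run_var <- 0.9 * st$layers[[i]]$run_var +
        0.1 * caches[[i]]$bn$var
    }
  }
  logits <- x                                       # [2, B]
  B <- ncol(logits)
  zmax <- apply(logits, 2, max)
  ez <- exp(sweep(logits, 2, zmax))
  p <- sweep(ez, 2, colSums(ez), `/`)
  loss <- -mean(log(pmax(p[cbind(yb, seq_len(B))], 1e-12)))
  dz <- p
  dz[cbind(yb, seq_len(B))] <- dz[cbind(yb, seq_len(B))] - 1
  dz <- dz / B

  st$t <- st$t + 1L
  grads <- vector("list", nl)
  dout <- dz
  for (i in rev(seq_len(nl))) {
    ly <- spec$layers[[i]]
    lst <- st$layers[[i]]
    cc <- caches[[i]]
    if (ly$type == "fc") {
      if (ly$bn) {
        dyy <- dout * cc$ste_mask                   # STE through sign
        bb <- bn_bwd(dyy, cc$bn, lst$gamma, dim(cc$bn$y))
        dz_fc <- bb$dx
        grads[[i]]$dgamma <- bb$dgamma; grads[[i]]$dbeta <- bb$dbeta
      } else {
        dz_fc <- dout
      }
      wmat <- matrix(cc$wb, nrow = ly$f_in)
      grads[[i]]$dw <- array(tcrossprod(cc$v, dz_fc), dim = dim(lst$w))
      dv <- wmat %*% dz_fc                          # [Fin, B]
      if (i > 1L && !is.null(cc$xdim4) && length(cc$xdim4) == 4L) {
        d4 <- cc$xdim4
        B2 <- d4[4]
        dout <- array(0, dim = d4)
        for (b in seq_len(B2)) {
          tmp <- array(0, dim = d4[1:3])
          tmp <- aperm(array(dv[, b], dim = d4[c(2, 1, 3)]), c(2, 1, 3))
          dout[, , , b] <- tmp
        }
      } else {
        dout <- dv
      }
    } else {
      dpool <- pool_bwd(dout, cc$pool)
      dyy <- dpool * cc$ste_mask
      bb <- bn_bwd(dyy, cc$bn, lst$gamma, dim(cc$bn$y))
      grads[[i]]$dgamma <- bb$dgamma; grads[[i]]$dbeta <- bb$dbeta
      cb <- conv_bwd(bb$dx, cc$cols, cc$wb, idx_list[[i]], cc$xdim,
                     need_dx = i > 1L)
      grads[[i]]$dw <- cb$dw
      dout <- cb$dx
    }
  }

  for (i in seq_len(nl)) {
    lst <- st$layers[[i]]
    gw <- grads[[i]]$dw * (abs(lst$w) <= 1)         # STE clip on latent
    up <- adam_step(lst$w, gw, lst$mw, lst$vw, lr, st$t)
    st$layers[[i]]$w <- pmin(pmax(up$par, -1), 1)
    st$layers[[i]]$mw <- up$m; st$layers[[i]]$vw <- up$v
    if (!is.null(grads[[i]]$dgamma)) {
      ug <- adam_step(lst$gamma, grads[[i]]$dgamma, lst$mg, lst$vg, lr, st$t)
      st$layers[[i]]$gamma <- ug$par
      st$layers[[i]]$mg <- ug$m; st$layers[[i]]$vg <- ug$v
      ub <- adam_step(lst$beta, grads[[i]]$dbeta, lst$mb, lst$vb, lr, st$t)
      st$layers[[i]]$beta <- ub$par
      st$layers[[i]]$mb <- ub$m; st$layers[[i]]$vb <- ub$v
    }
  }
  list(state = st, loss = loss)
}

# eval-mode forward of the binarized float network (running BN stats);
# x [H,W,1,B] in +-1. Returns logits [2,B].
forward_eval <- function(st, spec, x, idx_list) {
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    lst <- st$layers[[i]]
    wb <- sign_pm1(lst$w)
    if (ly$type == "conv") {
      pre <- conv_fwd(x, wb, idx_list[[i]])$pre
      x <- pool_fwd(sign_pm1(bn_fwd_eval(pre, lst)))$y
    } else {
      v <- if (length(dim(x)) == 4L) apply(x, 4, flatten_chw) else x
      z <- crossprod(matrix(wb, nrow = ly$f_in), v)
      x <- if (ly$bn) sign_pm1(bn_fwd_eval(z, lst)) else z
    }
  }
  x
}

im2col_index_list <- function(spec) {
  out <- vector("list", length(spec$layers))
  size <- spec$input_size
  c_in <- 1L
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    if (ly$type == "conv") {
      out[[i]] <- im2col_indices(size, size, c_in, ly$kernel)
      size <- (size - ly$kernel + 1L) %/% 2L
      c_in <- ly$c_out
    }
  }
  out
}

#' Predictions of the pre-fold binarized float network
#'
#' Evaluates the trained network in its pre-fold form: binarized (+-1)
#' weights and activations but batch norm computed in floating point from
#' the running statistics, followed by sign. This is the model the integer
#' popcount thresholds are folded from; [bcnn_infer] on the folded model
#' must agree with it everywhere.
#'
#' @param model a [bcnn_model] carrying its float training state.
#' @param spectrograms 0/1 array `24 x 24 x n` (or a single matrix).
#' @return character vector of `"fall"` / `"nonfall"` predictions.
#' @export
predict_prefold <- function(model, spectrograms) {
  st <- model$meta$float_state
  if (is.null(st)) stop("model carries no float training state")
  x <- spec_input_array(spectrograms)
  logits <- forward_eval(st, model$spec, x, im2col_index_list(model$spec))
  ifelse(logits[1, ] > logits[2, ], "fall", "nonfall")
}

spec_input_array <- function(spectrograms) {
  if (is.matrix(spectrograms)) dim(spectrograms) <- c(dim(spectrograms), 1L)
  d <- dim(spectrograms)
  array(2 * as.numeric(spectrograms) - 1, dim = c(d[1], d[2], 1L, d[3]))
}

#' Predict fall / non-fall for a batch of spectrograms
#'
#' Integer XNOR/popcount inference ([bcnn_infer]) applied sample-wise.
#'
#' @param model a [bcnn_model].
#' @param spectrograms 0/1 array `24 x 24 x n` or a single matrix.
#' @return character vector of `"fall"` / `"nonfall"`.
#' @export
bcnn_predict <- function(model, spectrograms) {
  if (is.matrix(spectrograms)) dim(spectrograms) <- c(dim(spectrograms), 1L)
  n <- dim(spectrograms)[3]
  vapply(seq_len(n),
         function(i) bcnn_infer(model, spectrograms[, , i])$class,
         character(1))
}

#' Fold batch-norm parameters into integer popcount thresholds
#'
#' Maps per-channel batch-norm parameters to the all-integer activation
#' rule used at inference. With real threshold
#' `T = mu - (beta/gamma) * sqrt(sigma2 + eps)` and fan-in `N`, the output
#' bit for an integer pre-activation `x = 2p - N` (p the raw popcount) is 1
#' iff `sign(gamma) * (x - T) >= 0`. Because achievable pre-activations
#' share N's parity, this is exactly `p >= t` (gamma positive,
#' `t = ceiling((T + N)/2)`) or `p <= t` (gamma negative,
#' `t = floor((T + N)/2)`). Thresholds falling outside `[0, N + 1]` are
#' re-expressed as the equivalent always-on / always-off threshold so the
#' stored value stays in range without changing any achievable decision.
#'
#' @param gamma,beta,mu,sigma2 per-channel batch-norm parameters.
#' @param n_fan layer fan-in N.
#' @param eps batch-norm stability constant.
#' @return list with `gamma_sign` (+1/-1) and integer `popcount_threshold`
#'   in `[0, n_fan + 1]`, both per channel.
#' @export
fold_popcount_threshold <- function(gamma, beta, mu, sigma2, n_fan,
                                    eps = 1e-5) {
  fold <- fold_bn_to_threshold(gamma, beta, mu, sigma2, eps)
  tt <- fold$threshold
  gs <- fold$gamma_sign
  thr <- ifelse(gs > 0, ceiling((tt + n_fan) / 2), floor((tt + n_fan) / 2))
  for (j in seq_along(thr)) {
    if (gs[j] > 0) {
      if (thr[j] < 0) thr[j] <- 0                  # always 1
      if (thr[j] > n_fan + 1) thr[j] <- n_fan + 1  # always 0
    } else {
      if (thr[j] > n_fan) thr[j] <- n_fan + 1      # always 1 (p <= N+1)
      if (thr[j] < 0) { gs[j] <- 1; thr[j] <- n_fan + 1 }  # always 0
    }
  }
  list(gamma_sign = gs, popcount_threshold = as.integer(thr))
}

fold_layer <- function(lst, n_fan) {
  fold_popcount_threshold(lst$gamma, lst$beta, lst$run_mean, lst$run_var,
                          n_fan, BN_EPS)
}

fold_state <- function(st, spec, meta = list()) {
  nl <- length(spec$layers)
  weights <- vector("list", nl)
  bn <- vector("list", nl)
  for (i in seq_len(nl)) {
    ly <- spec$layers[[i]]
    lst <- st$layers[[i]]
    weights[[i]] <- array(as.integer(lst$w >= 0), dim = dim(lst$w))
    if (ly$bn) {
      n_fan <- if (ly$type == "conv") ly$kernel^2 * ly$c_in else ly$f_in
      bn[[i]] <- fold_layer(lst, n_fan)
    }
  }
  meta$float_state <- st
  bcnn_model(spec, weights, bn, meta)
}

#' Train a binarized network on labeled spectrograms
#'
#' Straight-through-estimator training: latent real weights in `[-1, 1]`
#' are binarized by sign on the forward pass; gradients pass through the
#' sign inside the clip range and are zeroed outside. Batch norm is trained
#' in float on every layer except the final fully connected one; the binary
#' activation's gradient uses the hard-tanh window. After training, batch
#' norm is folded into per-channel integer popcount thresholds and the
#' weights hardened to bits; the folded integer model's predictions match
#' the pre-fold float model exactly.
#'
#' The dataset is shuffled under the config seed and split into train/test;
#' the returned model's `meta` records the split, per-epoch losses and the
#' train/test accuracies of the folded model.
#'
#' @param spectrograms 0/1 array `24 x 24 x n`.
#' @param labels character/factor of `"fall"` / `"nonfall"` (activity codes
#'   `"a"`..`"l"` are mapped via [binary_label]).
#' @param spec a [network_spec].
#' @param cfg a [train_config].
#' @param verbose print per-epoch loss every 10 epochs.
#' @return a trained [bcnn_model].
#' @export
bcnn_train <- function(spectrograms, labels, spec = network_spec(c(32, 32, 32),
                                                                 c(32, 2)),
                       cfg = train_config(), verbose = FALSE) {
  labels <- as.character(labels)
  if (all(labels %in% letters[1:12])) labels <- binary_label(labels)
  if (!all(labels %in% c("fall", "nonfall"))) {
    stop("labels must be activity codes a-l or fall/nonfall")
  }
  n <- dim(spectrograms)[3]
  if (n < 2L || length(unique(labels)) < 2L) {
    stop("training needs both classes present")
  }
  if (length(labels) != n) stop("label/spectrogram count mismatch")

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  set.seed(cfg$seed)

  ord <- sample.int(n)
  n_train <- max(1L, floor(cfg$split * n))
  tr_idx <- ord[seq_len(n_train)]
  te_idx <- ord[-seq_len(n_train)]

  x_all <- spec_input_array(spectrograms)
  y_num <- ifelse(labels == "fall", 1L, 2L)

  st <- init_train_state(spec)
  idx_list <- im2col_index_list(spec)
  losses <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    lr <- lr_at(cfg, ep - 1L)
    perm <- sample(tr_idx)
    bs <- cfg$batch_size
    nb <- ceiling(length(perm) / bs)
    ep_loss <- 0
    for (b in seq_len(nb)) {
      bi <- perm[((b - 1L) * bs + 1L):min(b * bs, length(perm))]
      res <- train_batch(st, spec, x_all[, , , bi, drop = FALSE],
                         y_num[bi], lr, idx_list)
      st <- res$state
      ep_loss <- ep_loss + res$loss * length(bi)
    }
    losses[ep] <- ep_loss / length(perm)
    if (verbose && ep %% 10L == 0L) {
      message(sprintf("epoch %3d  loss %.4f  lr %g", ep, losses[ep], lr))
    }
  }

  model <- fold_state(st, spec, meta = list(
    seed = cfg$seed, epochs = cfg$epochs,
    split = sprintf("%d train / %d test (shuffled %g/%g)",
                    length(tr_idx), length(te_idx),
                    cfg$split, 1 - cfg$split),
    train_idx = tr_idx, test_idx = te_idx, losses = losses))
  pred_tr <- bcnn_predict(model, spectrograms[, , tr_idx, drop = FALSE])
  model$meta$train_accuracy <- mean(pred_tr == labels[tr_idx])
  if (length(te_idx) > 0L) {
    pred_te <- bcnn_predict(model, spectrograms[, , te_idx, drop = FALSE])
    model$meta$test_accuracy <- mean(pred_te == labels[te_idx])
  }
  model
}

#' Map activity codes to the binary fall / non-fall label
#'
#' Codes `"a"`..`"e"` are fall activities, `"f"`..`"l"` non-fall.
#'
#' @param code character vector of activity codes.
#' @return character vector of `"fall"` / `"nonfall"`.
#' @export
binary_label <- function(code) {
  if (!all(code %in% letters[1:12])) stop("activity codes are a-l")
  ifelse(code %in% letters[1:5], "fall", "nonfall")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
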