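test_that("synthesized frames follow CW Doppler physics", {
  cfg <- sim_config(noise_snr_db = Inf, n_per_class = 1)
  still <- structure(list(code = "z", description = "stationary",
                          direction_set = c(0), vert_frac = 0, amp = 1,
                          fall = FALSE, scatter_amps = c(1),
                          profile = function(t, t0, vs) cbind(torso = 0 * t)),
                     class = "activity_template")
  fr <- synthesize_activity(still, 0, cfg, seed = 1)
  expect_length(fr$samples, 1600)
  # stationary target: constant phase, all energy at Doppler bin 0
  mags <- oracle_float_magnitudes(fr$samples)
  expect_true(all(apply(mags, 2, which.max) == 1))

  # constant +1 m/s toward the radar: tone at 2v/lambda ~ 160.9 Hz
  mover <- still
  mover$profile <- function(t, t0, vs) cbind(torso = rep(1, length(t)))
  frm <- synthesize_activity(mover, 0, cfg, seed = 1)
  fd <- 2 * 1 / (299792458 / cfg$carrier_hz)
  expect_equal(fd, 160.9, tolerance = 1e-3)
  want_bin <- round(fd / (cfg$sample_rate_hz / 128)) + 1   # 1-based FFT bin
  mags <- oracle_float_magnitudes(frm$samples)
  expect_true(all(apply(mags[, 3:22], 2, which.max) == want_bin))

  # lateral motion: cos(90 deg) = 0, Doppler collapses to DC
  lat <- mover
  lat$direction_set <- c(90)
  frl <- synthesize_activity(lat, 90, cfg, seed = 1)
  magl <- oracle_float_magnitudes(frl$samples)
  expect_true(all(apply(magl, 2, which.max) == 1))

  expect_error(synthesize_activity(still, 45, cfg), "direction set")
  # Nyquist guard: 40 m/s would alias at fs = 2000 Hz
  fast <- mover
  fast$profile <- function(t, t0, vs) cbind(torso = rep(40, length(t)))
  expect_error(synthesize_activity(fast, 0, cfg, seed = 1), "Nyquist")
})

test_that("activity templates satisfy the kinematic class contract", {
  tpls <- activity_templates()
  expect_identical(names(tpls), letters[1:12])
  tt <- seq(0, 0.8, by = 1 / 2000)
  for (tpl in tpls) {
    v <- tpl$profile(tt, 0.15, 1)
    peak <- max(abs(v[, 1]))
    if (tpl$fall) {
      # impulsive: torso peak >= 1.5 m/s within 0.6 s of onset
      expect_gte(peak, 1.5)
      t_peak <- tt[which.max(abs(v[, 1]))] - 0.15
      expect_lte(t_peak, 0.6)
    } else if (!tpl$code %in% c("f", "g")) {       # gait classes are periodic
      expect_lte(peak, 1.0)
    }
  }
})

test_that("dataset generation is deterministic with faithful class ratios", {
  cfg <- sim_config(n_per_class = 3, seed = 5)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$frames, d2$frames)
  expect_identical(d1$manifest, d2$manifest)
  expect_true(all(vapply(d1$frames, function(f) length(f$samples),
                         integer(1)) == 1600L))
  expect_identical(sort(unique(d1$subject_id)), 1:5)

  # published class proportions under the default count map
  counts <- sim_config()$n_per_class
  expect_identical(unname(counts[["b"]] / counts[["a"]]), 2)
  expect_identical(sum(counts), 2570L)
  expect_error(generate_dataset(sim_config(n_per_class = 0)), "at least one")
})

test_that("fall classes dominate the off-center Doppler band", {
  cp <- corpus_480()
  is_fall <- binary_label(cp$labels) == "fall"
  # per-frame maximum Doppler extent of set bits (rows away from DC row 13)
  extent <- apply(cp$specs, 3, function(m) {
    rows <- which(rowSums(m) > 0)
    if (length(rows) == 0) 0 else max(abs(rows - 13))
  })
  expect_gt(mean(extent[is_fall]), mean(extent[!is_fall]))
  # nearly every fall frame lights up off-center bins
  off_center <- apply(cp$specs, 3, function(m) sum(m[-(12:14), ]) > 0)
  expect_gte(mean(off_center[is_fall]), 0.95)
})
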