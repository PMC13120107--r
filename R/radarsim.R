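#' Activity templates for the synthetic CW-radar generator
#'
#' Twelve activity templates mirroring the dataset design: five fall
#' activities (codes a-e) and seven non-fall daily activities (f-l). Each
#' template is a kinematic profile — piecewise radial-velocity functions of
#' one to three point scatterers (torso plus limbs, in m/s) — together with
#' the set of nominal motion directions relative to the radar line of sight
#' ({0, +-90, 180} degrees for standing falls; seated falls exclude
#' backward), a relative amplitude, a vertical-motion fraction (how much of
#' the motion is toward the floor, hence visible at any aspect angle), and
#' an event duration.
#'
#' Fall templates are impulsive: peak speed of at least 1.5 m/s reached
#' within 0.6 s of motion onset. Non-fall templates are either periodic
#' (gait) or peak below 1.0 m/s torso speed.
#'
#' @return named list of `activity_template` objects, codes `"a"`..`"l"`.
#' @export
activity_templates <- function() {
  pulse <- function(t, t0, width, vp) {
    u <- (t - t0) / width
    ifelse(u > 0 & u < 1, vp * sin(pi * u)^2, 0)
  }
  tpl <- function(code, description, directions, vert_frac, amp, fall,
                  scatter_amps, profile) {
    structure(list(code = code, description = description,
                   direction_set = directions, vert_frac = vert_frac,
                   amp = amp, fall = fall, scatter_amps = scatter_amps,
                   profile = profile),
              class = "activity_template")
  }
  list(
    a = tpl("a", "standing, then falling forward", c(0), 0.35, 1.0, TRUE,
            c(1, 0.4),
            function(t, t0, vs) cbind(torso = pulse(t, t0, 0.55, 2.8 * vs),
                                      limb = pulse(t, t0 + 0.05, 0.45,
                                                   3.6 * vs))),
    b = tpl("b", "standing, then falling to the left/right", c(-90, 90),
            0.35, 1.0, TRUE, c(1, 0.4),
            function(t, t0, vs) cbind(torso = pulse(t, t0, 0.55, 2.5 * vs),
                                      limb = pulse(t, t0 + 0.05, 0.45,
                                                   3.2 * vs))),
    c = tpl("c", "standing, then falling backward", c(180), 0.35, 1.0, TRUE,
            c(1, 0.4),
            function(t, t0, vs) cbind(torso = pulse(t, t0, 0.55, 2.6 * vs),
                                      limb = pulse(t, t0 + 0.05, 0.45,
                                                   3.3 * vs))),
    d = tpl("d", "sitting, then falling forward", c(0), 0.4, 0.9, TRUE,
            c(1, 0.35),
            function(t, t0, vs) cbind(torso = pulse(t, t0, 0.5, 1.9 * vs),
                                      limb = pulse(t, t0 + 0.04, 0.4,
                                                   2.5 * vs))),
    e = tpl("e", "sitting, then falling to the left/right", c(-90, 90),
            0.4, 0.9, TRUE, c(1, 0.35),
            function(t, t0, vs) cbind(torso = pulse(t, t0, 0.5, 1.8 * vs),
                                      limb = pulse(t, t0 + 0.04, 0.4,
                                                   2.4 * vs))),
    f = tpl("f", "walking slowly without moving arms", c(0, 180), 0.05,
            0.8, FALSE, c(1),
            function(t, t0, vs) cbind(torso = 0.5 * vs +
                                        0.08 * vs * sin(2 * pi * 1.6 * t))),
    g = tpl("g", "walking quickly while swinging arms", c(0, 180), 0.05,
            0.8, FALSE, c(1, 0.35),
            function(t, t0, vs) cbind(torso = 0.9 * vs +
                                        0.12 * vs * sin(2 * pi * 2 * t),
                                      arm = 0.9 * vs + 1.1 * vs *
                                        sin(2 * pi * 2 * t + 1))),
    h = tpl("h", "squatting", c(0, -90, 90, 180), 0.55, 0.8, FALSE, c(1),
            function(t, t0, vs) cbind(torso = 0.55 * vs *
                                        sin(2 * pi * (t - t0) / 1.3) *
                                        (t > t0 & t < t0 + 1.3))),
    i = tpl("i", "sitting on a chair", c(0, -90, 90), 0.55, 0.8, FALSE,
            c(1),
            function(t, t0, vs) cbind(torso = pulse(t, t0, 0.8, 0.65 * vs))),
    j = tpl("j", "standing up from sitting on a chair", c(0, -90, 90),
            0.55, 0.8, FALSE, c(1),
            function(t, t0, vs) cbind(torso = -pulse(t, t0, 0.8, 0.6 * vs))),
    k = tpl("k", "lying down, then lifting the upper body", c(0, -90, 90),
            0.5, 0.7, FALSE, c(1),
            function(t, t0, vs) cbind(torso = -pulse(t, t0 + 0.1, 0.7,
                                                     0.5 * vs))),
    l = tpl("l", "lying down", c(0, -90, 90), 0.5, 0.8, FALSE, c(1),
            function(t, t0, vs) cbind(torso = pulse(t, t0, 0.9, 0.85 * vs)))
  )
}

#' @export
print.activity_template <- function(x, ...) {
  cat(sprintf("<activity_template %s: %s (%s)>\n", x$code, x$description,
              if (x$fall) "fall" else "non-fall"))
  invisible(x)
}

#' Published per-class sample counts of the acquisition campaign
#' @return named integer vector, codes `"a"`..`"l"`.
#' @export
table_counts <- function() {
  c(a = 170L, b = 340L, c = 170L, d = 150L, e = 300L, f = 145L, g = 145L,
    h = 265L, i = 190L, j = 190L, k = 240L, l = 265L)
}

#' Synthetic CW-radar generator configuration
#'
#' @param sample_rate_hz baseband ADC rate; 2000 Hz keeps every template's
#'   Doppler inside Nyquist and makes one 1600-sample frame 0.8 s long.
#' @param carrier_hz radar carrier (24.125 GHz, the sensor's band).
#' @param noise_snr_db additive complex-Gaussian noise level relative to
#'   signal power.
#' @param amp_base baseband amplitude of a unit-amplitude scatterer, in the
#'   real units of the Q(16,11) datapath; the default places typical
#'   spectrogram magnitudes astride the raw-1140 binarization threshold.
#' @param n_per_class per-class sample counts: a single integer (uniform),
#'   a named vector by code, or `"table"` for counts proportional to the
#'   published acquisition campaign.
#' @param n_subjects synthetic subject pool for LOSO splits.
#' @param seed master RNG seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(sample_rate_hz = 2000, carrier_hz = 24.125e9,
                       noise_snr_db = 20, amp_base = 0.15,
                       n_per_class = "table", n_subjects = 5L, seed = 0L) {
  if (identical(n_per_class, "table")) {
    n_per_class <- table_counts()
  } else if (length(n_per_class) == 1L && is.numeric(n_per_class)) {
    n_per_class <- stats::setNames(rep(as.integer(n_per_class), 12L),
                                   letters[1:12])
  }
  if (any(n_per_class < 1L)) stop("need at least one sample per class")
  structure(list(sample_rate_hz = sample_rate_hz, carrier_hz = carrier_hz,
                 noise_snr_db = noise_snr_db, amp_base = amp_base,
                 n_per_class = n_per_class,
                 n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed)),
            class = "sim_config")
}

doppler_per_mps <- function(carrier_hz) {
  lambda <- 299792458 / carrier_hz
  2 / lambda
}

#' Synthesize one activity frame
#'
#' Point-scatterer CW baseband model: each scatterer contributes
#' `a_i * exp(1i * (4*pi/lambda) * r_i(t))` with `r_i(t)` the integral of
#' its radial velocity `v_i(t) * cos(direction)`, plus complex Gaussian
#' noise. Exactly `frame_length()` samples, with the event pulse centered
#' in the frame. Deterministic under `seed`.
#'
#' @param template an entry of [activity_templates] (or its code).
#' @param direction nominal direction in degrees; must belong to the
#'   template's direction set.
#' @param cfg a [sim_config].
#' @param seed RNG seed for the noise and jitter draws.
#' @param projection radial projection factor; defaults to
#'   `cos(direction * pi / 180)`. The dataset generator passes jittered
#'   aspect projections here.
#' @param vel_scale velocity multiplier (subject/sample jitter).
#' @param amp_scale amplitude multiplier.
#' @param t0 motion onset time in seconds.
#' @return a [radar_frame].
#' @export
synthesize_activity <- function(template, direction, cfg = sim_config(),
                                seed = 0L,
                                projection = cos(direction * pi / 180),
                                vel_scale = 1, amp_scale = 1, t0 = 0.15) {
  if (is.character(template)) template <- activity_templates()[[template]]
  stopifnot(inherits(template, "activity_template"))
  if (!direction %in% template$direction_set) {
    stop("direction ", direction, " not in template ", template$code,
         "'s direction set")
  }
  fs <- cfg$sample_rate_hz
  n <- frame_length()
  tt <- (0:(n - 1L)) / fs
  v <- template$profile(tt, t0, vel_scale)         # [n, n_scatterers], m/s
  v_rad <- v * projection
  fd_max <- max(abs(v_rad)) * doppler_per_mps(cfg$carrier_hz)
  if (fd_max >= fs / 2) {
    stop("Nyquist violation for template ", template$code,
         ": peak Doppler ", round(fd_max), " Hz at fs ", fs, " Hz")
  }
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  set.seed(seed)
  dt <- 1 / fs
  lambda <- 299792458 / cfg$carrier_hz
  sig <- complex(real = rep(0, n), imaginary = rep(0, n))
  base <- cfg$amp_base * template$amp * amp_scale
  for (s in seq_len(ncol(v))) {
    r <- cumsum(v_rad[, s]) * dt
    scat_amp <- base * template$scatter_amps[s]
    phase0 <- stats::runif(1, 0, 2 * pi)
    sig <- sig + scat_amp * exp(1i * (4 * pi / lambda * r + phase0))
  }
  if (is.finite(cfg$noise_snr_db)) {
    p_sig <- mean(Mod(sig)^2)
    p_noise <- p_sig / 10^(cfg$noise_snr_db / 10)
    sd_n <- sqrt(p_noise / 2)
    sig <- sig + complex(real = stats::rnorm(n, 0, sd_n),
                         imaginary = stats::rnorm(n, 0, sd_n))
  }
  radar_frame(sig, sample_rate_hz = fs, label = template$code)
}

#' Generate a labeled synthetic dataset
#'
#' Draws `n_per_class` frames per activity. Every frame gets per-sample
#' jitter from the seeded RNG: direction drawn from the template's
#' direction set, an aspect-angle jitter of up to +-25 degrees around it,
#' amplitude and velocity-scale jitter, onset-timing jitter, and noise.
#' The radial projection is `|cos|` of the jittered aspect, floored at the
#' template's vertical-motion fraction (a falling or sitting body always
#' has a motion component visible to the radar regardless of aspect).
#' Synthetic subject ids 1..`n_subjects` are assigned cyclically, each with
#' a fixed velocity multiplier, enabling leave-one-subject-out splits.
#' Byte-identical regeneration from the same config; the manifest records
#' every per-frame draw.
#'
#' @param cfg a [sim_config].
#' @return list with `frames` (list of [radar_frame]), `labels`,
#'   `subject_id`, and `manifest` (data frame of all per-frame parameters).
#' @export
generate_dataset <- function(cfg = sim_config()) {
  tpls <- activity_templates()
  counts <- cfg$n_per_class
  if (length(counts) == 0L) stop("empty class map")
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  set.seed(cfg$seed)
  subj_vel <- seq(0.9, 1.1, length.out = cfg$n_subjects)

  rows <- list()
  frames <- list()
  idx <- 0L
  for (code in names(counts)) {
    tpl <- tpls[[code]]
    for (rep_i in seq_len(counts[[code]])) {
      idx <- idx + 1L
      subject <- ((idx - 1L) %% cfg$n_subjects) + 1L
      direction <-
        tpl$direction_set[sample.int(length(tpl$direction_set), 1L)]
      aspect <- direction + stats::runif(1, -25, 25)
      proj_mag <- max(abs(cos(aspect * pi / 180)), tpl$vert_frac)
      proj_sign <- if (abs(cos(direction * pi / 180)) >= tpl$vert_frac) {
        sign(cos(direction * pi / 180))
      } else sample(c(-1, 1), 1L)
      projection <- proj_sign * proj_mag
      vel_scale <- subj_vel[subject] * stats::runif(1, 0.85, 1.15)
      amp_scale <- stats::runif(1, 0.8, 1.25)
      t0 <- 0.15 + stats::runif(1, -0.07, 0.07)
      frame_seed <- sample.int(2^30, 1L)
      fr <- synthesize_activity(tpl, direction, cfg, seed = frame_seed,
                                projection = projection,
                                vel_scale = vel_scale,
                                amp_scale = amp_scale, t0 = t0)
      fr$subject_id <- subject
      frames[[idx]] <- fr
      rows[[idx]] <- data.frame(
        index = idx, code = code, subject_id = subject,
        direction = direction, projection = projection,
        vel_scale = vel_scale, amp_scale = amp_scale, t0 = t0,
        frame_seed = frame_seed, noise_snr_db = cfg$noise_snr_db,
        amp_base = cfg$amp_base, sample_rate_hz = cfg$sample_rate_hz,
        master_seed = cfg$seed)
    }
  }
  manifest <- do.call(rbind, rows)
  list(frames = frames,
       labels = manifest$code,
       subject_id = manifest$subject_id,
       manifest = manifest)
}

#' Preprocess a frame collection into a spectrogram array
#'
#' Runs [stft_binary_spectrogram] over a list of frames.
#'
#' @param frames list of [radar_frame]s (or the list returned by
#'   [generate_dataset]).
#' @param cfg an [stft_config].
#' @param arithmetic `"fixed"` or `"float"` datapath.
#' @return 0/1 array `24 x 24 x n`.
#' @export
preprocess_frames <- function(frames, cfg = stft_config(),
                              arithmetic = "fixed") {
  if (!is.null(frames$frames)) frames <- frames$frames
  n <- length(frames)
  out <- array(0L, dim = c(cfg$n_kept_bins, cfg$n_columns, n))
  for (i in seq_len(n)) {
    out[, , i] <- stft_binary_spectrogram(frames[[i]], cfg,
                                          arithmetic = arithmetic)$bits
  }
  out
}

#' The standard seeded synthetic corpus
#'
#' Convenience wrapper: 40 frames per class (480 total) at seed 0 under the
#' default generator settings — the corpus size used throughout the test
#' suite and examples. Pass `n_per_class = "table"` for a corpus with the
#' published class proportions.
#'
#' @param n_per_class forwarded to [sim_config].
#' @param seed forwarded to [sim_config].
#' @return as [generate_dataset].
#' @export
synthetic_corpus <- function(n_per_class = 40L, seed = 0L) {
  generate_dataset(sim_config(n_per_class = n_per_class, seed = seed))
}
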