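#' rTMS pulse schedule
#'
#' Builds the pulse-time schedule of a repetitive transcranial magnetic
#' stimulation protocol: `n_trains` trains of `train_duration` seconds at
#' `pulse_rate` Hz, separated by `inter_train_interval` seconds. The first
#' pulse of each train falls exactly at the train onset. By package
#' convention the trailing inter-train interval is counted in the protocol
#' duration, so 24 trains of 10 s at 5 Hz with 5-s intervals give 1200 pulses
#' over 6 minutes.
#'
#' @param n_trains number of trains (> 0).
#' @param train_duration train length in seconds (> 0).
#' @param pulse_rate within-train pulse rate in Hz (> 0).
#' @param inter_train_interval pause between trains in seconds (>= 0).
#' @return Object of class `pulse_schedule`: list with `pulse_times` (s),
#'   `n_pulses`, `duration` (s) and the four input parameters.
#' @export
#' @examples
#' sched <- generate_rtms_schedule(24, 10, 5, 5)
#' sched$n_pulses      # 1200
#' sched$duration / 60 # 6 minutes
generate_rtms_schedule <- function(n_trains, train_duration, pulse_rate,
                                   inter_train_interval) {
  assert_scalar_pos(n_trains, "n_trains")
  assert_scalar_pos(train_duration, "train_duration")
  assert_scalar_pos(pulse_rate, "pulse_rate")
  assert_scalar_pos(inter_train_interval, "inter_train_interval", strict = FALSE)
  if (n_trains != round(n_trains)) stop_invalid("`n_trains` must be integer")

  per_train <- train_duration * pulse_rate
  if (abs(per_train - round(per_train)) > 1e-9) {
    stop_invalid("train_duration x pulse_rate must be a whole pulse count")
  }
  per_train <- round(per_train)
  onsets <- (seq_len(n_trains) - 1) * (train_duration + inter_train_interval)
  within <- (seq_len(per_train) - 1) / pulse_rate
  times <- as.vector(outer(within, onsets, `+`))
  structure(list(
    pulse_times = times,
    n_pulses = length(times),
    n_trains = n_trains,
    train_duration = train_duration,
    pulse_rate = pulse_rate,
    inter_train_interval = inter_train_interval,
    duration = n_trains * (train_duration + inter_train_interval)
  ), class = "pulse_schedule")
}

#' Count stimulus harmonics inside the usable EEG band
#'
#' Number of harmonics of stimulation frequency `f` at or below `limit` Hz
#' (default 100 Hz, the conventional upper edge of meaningful scalp EEG).
#' A 20 Hz stimulus has 5, a 30 Hz stimulus 3, and a 40 Hz stimulus 2.
#'
#' @param f stimulation frequency in Hz.
#' @param limit upper frequency bound in Hz.
#' @return Integer harmonic count.
#' @export
n_harmonics_below <- function(f, limit = 100) {
  assert_scalar_pos(f, "f")
  assert_scalar_pos(limit, "limit")
  as.integer(floor(limit / f + 1e-9))
}

#' SSVEP session layout
#'
#' Describes the stimulus layout of one SSVEP session: frequency bands, number
#' of 1 Hz-spaced targets per band, blocks, and trial timing. Defaults encode
#' the four-band (LF 8-12, MF 18-22, HF 28-32, SHF 38-42 Hz), five-target,
#' four-block layout with 0.5 s cue, 4 s flicker, and 0.5 s rest per trial.
#'
#' @param bands named list of `c(lo, hi)` band edges in Hz.
#' @param targets_per_band targets per band (>= 2).
#' @param target_spacing spacing between targets in Hz.
#' @param n_blocks number of blocks.
#' @param cue_s,flicker_s,rest_s trial phase durations in seconds.
#' @param fs sampling rate in Hz.
#' @param channel_names montage labels.
#' @return Object of class `session_spec`.
#' @export
session_spec <- function(bands = list(LF = c(8, 12), MF = c(18, 22),
                                      HF = c(28, 32), SHF = c(38, 42)),
                         targets_per_band = 5, target_spacing = 1,
                         n_blocks = 4, cue_s = 0.5, flicker_s = 4,
                         rest_s = 0.5, fs = 250,
                         channel_names = standard_montage_64()$label) {
  if (targets_per_band < 2) stop_invalid("targets_per_band must be >= 2")
  assert_scalar_pos(flicker_s, "flicker_s")
  assert_scalar_pos(fs, "fs")
  for (nm in names(bands)) {
    fmax <- bands[[nm]][1] + (targets_per_band - 1) * target_spacing
    if (fmax >= fs / 2) {
      stop_invalid("band %s has target %.1f Hz at or above Nyquist", nm, fmax)
    }
  }
  structure(list(bands = bands, targets_per_band = targets_per_band,
                 target_spacing = target_spacing, n_blocks = n_blocks,
                 cue_s = cue_s, flicker_s = flicker_s, rest_s = rest_s,
                 fs = fs, channel_names = channel_names),
            class = "session_spec")
}

#' Target frequencies of a band
#' @param spec a [session_spec()].
#' @param band band name.
#' @return Numeric vector of target frequencies in Hz.
#' @export
band_targets <- function(spec, band) {
  lo <- spec$bands[[band]][1]
  lo + (seq_len(spec$targets_per_band) - 1) * spec$target_spacing
}

#' Neuromodulation effect configuration
#'
#' Ground-truth effect of the stimulation arm on the generated EEG. The
#' mechanism emulated is suppression of occipital task-unrelated background
#' power (`background_gain` < 1 under real stimulation), an optional change of
#' alpha-rhythm power (`alpha_gain`), and an increased rate of microstate-B
#' segments (`microstateB_occurrence_gain`). Sham stimulation and the
#' pre-stimulation timepoint carry unit gains by definition.
#'
#' @param condition `"real"` or `"sham"`.
#' @param timepoint `"Pre"`, `"Post0"` or `"Post20"`.
#' @param background_gain multiplicative factor on occipital 1/f background
#'   power (<= 1 means suppression).
#' @param alpha_gain factor on 8-12 Hz rhythm power.
#' @param microstateB_occurrence_gain factor on the rate of class-B segments.
#' @param subject_pt phosphene-threshold covariate, % of stimulator output.
#' @return Object of class `effect_config`.
#' @export
effect_config <- function(condition = c("sham", "real"),
                          timepoint = c("Pre", "Post0", "Post20"),
                          background_gain = 1, alpha_gain = 1,
                          microstateB_occurrence_gain = 1,
                          subject_pt = NA_real_) {
  condition <- match.arg(condition)
  timepoint <- match.arg(timepoint)
  gains <- c(background_gain, alpha_gain, microstateB_occurrence_gain)
  if (any(!is.finite(gains)) || any(gains <= 0)) {
    stop_invalid("all effect gains must be finite and > 0")
  }
  if ((condition == "sham" || timepoint == "Pre") && any(gains != 1)) {
    stop_invalid("sham condition and Pre timepoint imply unit gains")
  }
  structure(list(condition = condition, timepoint = timepoint,
                 background_gain = background_gain, alpha_gain = alpha_gain,
                 microstateB_occurrence_gain = microstateB_occurrence_gain,
                 subject_pt = subject_pt),
            class = "effect_config")
}

#' Generative signal model for synthetic SSVEP EEG
#'
#' Parameters of the trial generator: an occipitally weighted harmonic series
#' at the stimulation frequency (fundamental amplitude `fundamental_amp`,
#' geometric harmonic decay `harmonic_decay`, `n_harmonics` harmonics), a
#' 1/f^`noise_exponent` background of RMS `noise_scale` per channel, and an
#' occipital alpha rhythm of amplitude `alpha_amp` at `alpha_freq`.
#'
#' @param fundamental_amp amplitude of the fundamental in uV.
#' @param harmonic_decay geometric decay ratio r in (0, 1]; harmonic h has
#'   amplitude `fundamental_amp * r^(h-1)`.
#' @param n_harmonics number of harmonics H (fundamental included).
#' @param phase stimulus phase in radians.
#' @param topography per-channel source weights, max 1 (default Gaussian
#'   around Oz, see [occipital_topography()]).
#' @param noise_exponent spectral slope chi of the 1/f^chi background.
#' @param noise_scale background RMS per channel in uV.
#' @param alpha_freq alpha rhythm frequency in Hz.
#' @param alpha_amp alpha rhythm amplitude in uV at the topography peak.
#' @param channel_names montage labels.
#' @return Object of class `signal_model`.
#' @export
signal_model <- function(fundamental_amp = 1.5, harmonic_decay = 0.5,
                         n_harmonics = 2, phase = 0,
                         topography = NULL, noise_exponent = 1,
                         noise_scale = 5, alpha_freq = 10, alpha_amp = 2,
                         channel_names = standard_montage_64()$label) {
  if (harmonic_decay <= 0 || harmonic_decay > 1) {
    stop_invalid("harmonic_decay must be in (0, 1]")
  }
  if (n_harmonics < 1) stop_invalid("n_harmonics must be >= 1")
  if (is.null(topography)) topography <- occipital_topography(channel_names)
  if (!all(is.finite(topography))) stop_invalid("topography must be finite")
  topography <- topography / max(topography)
  structure(list(fundamental_amp = fundamental_amp,
                 harmonic_decay = harmonic_decay,
                 n_harmonics = as.integer(n_harmonics), phase = phase,
                 topography = topography, noise_exponent = noise_exponent,
                 noise_scale = noise_scale, alpha_freq = alpha_freq,
                 alpha_amp = alpha_amp, channel_names = channel_names),
            class = "signal_model")
}

# 1/f^chi noise: spectrally shaped white Gaussian noise, unit RMS.
pink_noise <- function(n, fs, chi) {
  w <- stats::rnorm(n)
  if (chi == 0) return(w / stats::sd(w))
  X <- stats::fft(w)
  f <- c(0, seq_len(n - 1)) / n * fs
  f <- pmin(f, fs - f)            # two-sided frequency magnitude
  shape <- ifelse(f > 0, f^(-chi / 2), 0)
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Occipital channel mask used when applying effect gains.
occipital_mask <- function(channel_names) {
  channel_names %in% occipital_montage()
}

#' Generate one synthetic SSVEP trial
#'
#' One flicker epoch: occipitally weighted harmonic series at target frequency
#' `f`, plus 1/f background noise and an alpha rhythm. Effect gains act on the
#' power of the background (and alpha) on occipital channels, leaving the
#' stimulus-locked component untouched; this is the generator's ground-truth
#' mechanism. Deterministic given `seed`.
#'
#' @param f target frequency in Hz (< fs/2; all harmonics must stay below
#'   Nyquist).
#' @param model a [signal_model()].
#' @param effect an [effect_config()].
#' @param duration trial length in seconds.
#' @param fs sampling rate in Hz.
#' @param seed RNG seed.
#' @return Object of class `ssvep_trial`: list with `data` (channels x
#'   samples, uV), `fs`, `channel_names`, `f_target`, and the effect applied.
#' @export
generate_ssvep_trial <- function(f, model, effect = effect_config(),
                                 duration = 4, fs = 250, seed = 1) {
  assert_scalar_pos(duration, "duration")
  if (f >= fs / 2) stop_invalid("target %g Hz at or above Nyquist", f)
  H <- model$n_harmonics
  if (H * f >= fs / 2) {
    stop_invalid("harmonic %d of %g Hz is at or above Nyquist (%g Hz)",
                 H, f, fs / 2)
  }
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1) / fs
  amps <- model$fundamental_amp * model$harmonic_decay^(seq_len(H) - 1)
  src <- rep(0, n)
  for (h in seq_len(H)) {
    src <- src + amps[h] * sin(2 * pi * h * f * tt + h * model$phase)
  }
  C <- length(model$channel_names)
  data <- outer(model$topography, src)    # C x n
  occ <- occipital_mask(model$channel_names)
  bg_amp <- ifelse(occ, sqrt(effect$background_gain), 1)
  with_seed(seed, {
    if (model$noise_scale > 0) {
      noise <- t(vapply(seq_len(C), function(i) {
        pink_noise(n, fs, model$noise_exponent)
      }, numeric(n)))
      data <- data + (model$noise_scale * bg_amp) * noise
    }
    if (model$alpha_amp > 0) {
      aphase <- stats::runif(1, 0, 2 * pi)
      alpha <- sin(2 * pi * model$alpha_freq * tt + aphase)
      a_amp <- model$alpha_amp * sqrt(effect$alpha_gain)
      data <- data + (a_amp * model$topography) %o% alpha
    }
  })
  rownames(data) <- model$channel_names
  structure(list(data = data, fs = fs, channel_names = model$channel_names,
                 f_target = f, effect = effect),
            class = "ssvep_trial")
}

#' Generate a full SSVEP session
#'
#' One trial per (block, band, target), with band order and within-band target
#' order randomized independently per block (seeded). Per-target stimulus
#' phases follow the sampled-phase convention `0.35 * pi * (k - 1)`.
#'
#' @param spec a [session_spec()].
#' @param model a [signal_model()].
#' @param effect an [effect_config()].
#' @param seed RNG seed; per-trial noise seeds are derived from it.
#' @return Object of class `trial_set`: `data` array (channels x samples x
#'   trials), `info` data.frame (`block`, `band`, `f_target`, `order`,
#'   `condition`, `timepoint`), `fs`, `channel_names`.
#' @export
generate_session <- function(spec = session_spec(), model = signal_model(),
                             effect = effect_config(), seed = 1) {
  if (!identical(model$channel_names, spec$channel_names)) {
    stop_invalid("signal model and session spec must share the channel set")
  }
  n <- round(spec$flicker_s * spec$fs)
  bands <- names(spec$bands)
  rows <- list()
  with_seed(derive_seed(seed, "order"), {
    for (blk in seq_len(spec$n_blocks)) {
      for (bnd in sample(bands)) {
        targ <- band_targets(spec, bnd)
        for (k in sample(seq_along(targ))) {
          rows[[length(rows) + 1L]] <-
            data.frame(block = blk, band = bnd, f_target = targ[k],
                       target_index = k, stringsAsFactors = FALSE)
        }
      }
    }
  })
  info <- do.call(rbind, rows)
  info$order <- seq_len(nrow(info))
  info$condition <- effect$condition
  info$timepoint <- effect$timepoint
  data <- array(0, dim = c(length(spec$channel_names), n, nrow(info)),
                dimnames = list(spec$channel_names, NULL, NULL))
  for (i in seq_len(nrow(info))) {
    m <- model
    m$phase <- 0.35 * pi * (info$target_index[i] - 1)
    tr <- generate_ssvep_trial(
      info$f_target[i], m, effect, spec$flicker_s, spec$fs,
      seed = derive_seed(seed, "trial", info$block[i], info$band[i],
                         info$target_index[i]))
    data[, , i] <- tr$data
  }
  structure(list(data = data, info = info, fs = spec$fs,
                 channel_names = spec$channel_names),
            class = "trial_set")
}

#' Generate a resting-state recording
#'
#' Background-only EEG (1/f noise plus alpha rhythm, no stimulus-locked
#' component), with effect gains applied as in [generate_ssvep_trial()].
#'
#' @inheritParams generate_ssvep_trial
#' @return An [eeg_recording()].
#' @export
generate_resting_recording <- function(model = signal_model(),
                                       effect = effect_config(),
                                       duration = 120, fs = 250, seed = 1) {
  assert_scalar_pos(duration, "duration")
  n <- round(duration * fs)
  C <- length(model$channel_names)
  data <- matrix(0, C, n)
  occ <- occipital_mask(model$channel_names)
  bg_amp <- ifelse(occ, sqrt(effect$background_gain), 1)
  with_seed(seed, {
    if (model$noise_scale > 0) {
      for (i in seq_len(C)) {
        data[i, ] <- (model$noise_scale * bg_amp[i]) *
          pink_noise(n, fs, model$noise_exponent)
      }
    }
    if (model$alpha_amp > 0) {
      tt <- (seq_len(n) - 1) / fs
      aphase <- stats::runif(1, 0, 2 * pi)
      alpha <- sin(2 * pi * model$alpha_freq * tt + aphase)
      data <- data + (model$alpha_amp * sqrt(effect$alpha_gain) *
                        model$topography) %o% alpha
    }
  })
  rownames(data) <- model$channel_names
  eeg_recording(data, fs, model$channel_names)
}

#' Canonical microstate template topographies
#'
#' Four documented dipolar template maps used both as generator defaults and
#' for naming fitted maps A-D: A and B are the two diagonal
#' occipito-frontal gradients, C is the anterior-posterior gradient, and D a
#' fronto-central focal map. Average-referenced, unit L2 norm.
#'
#' @param channel_names montage labels.
#' @return Matrix k x channels with rownames A-D.
#' @export
canonical_microstate_templates <- function(channel_names = standard_montage_64()$label) {
  mon <- standard_montage_64()
  idx <- match(channel_names, mon$label)
  if (anyNA(idx)) stop_invalid("unknown channel label(s) in montage")
  xyz <- as.matrix(mon[idx, c("x", "y", "z")])
  proj <- function(v) xyz %*% v / sqrt(sum(v^2))
  fc <- match("FC1", mon$label)
  ctr <- colMeans(mon[match(c("FC1", "FC2", "Fz"), mon$label), c("x", "y", "z")])
  dctr <- sqrt(rowSums(sweep(xyz, 2, as.numeric(ctr))^2))
  maps <- rbind(
    A = as.numeric(proj(c(1, 1, 0))),     # right-frontal vs left-occipital
    B = as.numeric(proj(c(-1, 1, 0))),    # left-frontal vs right-occipital
    C = as.numeric(proj(c(0, 1, 0))),     # anterior vs posterior
    D = exp(-dctr^2 / (2 * 0.045^2))      # fronto-central focal
  )
  maps <- maps - rowMeans(maps)
  maps / sqrt(rowSums(maps^2))
}

#' Microstate sequence generator settings
#'
#' Semi-Markov generative model for microstate-structured EEG: class dwell
#' times are gamma-distributed around `mean_dwell`, class-to-class jumps
#' follow `transition_matrix` (zero diagonal, row-stochastic), and the active
#' map is rendered through an oscillatory global-field-power envelope plus
#' sensor noise.
#'
#' @param maps k x channels template maps (default the canonical A-D set).
#' @param transition_matrix k x k row-stochastic matrix with zero diagonal.
#' @param mean_dwell mean dwell time in ms, scalar or per class.
#' @param dwell_shape gamma shape of the dwell distribution.
#' @param gfp_envelope_scale envelope amplitude in uV.
#' @param sensor_noise_sd additive white sensor noise SD in uV.
#' @param channel_names montage labels.
#' @return Object of class `microstate_gen_spec`.
#' @export
microstate_gen_spec <- function(maps = NULL, transition_matrix = NULL,
                                mean_dwell = 80, dwell_shape = 2,
                                gfp_envelope_scale = 5, sensor_noise_sd = 1,
                                channel_names = standard_montage_64()$label) {
  if (is.null(maps)) maps <- canonical_microstate_templates(channel_names)
  k <- nrow(maps)
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(1 / (k - 1), k, k)
    diag(transition_matrix) <- 0
  }
  if (any(diag(transition_matrix) != 0)) {
    stop_invalid("transition_matrix must have zero diagonal")
  }
  if (any(abs(rowSums(transition_matrix) - 1) > 1e-12) ||
      any(transition_matrix < 0)) {
    stop_invalid("transition_matrix rows must be non-negative and sum to 1")
  }
  if (any(mean_dwell <= 0)) stop_invalid("mean_dwell must be > 0")
  mean_dwell <- rep_len(mean_dwell, k)
  structure(list(maps = maps, k = k, transition_matrix = transition_matrix,
                 mean_dwell = mean_dwell, dwell_shape = dwell_shape,
                 gfp_envelope_scale = gfp_envelope_scale,
                 sensor_noise_sd = sensor_noise_sd,
                 channel_names = channel_names),
            class = "microstate_gen_spec")
}

#' Apply an effect configuration to a microstate generator
#'
#' Realizes `microstateB_occurrence_gain`: the transition probability into
#' class B (row-wise) is multiplied by the gain and rows are renormalized, so
#' B segments occur more often while dwell-time distributions are unchanged.
#'
#' @param gen a [microstate_gen_spec()].
#' @param effect an [effect_config()].
#' @return Modified `microstate_gen_spec`.
#' @export
apply_microstate_effect <- function(gen, effect) {
  g <- effect$microstateB_occurrence_gain
  if (g == 1) return(gen)
  b <- match("B", rownames(gen$maps))
  if (is.na(b)) stop_invalid("generator maps carry no class B")
  tm <- gen$transition_matrix
  tm[, b] <- tm[, b] * g
  tm <- tm / rowSums(tm)
  gen$transition_matrix <- tm
  gen
}

#' Generate a microstate-structured EEG recording
#'
#' Draws a semi-Markov class sequence (gamma dwell times, Markov jumps at run
#' boundaries), renders it as template map x oscillatory envelope plus white
#' sensor noise, and returns the recording together with the true per-sample
#' labels.
#'
#' @param gen a [microstate_gen_spec()].
#' @param duration recording length in seconds (>= 1).
#' @param fs sampling rate in Hz.
#' @param seed RNG seed.
#' @param effect optional [effect_config()] applied via
#'   [apply_microstate_effect()].
#' @return List with `recording` (an [eeg_recording()]) and `labels`
#'   (class `label_sequence`: integer per-sample class, 1-based, plus `fs`
#'   and class `names`).
#' @export
generate_microstate_recording <- function(gen = microstate_gen_spec(),
                                          duration = 120, fs = 250, seed = 1,
                                          effect = NULL) {
  if (duration < 1) stop_invalid("duration must be >= 1 s")
  if (!is.null(effect)) gen <- apply_microstate_effect(gen, effect)
  n <- round(duration * fs)
  k <- gen$k
  labels <- integer(n)
  with_seed(seed, {
    state <- sample.int(k, 1)
    pos <- 1L
    while (pos <= n) {
      dwell_ms <- stats::rgamma(1, shape = gen$dwell_shape,
                                scale = gen$mean_dwell[state] / gen$dwell_shape)
      len <- max(1L, round(dwell_ms / 1000 * fs))
      labels[pos:min(n, pos + len - 1L)] <- state
      pos <- pos + len
      state <- sample.int(k, 1, prob = gen$transition_matrix[state, ])
    }
    tt <- (seq_len(n) - 1) / fs
    envelope <- gen$gfp_envelope_scale *
      (0.4 + 0.6 * abs(sin(2 * pi * 10.3 * tt + stats::runif(1, 0, 2 * pi)))) *
      sign(sin(2 * pi * 10.3 * tt))
    envelope[envelope == 0] <- gen$gfp_envelope_scale * 0.4
    # unit-norm zero-mean maps are scaled so the clean-signal GFP equals the
    # envelope (GFP of a*m is a/sqrt(C-1) for such maps)
    C <- ncol(gen$maps)
    data <- sweep(t(gen$maps[labels, , drop = FALSE]), 2,
                  envelope * sqrt(C - 1), `*`)
    if (gen$sensor_noise_sd > 0) {
      data <- data + matrix(stats::rnorm(length(data), sd = gen$sensor_noise_sd),
                            nrow(data), ncol(data))
    }
  })
  rownames(data) <- gen$channel_names
  list(recording = eeg_recording(data, fs, gen$channel_names),
       labels = structure(list(labels = labels, fs = fs,
                               k = k, names = rownames(gen$maps)),
                          class = "label_sequence"))
}
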