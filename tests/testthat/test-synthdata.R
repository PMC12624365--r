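test_that("rTMS schedule arithmetic and invariants hold across protocols", {
  s <- generate_rtms_schedule(24, 10, 5, 5)
  expect_equal(s$n_pulses, 1200)
  expect_equal(s$duration, 360)
  expect_equal(s$pulse_times[1], 0)

  expect_equal(generate_rtms_schedule(1, 1, 1, 0)$n_pulses, 1)
  expect_equal(generate_rtms_schedule(1, 1, 1, 0)$duration, 1)

  # brute-force enumeration oracle for a two-train protocol
  s2 <- generate_rtms_schedule(2, 10, 5, 5)
  manual <- c(seq(0, 9.8, by = 0.2), 15 + seq(0, 9.8, by = 0.2))
  expect_equal(s2$pulse_times, manual)
  expect_equal(s2$n_pulses, 100)
  expect_equal(s2$duration, 30)

  # property: count/duration identities and within-train spacing
  set.seed(42)
  for (i in 1:20) {
    nt <- sample(1:30, 1); td <- sample(1:12, 1); pr <- sample(1:20, 1)
    iti <- runif(1, 0, 10)
    p <- generate_rtms_schedule(nt, td, pr, iti)
    expect_equal(p$n_pulses, nt * td * pr)
    expect_equal(p$duration, nt * (td + iti))
    expect_true(all(diff(p$pulse_times) > 0))
    within <- p$pulse_times[seq_len(td * pr)]
    expect_equal(diff(within), rep(1 / pr, td * pr - 1))
  }
  expect_error(generate_rtms_schedule(0, 10, 5, 5), "positive")
  expect_error(generate_rtms_schedule(24, 10, -5, 5), "positive")
})

test_that("noiseless trials are pure harmonic series with no off-harmonic power", {
  m <- quiet_model()
  tr <- generate_ssvep_trial(20, m, effect_config(), 4, 250, seed = 1)
  sp <- compute_spectrum(tr$data["Oz", , drop = FALSE], fs = 250, channels = NULL)
  on_h <- sp$freqs %in% c(20, 40)
  expect_gt(sum(sp$power[on_h]), 0)
  expect_lt(max(sp$power[!on_h]), 1e-20)
  expect_error(generate_ssvep_trial(130, m, effect_config(), 4, 250, 1), "Nyquist")
  expect_error(
    generate_ssvep_trial(80, signal_model(n_harmonics = 2), effect_config(),
                         4, 250, 1),
    "harmonic")
})

test_that("trial power at the fundamental matches the analytic sinusoid value", {
  # closed form: amplitude a1 sinusoid carries a1^2/2 in its bin; per-bin
  # noise leakage averages out over seeds
  m <- signal_model()
  pow <- vapply(1:20, function(s) {
    tr <- generate_ssvep_trial(20, m, effect_config(), 4, 250, seed = s)
    sp <- compute_spectrum(tr$data["Oz", , drop = FALSE], fs = 250,
                           channels = NULL)
    sp$power[which.min(abs(sp$freqs - 20))]
  }, numeric(1))
  expect_lt(abs(mean(pow) - m$fundamental_amp^2 / 2) /
              (m$fundamental_amp^2 / 2), 0.05)
})

test_that("background gain halves task-unrelated power but not task power", {
  m <- signal_model()
  ratios <- vapply(1:10, function(s) {
    t1 <- generate_ssvep_trial(20, m, effect_config(), 4, 250, seed = s)
    t5 <- generate_ssvep_trial(
      20, m, effect_config("real", "Post0", background_gain = 0.5),
      4, 250, seed = s)
    c1 <- task_component_powers(compute_spectrum(t1), 20)
    c5 <- task_component_powers(compute_spectrum(t5), 20)
    c(unrel = c5$task_unrelated / c1$task_unrelated,
      rel = c5$task_related / c1$task_related)
  }, numeric(2))
  expect_lt(abs(mean(ratios["unrel", ]) - 0.5), 0.05)
  # single-bin task power carries a signal-background cross term; the
  # invariance of the stimulus-locked component itself is exact (next block)
  expect_lt(abs(mean(ratios["rel", ]) - 1), 0.03)

  # exact invariance: the paired difference of same-seed trials is purely
  # rescaled occipital background; the stimulus-locked part cancels
  t1 <- generate_ssvep_trial(20, m, effect_config(), 4, 250, seed = 3)
  t5 <- generate_ssvep_trial(
    20, m, effect_config("real", "Post0", background_gain = 0.5),
    4, 250, seed = 3)
  noise_only <- generate_ssvep_trial(
    20, signal_model(fundamental_amp = 0, alpha_amp = 0), effect_config(),
    4, 250, seed = 3)
  d <- t5$data - t1$data
  occ <- rownames(d) %in% occipital_montage()
  expect_equal(d[occ, ], (sqrt(0.5) - 1) * noise_only$data[occ, ],
               tolerance = 1e-12)
  expect_true(all(d[!occ, ] == 0))
})

test_that("sessions enumerate the full design with uniform label marginals", {
  ses <- generate_session(session_spec(), signal_model(noise_scale = 0.5),
                          effect_config(), seed = 11)
  expect_equal(dim(ses$data)[3], 80)   # 4 blocks x 4 bands x 5 targets
  counts <- table(ses$info$band, ses$info$f_target)
  expect_true(all(counts[counts > 0] == 4))
  for (b in unique(ses$info$band)) {
    expect_equal(length(unique(ses$info$f_target[ses$info$band == b])), 5)
  }

  one <- generate_session(
    session_spec(bands = list(MF = c(18, 22)), targets_per_band = 2,
                 n_blocks = 1),
    quiet_model(), effect_config(), seed = 1)
  expect_equal(dim(one$data)[3], 2)
})

test_that("generators are seed-reproducible and seeds decorrelate noise", {
  sp <- mf_spec(n_blocks = 1)
  a <- generate_session(sp, signal_model(), effect_config(), seed = 5)
  b <- generate_session(sp, signal_model(), effect_config(), seed = 5)
  expect_identical(a$data, b$data)
  expect_identical(a$info, b$info)

  # 1/f noise is long-range correlated, so decorrelation is assessed after
  # the pipeline's own 1-90 Hz bandpass (as any analysis sees the data);
  # below 1 Hz the correlation estimator has almost no degrees of freedom
  m <- signal_model(alpha_amp = 0)
  r1 <- preprocess_recording(
    generate_resting_recording(m, effect_config(), 60, 250, seed = 1))
  r2 <- preprocess_recording(
    generate_resting_recording(m, effect_config(), 60, 250, seed = 2))
  cors <- vapply(seq_len(nrow(r1$data)), function(i) {
    cor(r1$data[i, ], r2$data[i, ])
  }, numeric(1))
  expect_lt(mean(abs(cors)), 0.05)
})

test_that("resting recordings carry alpha power scaled by the alpha gain", {
  m <- signal_model()
  r1 <- generate_resting_recording(m, effect_config(), 120, 250, seed = 3)
  r2 <- generate_resting_recording(
    m, effect_config("real", "Post0", alpha_gain = 2), 120, 250, seed = 3)
  expect_equal(ncol(r1$data), 30000)
  # isolate the rhythm from the 1/f floor: narrow band around the alpha
  # peak minus a matched-width control band
  a1 <- mean(band_power(r1, 9.5, 10.5, channels = occipital_montage())) -
    mean(band_power(r1, 14.5, 15.5, channels = occipital_montage()))
  a2 <- mean(band_power(r2, 9.5, 10.5, channels = occipital_montage())) -
    mean(band_power(r2, 14.5, 15.5, channels = occipital_montage()))
  expect_lt(abs(a2 / a1 - 2), 0.2)
  r0 <- generate_resting_recording(quiet_model(), effect_config(), 2, 250, 1)
  expect_true(all(r0$data == 0))
})

test_that("microstate generator produces exact maps when noiseless and honest dwell stats", {
  gs <- microstate_gen_spec(sensor_noise_sd = 0)
  out <- generate_microstate_recording(gs, duration = 5, seed = 2)
  V <- average_ref_for_test(out$recording$data)
  for (t in sample(ncol(V), 25)) {
    r <- abs(cor(V[, t], gs$maps[out$labels$labels[t], ]))
    expect_gt(r, 1 - 1e-9)
  }

  out2 <- generate_microstate_recording(microstate_gen_spec(mean_dwell = 80),
                                        duration = 120, seed = 7)
  runs <- rle(out2$labels$labels)$lengths
  interior <- runs[-c(1, length(runs))]
  expect_lt(abs(mean(interior) / 250 * 1000 - 80) / 80, 0.10)

  tm <- matrix(0, 4, 4)
  tm[1, 2] <- 1; tm[2, 1] <- 1; tm[3, 4] <- 1; tm[4, 3] <- 1
  gs3 <- microstate_gen_spec(transition_matrix = tm)
  out3 <- generate_microstate_recording(gs3, duration = 5, seed = 1)
  v <- rle(out3$labels$labels)$values
  expect_true(all(v %in% c(1, 2)) || all(v %in% c(3, 4)))
  expect_true(all(diff(v) != 0))

  bad <- matrix(0.5, 4, 4)
  expect_error(microstate_gen_spec(transition_matrix = bad), "diagonal")
})

test_that("effect configuration enforces the sham/Pre unit-gain contract", {
  expect_error(effect_config("sham", "Post0", background_gain = 0.5), "unit")
  expect_error(effect_config("real", "Pre", alpha_gain = 2), "unit")
  expect_error(effect_config("real", "Post0", background_gain = -1), "finite")
  e <- effect_config("real", "Post0", background_gain = 0.5)
  expect_equal(e$background_gain, 0.5)
})
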