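test_that("periodograms resolve sinusoids with Parseval-consistent scaling", {
  fs <- 250
  t <- (0:999) / fs
  x <- sin(2 * pi * 20 * t)
  sp <- compute_spectrum(matrix(x, 1), fs = fs, channels = NULL)
  expect_equal(sp$freqs[which.max(sp$power)], 20)
  expect_equal(sp$resolution, 0.25)

  y <- sin(2 * pi * 20 * t) + 0.5 * sin(2 * pi * 31 * t)
  spy <- compute_spectrum(matrix(y, 1), fs = fs, channels = NULL)
  p20 <- spy$power[which.min(abs(spy$freqs - 20))]
  p31 <- spy$power[which.min(abs(spy$freqs - 31))]
  expect_equal(p20 / p31, 4, tolerance = 0.01)   # squared amplitude ratio

  set.seed(5)
  z <- rnorm(1000)
  spz <- compute_spectrum(matrix(z, 1), fs = fs, channels = NULL)
  expect_equal(sum(spz$power), mean(z^2), tolerance = 0.005)

  expect_error(compute_spectrum(matrix(z, 1), fs = fs, channels = "Oz"),
               "empty channel")
})

test_that("task component powers agree with a brute-force bin oracle", {
  freqs <- seq(0, 125, by = 0.25)
  set.seed(2)
  p <- rexp(length(freqs))
  sp <- structure(list(freqs = freqs, power = p, fs = 250, resolution = 0.25),
                  class = "eeg_spectrum")
  tc <- task_component_powers(sp, 20)
  i <- which(freqs == 20)
  nb <- which(freqs >= 19 & freqs <= 21)
  nb <- setdiff(nb, i)
  expect_identical(tc$task_related, p[i])
  expect_identical(tc$task_unrelated, mean(p[nb]))
  expect_equal(tc$snr_db, 10 * log10(p[i] / mean(p[nb])))

  flat <- sp; flat$power <- rep(3, length(freqs))
  expect_equal(task_component_powers(flat, 20)$snr_db, 0)
  boosted <- flat; boosted$power[which(freqs == 20)] <- 300
  expect_equal(task_component_powers(boosted, 20)$snr_db, 20)
  expect_error(task_component_powers(sp, 125), "outside")
})

test_that("wide SNR sums harmonics, matches narrow SNR at Nh = 1, flat is 0 dB", {
  freqs <- seq(0, 125, by = 0.25)
  flat <- structure(list(freqs = freqs, power = rep(2, length(freqs)),
                         fs = 250, resolution = 0.25),
                    class = "eeg_spectrum")
  expect_equal(wide_snr(flat, 20, 3), 0)

  set.seed(3)
  noisy <- flat; noisy$power <- rexp(length(freqs))
  expect_equal(wide_snr(noisy, 20, 1),
               task_component_powers(noisy, 20)$snr_db, tolerance = 1e-12)

  series <- flat
  series$power[freqs %in% c(20, 40, 60)] <- c(200, 100, 50)
  # brute-force oracle
  hb <- which(freqs %in% c(20, 40, 60))
  bg <- vapply(c(20, 40, 60), function(fh) {
    nb <- setdiff(which(freqs >= fh - 1 & freqs <= fh + 1), hb)
    mean(series$power[nb])
  }, numeric(1))
  expect_equal(wide_snr(series, 20, 3),
               10 * log10(sum(series$power[hb]) / sum(bg)))
  expect_gt(wide_snr(series, 20, 3), 0)
})

test_that("band power integrates the right bins and scales quadratically", {
  fs <- 250
  t <- (0:(20 * fs - 1)) / fs
  x <- matrix(sin(2 * pi * 10 * t), 1)
  rownames(x) <- "Oz"
  bp_a <- band_power(x, 8, 12, fs = fs)
  bp_b <- band_power(x, 18, 22, fs = fs)
  expect_gt(bp_a, 100 * max(bp_b, 1e-12))
  expect_equal(unname(band_power(2 * x, 8, 12, fs = fs) / bp_a), 4,
               tolerance = 0.01)

  sp <- compute_spectrum(x, fs = fs, channels = NULL)
  expect_equal(unname(band_power(sp, 8, 12)), 0.5, tolerance = 0.01)
  expect_error(band_power(sp, 12, 8), "lo must be")
})

test_that("similarity scores isolate fundamental versus second harmonic", {
  tr <- generate_ssvep_trial(20, quiet_model(n_harmonics = 1),
                             effect_config(), 4, 250, 1)
  expect_gt(similarity_score(tr, 20, "fundamental"), 0.999)

  m2 <- quiet_model(n_harmonics = 2, harmonic_decay = 1)
  tr2 <- generate_ssvep_trial(20, m2, effect_config(), 4, 250, 1)
  # remove fundamental content by construction: pure 40 Hz trial
  pure2 <- generate_ssvep_trial(40, quiet_model(n_harmonics = 1),
                                effect_config(), 4, 250, 1)
  expect_gt(similarity_score(pure2, 20, "second_harmonic"), 0.999)
  noise <- generate_ssvep_trial(20, signal_model(fundamental_amp = 0),
                                effect_config(), 4, 250, 1)
  expect_lt(similarity_score(noise, 20, "fundamental"), 0.5)
  expect_error(similarity_score(tr, 70, "second_harmonic"), "Nyquist")

  rho <- vapply(c(0.5, 1.5, 3), function(a1) {
    t1 <- generate_ssvep_trial(20, signal_model(fundamental_amp = a1),
                               effect_config(), 4, 250, 9)
    similarity_score(t1, 20, "fundamental")
  }, numeric(1))
  expect_true(all(diff(rho) > 0))
})

test_that("narrow-band SNR is invariant to global channel scaling", {
  tr <- generate_ssvep_trial(20, signal_model(), effect_config(), 4, 250, 4)
  s1 <- task_component_powers(compute_spectrum(tr), 20)$snr_db
  s2 <- task_component_powers(
    compute_spectrum(list(data = tr$data * 7, fs = 250)), 20)$snr_db
  expect_equal(s1, s2, tolerance = 1e-9)
})
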