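test_that("sub-band weights follow n^(-a) + b and decrease monotonically", {
  expect_equal(subband_weight(1), 1.25)
  expect_equal(subband_weight(2), 2^(-1.25) + 0.25)   # 0.67045 (5 s.f.)
  w <- subband_weight(1:7)
  expect_true(all(diff(w) < 0))
  expect_error(subband_weight(0), ">= 1")
})

test_that("the first canonical correlation matches stats::cancor", {
  set.seed(8)
  X <- matrix(rnorm(200 * 4), 200)
  Y <- matrix(rnorm(200 * 3), 200)
  Y[, 1] <- X[, 1] + 0.5 * rnorm(200)
  expect_equal(cca_max_cor(X, Y), cancor(X, Y)$cor[1], tolerance = 1e-10)
  # rank-deficient input must not error
  Xd <- cbind(X, X[, 1])
  expect_equal(cca_max_cor(Xd, Y), cancor(X, Y)$cor[1], tolerance = 1e-8)
})

test_that("FBCCA identifies targets, is scale invariant, and breaks ties low", {
  fc <- fbcca_config(18)
  tr0 <- generate_ssvep_trial(20, quiet_model(), effect_config(), 4, 250, 1)
  expect_equal(fbcca_classify(tr0, 18:22, fc)$predicted, 20)

  tr <- generate_ssvep_trial(19, signal_model(), effect_config(), 4, 250, 7)
  r1 <- fbcca_classify(tr, 18:22, fc)
  expect_equal(r1$predicted, 19)
  r10 <- fbcca_classify(list(data = tr$data * 10, fs = 250), 18:22, fc)
  expect_equal(r10$features, r1$features, tolerance = 1e-8)
  expect_equal(r10$predicted, r1$predicted)

  # feature bound and candidate-order equivariance
  wsum <- sum(subband_weight(seq_len(fc$N)))
  expect_true(all(r1$features >= 0 & r1$features <= wsum))
  rev_r <- fbcca_classify(tr, 22:18, fc)
  expect_equal(unname(rev_r$features), unname(rev(r1$features)))

  # zero trial: all features equal, tie broken toward lowest frequency
  zero <- matrix(0, 9, 500)
  rownames(zero) <- occipital_montage()
  rz <- fbcca_classify(list(data = zero, fs = 250), c(20, 18, 19), fc)
  expect_equal(rz$predicted, 18)
})

test_that("FBCCA seeded-session predictions match planted labels and accuracy rises with amplitude", {
  sp <- mf_spec(n_blocks = 1)
  fc <- fbcca_config(18)
  ses <- generate_session(sp, signal_model(), effect_config(), seed = 7)
  preds <- vapply(seq_len(dim(ses$data)[3]), function(i) {
    fbcca_classify(list(data = ses$data[, , i], fs = ses$fs),
                   band_targets(sp, "MF"), fc)$predicted
  }, numeric(1))
  expect_gte(mean(preds == ses$info$f_target), 0.8)

  acc <- vapply(c(0.4, 1.0, 2.5), function(a1) {
    s <- generate_session(sp, signal_model(fundamental_amp = a1),
                          effect_config(), seed = 21)
    cv <- accuracy_curve(fbcca_decoder(band_targets(sp, "MF"), fc, 250), s,
                         durations = 1)
    cv$accuracy
  }, numeric(1))
  # non-decreasing within one-trial resolution (5 trials -> 20% steps)
  expect_true(all(diff(acc) >= -20 + 1e-9))
  expect_gt(acc[3], acc[1])
})

test_that("harmonic references drop aliased harmonics with a warning", {
  expect_warning(h <- harmonic_reference(40, 250, 250, 5), "Nyquist")
  expect_equal(ncol(h), 6)   # 3 harmonics kept, sin+cos each
  expect_silent(harmonic_reference(20, 250, 250, 5))
})

test_that("TDCA separates noiseless classes perfectly and is order invariant", {
  sp <- session_spec(bands = list(MF = c(18, 22)), n_blocks = 2)
  ses <- generate_session(sp, quiet_model(), effect_config(), seed = 1)
  # noiseless duplicate trials make the within-class scatter singular;
  # the fit must warn and ridge-regularize rather than fail
  expect_warning(model <- tdca_fit(ses), "ridge")
  for (i in seq_len(dim(ses$data)[3])) {
    expect_equal(tdca_classify(model, ses$data[, , i])$predicted,
                 ses$info$f_target[i])
  }
  perm <- rev(seq_len(dim(ses$data)[3]))
  model2 <- suppressWarnings(tdca_fit(subset_trials(ses, perm)))
  expect_equal(abs(model2$W), abs(model$W), tolerance = 1e-6)

  tr <- ses$data[, , 3]
  expect_equal(tdca_classify(model, tr * 10)$predicted,
               tdca_classify(model, tr)$predicted)
  expect_error(tdca_classify(model, tr[, 1:100]), "samples")
})

test_that("TDCA leave-one-block-out beats chance and tracks FBCCA", {
  sp <- mf_spec(n_blocks = 4)
  ses <- generate_session(sp, signal_model(), effect_config(), seed = 13)
  acc_tdca <- tdca_lobo_accuracy(ses, duration = 1)
  expect_gt(acc_tdca, 0.2)
  fc <- fbcca_config(18)
  cv <- accuracy_curve(fbcca_decoder(band_targets(sp, "MF"), fc, 250), ses,
                       durations = 1)
  expect_gte(100 * acc_tdca, cv$accuracy - 10)
})
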