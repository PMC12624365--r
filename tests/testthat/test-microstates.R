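test_that("modified k-means recovers planted maps exactly when noiseless", {
  gs <- microstate_gen_spec(sensor_noise_sd = 0)
  out <- generate_microstate_recording(gs, duration = 10, seed = 5)
  mdl <- fit_microstates(out$recording, n_restarts = 5, seed = 1)
  for (i in 1:4) {
    expect_gt(spatial_correlation(mdl$maps[i, ], gs$maps[i, ]), 1 - 1e-6)
  }
  expect_gt(mdl$gev, 1 - 1e-9)
  expect_equal(rownames(mdl$maps), c("A", "B", "C", "D"))

  # duplicating the input does not change the fitted model
  mdl2 <- fit_microstates(list(out$recording, out$recording),
                          n_restarts = 5, seed = 1)
  expect_equal(abs(mdl2$maps), abs(mdl$maps), tolerance = 1e-9)
  expect_error(fit_microstates(out$recording, k = 1), ">= 2")
})

test_that("maps are recovered under 20% sensor noise on two minutes of data", {
  out <- generate_microstate_recording(microstate_gen_spec(),
                                       duration = 120, seed = 6)
  mdl <- fit_microstates(out$recording, n_restarts = 10, seed = 2)
  for (i in 1:4) {
    expect_gt(spatial_correlation(mdl$maps[i, ], microstate_gen_spec()$maps[i, ]),
              0.95)
  }
  bl <- backfit_labels(mdl, out$recording)
  expect_gt(mean(bl$labels == out$labels$labels), 0.9)
})

test_that("backfitting is polarity invariant", {
  gs <- microstate_gen_spec(sensor_noise_sd = 0)
  mdl <- structure(list(maps = gs$maps, gev = 1, k = 4,
                        channel_names = gs$channel_names),
                   class = "microstate_model")
  v <- gs$maps[2, ] * 5
  rec <- eeg_recording(cbind(v, -v), 250, gs$channel_names)
  bl <- backfit_labels(mdl, rec)
  expect_equal(bl$labels, c(2L, 2L))
  expect_error(backfit_labels(mdl, eeg_recording(matrix(rnorm(10), 5), 250,
                                                 paste0("c", 1:5))),
               "mismatch")
})

test_that("dynamics metrics match hand-computable label sequences", {
  ls <- structure(list(labels = rep(1L, 500), fs = 250, k = 4,
                       names = c("A", "B", "C", "D")),
                  class = "label_sequence")
  met <- microstate_metrics(ls)
  a <- met$per_class[met$per_class$class == "A", ]
  expect_equal(a$mean_duration_ms, 2000)
  expect_equal(a$occurrence_per_s, 0.5)
  expect_equal(a$contribution, 1)
  expect_equal(sum(met$per_class$contribution), 1)
  expect_equal(met$per_class$occurrence_per_s[2:4], rep(0, 3))

  alt <- structure(list(labels = rep(c(1L, 2L), 250), fs = 250, k = 4,
                        names = c("A", "B", "C", "D")),
                   class = "label_sequence")
  ma <- microstate_metrics(alt)
  expect_equal(ma$per_class$mean_duration_ms[1:2], c(4, 4))
  tm <- transition_matrix(alt)
  expect_equal(tm["A", "B"], 1)
  expect_equal(tm["B", "A"], 1)
  expect_true(all(is.na(tm["C", ])))
})

test_that("metrics recover generator dwell and transition ground truth", {
  out <- generate_microstate_recording(microstate_gen_spec(mean_dwell = 80),
                                       duration = 120, seed = 9)
  met <- microstate_metrics(out$labels)
  expect_lt(max(abs(met$per_class$mean_duration_ms - 80) / 80), 0.10)
  # occurrence x duration identity (edge effects only)
  with(met$per_class, expect_lt(
    max(abs(occurrence_per_s * mean_duration_ms - contribution * 1000) /
          (contribution * 1000)), 0.05))

  tmat <- matrix(c(0, .5, .3, .2,
                   .4, 0, .4, .2,
                   .25, .25, 0, .5,
                   .2, .6, .2, 0), 4, 4, byrow = TRUE)
  out2 <- generate_microstate_recording(
    microstate_gen_spec(transition_matrix = tmat), duration = 600, seed = 10)
  est <- transition_matrix(out2$labels)
  expect_lt(max(abs(est - tmat)), 0.05)

  rows <- rowSums(est, na.rm = TRUE)
  expect_equal(unname(rows), rep(1, 4), tolerance = 1e-9)
})

test_that("GEV matches a brute-force sample-wise oracle", {
  out <- generate_microstate_recording(duration = 2, seed = 3)
  rec <- out$recording
  rec$data <- rec$data[, 1:100]
  mdl <- fit_microstates(out$recording, n_restarts = 3, seed = 4)
  g <- gev(mdl, rec)
  # direct-sum oracle over samples
  V <- average_ref_for_test(rec$data)
  gfp <- apply(V, 2, sd)
  num <- 0
  for (t in seq_len(ncol(V))) {
    r2 <- max(vapply(1:4, function(k2) cor(V[, t], mdl$maps[k2, ])^2,
                     numeric(1)))
    num <- num + gfp[t]^2 * r2
  }
  expect_equal(unname(g), unname(num / sum(gfp^2)), tolerance = 1e-12)
  expect_true(g >= 0 && g <= 1)
})

test_that("spatial correlation is polarity invariant and rejects flat maps", {
  set.seed(1)
  m <- rnorm(64)
  expect_equal(spatial_correlation(m, m), 1)
  expect_equal(spatial_correlation(m, -m), 1)
  o <- residuals(lm(rnorm(64) ~ m))
  expect_lt(spatial_correlation(m, o), 1e-10)
  expect_error(spatial_correlation(m, rep(1, 64)), "zero-variance")
})

test_that("raising the generator's B occurrence raises estimated B metrics", {
  diffs <- vapply(1:8, function(s) {
    base <- generate_microstate_recording(duration = 45, seed = s)
    up <- generate_microstate_recording(
      duration = 45, seed = s,
      effect = effect_config("real", "Post0",
                             microstateB_occurrence_gain = 2))
    mb <- function(out) {
      mdl <- fit_microstates(out$recording, n_restarts = 10, seed = 100 + s)
      pc <- microstate_metrics(backfit_labels(mdl, out$recording))$per_class
      c(pc$occurrence_per_s[pc$class == "B"],
        pc$contribution[pc$class == "B"])
    }
    mb(up) - mb(base)
  }, numeric(2))
  # one-sided sign test on paired seeded runs
  expect_lt(binom.test(sum(diffs[1, ] > 0), 8, alternative = "greater")$p.value,
            0.05)
  expect_lt(binom.test(sum(diffs[2, ] > 0), 8, alternative = "greater")$p.value,
            0.05)
})
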