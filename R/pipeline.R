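#' Study configuration for the end-to-end pipeline
#'
#' Describes one simulated sham-controlled within-subject study: number of
#' subjects, stimulus layout, generative signal model, the per-condition and
#' per-timepoint ground-truth effect grid, decoder settings, and output
#' location. The effect grid always covers \{real, sham\} x \{Pre, Post0,
#' Post20\}; sham and Pre cells carry unit gains by construction.
#'
#' @param n_subjects simulated subjects.
#' @param seed master seed; all per-subject and per-stage seeds derive from it.
#' @param bands band names analyzed (subset of the session spec bands).
#' @param durations decoding durations in seconds.
#' @param decoders `"fbcca"` and/or `"tdca"`.
#' @param spec a [session_spec()] (bands are restricted to `bands`).
#' @param model a [signal_model()]; per-subject log-normal multipliers are
#'   applied to its signal and noise scales.
#' @param effects named list with `real_Post0` and `real_Post20` entries, each
#'   a list of `background_gain`, `alpha_gain`, `microstateB_occurrence_gain`.
#' @param subject_sdlog SD of the log-normal between-subject multipliers.
#' @param pt_mean,pt_sd phosphene-threshold covariate distribution (% output).
#' @param pt_slope linear scaling of effect strength by (centered, negated)
#'   phosphene threshold: lower threshold, stronger effect.
#' @param microstate_duration,resting_duration seconds of task-state
#'   microstate EEG and resting EEG per cell.
#' @param ms_restarts microstate fitting restarts.
#' @param n_perm permutations of the cluster test stage.
#' @param out_dir output directory for the TSV/JSON report.
#' @return Object of class `study_config`.
#' @export
study_config <- function(n_subjects = 12, seed = 1,
                         bands = c("MF", "HF"),
                         durations = seq(0.5, 4, by = 0.5),
                         decoders = "fbcca",
                         spec = session_spec(),
                         model = signal_model(),
                         effects = list(
                           real_Post0 = list(background_gain = 0.6,
                                             alpha_gain = 1.4,
                                             microstateB_occurrence_gain = 1.4),
                           real_Post20 = list(background_gain = 0.8,
                                              alpha_gain = 1.2,
                                              microstateB_occurrence_gain = 1.2)),
                         subject_sdlog = 0.2,
                         pt_mean = 60, pt_sd = 8, pt_slope = 1,
                         microstate_duration = 60, resting_duration = 60,
                         ms_restarts = 10, n_perm = 1000,
                         out_dir = tempfile("ssvep_run_")) {
  stopifnot(all(bands %in% names(spec$bands)))
  spec$bands <- spec$bands[bands]
  structure(list(n_subjects = n_subjects, seed = seed, bands = bands,
                 durations = durations, decoders = decoders, spec = spec,
                 model = model, effects = effects,
                 subject_sdlog = subject_sdlog, pt_mean = pt_mean,
                 pt_sd = pt_sd, pt_slope = pt_slope,
                 microstate_duration = microstate_duration,
                 resting_duration = resting_duration,
                 ms_restarts = ms_restarts, n_perm = n_perm,
                 out_dir = out_dir),
            class = "study_config")
}

# Effect config for one cell of the grid, scaled by the subject's phosphene
# threshold: s = 1 + pt_slope * (pt_mean - pt) / pt_mean, clamped >= 0.
subject_effect <- function(cfg, condition, timepoint, pt) {
  if (condition == "sham" || timepoint == "Pre") {
    return(effect_config(condition, timepoint, subject_pt = pt))
  }
  base <- cfg$effects[[paste0("real_", timepoint)]]
  s <- max(0, 1 + cfg$pt_slope * (cfg$pt_mean - pt) / cfg$pt_mean)
  scale_gain <- function(g) max(0.05, 1 + (g - 1) * s)
  effect_config(condition, timepoint,
                background_gain = scale_gain(base$background_gain),
                alpha_gain = scale_gain(base$alpha_gain),
                microstateB_occurrence_gain =
                  scale_gain(base$microstateB_occurrence_gain),
                subject_pt = pt)
}

# Subject-level draws: phosphene threshold and log-normal amplitude factors.
subject_profiles <- function(cfg) {
  with_seed(derive_seed(cfg$seed, "subjects"), {
    data.frame(
      subject = seq_len(cfg$n_subjects),
      pt = stats::rnorm(cfg$n_subjects, cfg$pt_mean, cfg$pt_sd),
      amp_mult = stats::rlnorm(cfg$n_subjects, 0, cfg$subject_sdlog),
      noise_mult = stats::rlnorm(cfg$n_subjects, 0, cfg$subject_sdlog))
  })
}

write_tsv <- function(df, path) {
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

grid_cells <- function() {
  expand.grid(condition = c("real", "sham"),
              timepoint = c("Pre", "Post0", "Post20"),
              stringsAsFactors = FALSE)
}

#' Run the full simulated-study pipeline
#'
#' Executes, for every subject x condition x timepoint cell: synthetic SSVEP
#' session generation, FBCCA (and optionally leave-one-block-out TDCA)
#' decoding with accuracy-versus-duration curves reduced to CDE, per-trial
#' spectral SNR / task-component / similarity features, task-state microstate
#' generation + segmentation + dynamics metrics, and resting-state band
#' power; then the inferential stage: paired one-sided tests of real-versus-
#' sham CDE change, a channel-space cluster permutation test of resting power
#' (real Pre vs Post0), and the correlation analyses (phosphene threshold vs
#' microstate-B change; resting alpha power change vs SNR change).
#'
#' All randomness derives from `cfg$seed`, so reruns with an identical
#' configuration are byte-identical. Stage outputs are TSV files whose names
#' carry a hash of the stage configuration; an existing stage file is reused
#' instead of recomputed.
#'
#' @param cfg a [study_config()].
#' @return The output directory, invisibly; the directory contains
#'   `cde.tsv`, `spectral.tsv`, `microstates.tsv`, `resting_power.tsv`,
#'   `stats_cde.tsv`, `clusters.json`, `correlations.tsv` and `report.json`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- subject_profiles(cfg)
  cells <- grid_cells()
  h <- config_hash(cfg[setdiff(names(cfg), "out_dir")])

  stage_path <- function(name, ext = "tsv") {
    file.path(cfg$out_dir, sprintf("%s-%s.%s", name, h, ext))
  }
  link_plain <- function(from, plain) {
    file.copy(from, file.path(cfg$out_dir, plain), overwrite = TRUE)
  }

  ## ---- stage 1+2: sessions -> decoding + spectral features --------------
  p_cde <- stage_path("cde")
  p_spec <- stage_path("spectral")
  if (!file.exists(p_cde) || !file.exists(p_spec)) {
    cde_rows <- list()
    spec_rows <- list()
    for (si in seq_len(nrow(subjects))) {
      model_s <- cfg$model
      model_s$fundamental_amp <- model_s$fundamental_amp * subjects$amp_mult[si]
      model_s$noise_scale <- model_s$noise_scale * subjects$noise_mult[si]
      for (ci in seq_len(nrow(cells))) {
        cond <- cells$condition[ci]
        tp <- cells$timepoint[ci]
        eff <- subject_effect(cfg, cond, tp, subjects$pt[si])
        ses <- generate_session(cfg$spec, model_s, eff,
                                seed = derive_seed(cfg$seed, "ses", si, cond, tp))
        for (bnd in cfg$bands) {
          idx <- which(ses$info$band == bnd)
          sub <- list(data = ses$data[, , idx, drop = FALSE],
                      info = ses$info[idx, , drop = FALSE],
                      fs = ses$fs, channel_names = ses$channel_names)
          class(sub) <- "trial_set"
          cands <- band_targets(cfg$spec, bnd)
          if ("fbcca" %in% cfg$decoders) {
            fc <- fbcca_config(cfg$spec$bands[[bnd]][1])
            curve <- accuracy_curve(fbcca_decoder(cands, fc, ses$fs), sub,
                                    cfg$durations)
            cde_rows[[length(cde_rows) + 1L]] <- data.frame(
              subject = si, condition = cond, timepoint = tp, band = bnd,
              decoder = "fbcca", cde = compute_cde(curve))
          }
          if ("tdca" %in% cfg$decoders) {
            acc <- vapply(cfg$durations, function(d) {
              100 * tdca_lobo_accuracy(sub, duration = d)
            }, numeric(1))
            cde_rows[[length(cde_rows) + 1L]] <- data.frame(
              subject = si, condition = cond, timepoint = tp, band = bnd,
              decoder = "tdca", cde = compute_cde(acc))
          }
          for (i in idx) {
            tr <- list(data = ses$data[, , i], fs = ses$fs)
            f <- ses$info$f_target[i]
            sp <- compute_spectrum(tr)
            tc <- task_component_powers(sp, f)
            spec_rows[[length(spec_rows) + 1L]] <- data.frame(
              subject = si, condition = cond, timepoint = tp, band = bnd,
              f_target = f, block = ses$info$block[i],
              snr_db = tc$snr_db, task_related = tc$task_related,
              task_unrelated = tc$task_unrelated,
              wide_snr_db = wide_snr(sp, f, default_nh(f)),
              sim_fund = similarity_score(tr, f, "fundamental"),
              sim_harm2 = similarity_score(tr, f, "second_harmonic"))
          }
        }
      }
    }
    write_tsv(do.call(rbind, cde_rows), p_cde)
    write_tsv(do.call(rbind, spec_rows), p_spec)
  }
  link_plain(p_cde, "cde.tsv")
  link_plain(p_spec, "spectral.tsv")
  cde <- utils::read.table(p_cde, header = TRUE, sep = "\t")
  spec_tab <- utils::read.table(p_spec, header = TRUE, sep = "\t")

  ## ---- stage 3: task-state microstates ----------------------------------
  p_ms <- stage_path("microstates")
  if (!file.exists(p_ms)) {
    ms_rows <- list()
    gen <- microstate_gen_spec(channel_names = cfg$spec$channel_names)
    for (si in seq_len(nrow(subjects))) {
      for (ci in seq_len(nrow(cells))) {
        cond <- cells$condition[ci]
        tp <- cells$timepoint[ci]
        eff <- subject_effect(cfg, cond, tp, subjects$pt[si])
        msr <- generate_microstate_recording(
          gen, cfg$microstate_duration, cfg$spec$fs,
          seed = derive_seed(cfg$seed, "ms", si, cond, tp), effect = eff)
        mdl <- fit_microstates(msr$recording, k = 4,
                               n_restarts = cfg$ms_restarts,
                               seed = derive_seed(cfg$seed, "msfit", si, cond, tp))
        met <- microstate_metrics(backfit_labels(mdl, msr$recording))
        pc <- met$per_class
        pc$subject <- si
        pc$condition <- cond
        pc$timepoint <- tp
        pc$gev <- mdl$gev
        ms_rows[[length(ms_rows) + 1L]] <- pc
      }
    }
    write_tsv(do.call(rbind, ms_rows), p_ms)
  }
  link_plain(p_ms, "microstates.tsv")
  ms_tab <- utils::read.table(p_ms, header = TRUE, sep = "\t")

  ## ---- stage 4: resting-state band power --------------------------------
  p_rest <- stage_path("resting_power")
  if (!file.exists(p_rest)) {
    rest_rows <- list()
    for (si in seq_len(nrow(subjects))) {
      model_s <- cfg$model
      model_s$fundamental_amp <- 0
      model_s$noise_scale <- cfg$model$noise_scale * subjects$noise_mult[si]
      for (ci in seq_len(nrow(cells))) {
        cond <- cells$condition[ci]
        tp <- cells$timepoint[ci]
        eff <- subject_effect(cfg, cond, tp, subjects$pt[si])
        rec <- generate_resting_recording(
          model_s, eff, cfg$resting_duration, cfg$spec$fs,
          seed = derive_seed(cfg$seed, "rest", si, cond, tp))
        bp <- band_power(rec, 8, 12)
        rest_rows[[length(rest_rows) + 1L]] <- data.frame(
          subject = si, condition = cond, timepoint = tp,
          channel = names(bp), alpha_power = as.numeric(bp))
      }
    }
    write_tsv(do.call(rbind, rest_rows), p_rest)
  }
  link_plain(p_rest, "resting_power.tsv")
  rest_tab <- utils::read.table(p_rest, header = TRUE, sep = "\t")

  ## ---- stage 5: inference ------------------------------------------------
  delta_cde <- function(condition, decoder, band) {
    pre <- cde$cde[cde$condition == condition & cde$timepoint == "Pre" &
                     cde$decoder == decoder & cde$band == band]
    p0 <- cde$cde[cde$condition == condition & cde$timepoint == "Post0" &
                    cde$decoder == decoder & cde$band == band]
    p0 - pre
  }
  stats_rows <- list()
  for (dec in cfg$decoders) {
    for (bnd in cfg$bands) {
      dr <- delta_cde("real", dec, bnd)
      ds <- delta_cde("sham", dec, bnd)
      ht <- paired_t(dr, ds, tail = "greater")
      stats_rows[[length(stats_rows) + 1L]] <- data.frame(
        decoder = dec, band = bnd,
        mean_delta_real = mean(dr), mean_delta_sham = mean(ds),
        t = ht$t, df = ht$df, p_one_tailed = ht$p)
    }
  }
  stats_tab <- do.call(rbind, stats_rows)
  stats_tab$p_fdr <- bh_fdr(stats_tab$p_one_tailed)$adjusted
  write_tsv(stats_tab, stage_path("stats_cde"))
  link_plain(stage_path("stats_cde"), "stats_cde.tsv")

  chs <- sort(unique(rest_tab$channel))
  pmat <- function(condition, timepoint) {
    sub <- rest_tab[rest_tab$condition == condition &
                      rest_tab$timepoint == timepoint, ]
    out <- matrix(NA_real_, cfg$n_subjects, length(chs),
                  dimnames = list(NULL, chs))
    out[cbind(sub$subject, match(sub$channel, chs))] <- sub$alpha_power
    out
  }
  nb <- channel_neighborhood(chs)
  clres <- cluster_permutation_test(pmat("real", "Post0"), pmat("real", "Pre"),
                                    nb, n_perm = cfg$n_perm, tail = "two",
                                    seed = derive_seed(cfg$seed, "cluster"))
  cl_json <- lapply(clres$clusters, function(cl) {
    list(labels = cl$labels, mass = cl$mass, p = cl$p, sign = cl$sign)
  })
  jsonlite::write_json(list(threshold = clres$threshold,
                            n_perm = clres$n_perm, clusters = cl_json),
                       file.path(cfg$out_dir, "clusters.json"),
                       auto_unbox = TRUE, digits = NA)

  ms_b <- function(condition, timepoint) {
    sub <- ms_tab[ms_tab$class == "B" & ms_tab$condition == condition &
                    ms_tab$timepoint == timepoint, ]
    sub$occurrence_per_s[order(sub$subject)]
  }
  d_occB <- ms_b("real", "Post0") - ms_b("real", "Pre")
  corr_rows <- list()
  ct <- pearson_corr(subjects$pt, d_occB)
  corr_rows[[1]] <- data.frame(x = "phosphene_threshold",
                               y = "delta_occurrence_B_real",
                               r = ct$r, df = ct$df, p = ct$p)
  snr_d <- function(condition, timepoint) {
    sub <- spec_tab[spec_tab$condition == condition &
                      spec_tab$timepoint == timepoint, ]
    tapply(sub$snr_db, sub$subject, mean)
  }
  d_snr <- snr_d("real", "Post0") - snr_d("real", "Pre")
  occ_pow <- function(condition, timepoint) {
    sub <- rest_tab[rest_tab$condition == condition &
                      rest_tab$timepoint == timepoint &
                      rest_tab$channel %in% occipital_montage(), ]
    tapply(sub$alpha_power, sub$subject, mean)
  }
  d_pow <- occ_pow("real", "Post0") - occ_pow("real", "Pre")
  ct2 <- pearson_corr(as.numeric(d_pow), as.numeric(d_snr))
  corr_rows[[2]] <- data.frame(x = "delta_resting_alpha_power_real",
                               y = "delta_task_snr_real",
                               r = ct2$r, df = ct2$df, p = ct2$p)
  corr_tab <- do.call(rbind, corr_rows)
  write_tsv(corr_tab, stage_path("correlations"))
  link_plain(stage_path("correlations"), "correlations.tsv")

  report <- list(
    config_hash = h,
    n_subjects = cfg$n_subjects,
    bands = cfg$bands,
    decoders = cfg$decoders,
    cde_tests = stats_tab,
    n_clusters = length(clres$clusters),
    correlations = corr_tab)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(cfg$out_dir)
}
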