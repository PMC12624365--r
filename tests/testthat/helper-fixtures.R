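# Shared miniature fixtures: one-band session specs and low-cost models keep
# the suite fast while exercising the full pipeline surface.

mf_spec <- function(n_blocks = 4) {
  session_spec(bands = list(MF = c(18, 22)), n_blocks = n_blocks)
}

quiet_model <- function(...) {
  signal_model(noise_scale = 0, alpha_amp = 0, ...)
}

tiny_recording <- function(n_ch = 4, n = 500, fs = 250, seed = 1) {
  set.seed(seed)
  eeg_recording(matrix(rnorm(n_ch * n), n_ch),
                fs, paste0("ch", seq_len(n_ch)))
}

average_ref_for_test <- function(data) {
  sweep(data, 2, colMeans(data))
}

# Subset a trial_set by trial index.
subset_trials <- function(ts, idx) {
  out <- list(data = ts$data[, , idx, drop = FALSE],
              info = ts$info[idx, , drop = FALSE],
              fs = ts$fs, channel_names = ts$channel_names)
  class(out) <- "trial_set"
  out
}
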