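#' One-sided power spectrum of an EEG segment
#'
#' Single-taper periodogram at 1/T Hz resolution, Parseval-consistent: the
#' power values sum to the time-domain mean square. By default the channels
#' of the occipital montage are averaged before spectral estimation;
#' `average = FALSE` returns a channels x bins matrix.
#'
#' @param x an `ssvep_trial`, `eeg_recording`, or channels x samples matrix.
#' @param fs sampling rate (taken from the object when available).
#' @param channels channel subset (default occipital montage when labels are
#'   available; `NULL` keeps all channels).
#' @param average average channels before the periodogram.
#' @return Object of class `eeg_spectrum`: list with `freqs` (Hz), `power`
#'   (uV^2 per bin; vector, or matrix if `average = FALSE`), `fs`,
#'   `resolution`.
#' @export
compute_spectrum <- function(x, fs = NULL, channels = occipital_montage(),
                             average = TRUE) {
  data <- if (is.list(x)) x$data else x
  if (is.null(fs)) fs <- if (is.list(x)) x$fs else stop_invalid("fs required")
  if (!is.null(channels)) {
    sel <- intersect(channels, rownames(data))
    if (!length(sel)) {
      stop_invalid("empty channel selection (no matching channel labels)")
    }
    data <- data[sel, , drop = FALSE]
  }
  n <- ncol(data)
  if (n < fs) stop_invalid("segment shorter than 1 s")
  if (average) data <- matrix(colMeans(data), 1)
  nf <- floor(n / 2) + 1L
  P <- t(apply(data, 1, function(v) {
    X <- stats::fft(v)
    p <- Mod(X[seq_len(nf)])^2 / n^2
    scale <- rep(2, nf)
    scale[1] <- 1
    if (n %% 2 == 0) scale[nf] <- 1
    p * scale
  }))
  freqs <- (seq_len(nf) - 1) * fs / n
  if (average) P <- as.numeric(P)
  structure(list(freqs = freqs, power = P, fs = fs, resolution = fs / n),
            class = "eeg_spectrum")
}

spectrum_bin <- function(spec, f) {
  i <- which.min(abs(spec$freqs - f))
  if (abs(spec$freqs[i] - f) > spec$resolution / 2 + 1e-9) {
    stop_invalid("frequency %g Hz does not align with the spectral grid", f)
  }
  i
}

spec_power_vec <- function(spec) {
  if (is.matrix(spec$power)) colMeans(spec$power) else spec$power
}

#' Task-related and task-unrelated power around a stimulation frequency
#'
#' Decomposes the local spectrum at stimulation frequency `f`: the
#' task-related component is the power in the `f` bin; the task-unrelated
#' component is the mean power over the bins within `f +- half_width` Hz
#' excluding the `f` bin; their ratio in dB is the narrow-band SNR.
#'
#' @param spec an [compute_spectrum()] result.
#' @param f stimulation frequency in Hz.
#' @param half_width neighborhood half-width in Hz (default 1).
#' @return List with `task_related`, `task_unrelated` (uV^2) and `snr_db`.
#' @export
task_component_powers <- function(spec, f, half_width = 1) {
  p <- spec_power_vec(spec)
  i <- spectrum_bin(spec, f)
  if (f - half_width < spec$freqs[1] - 1e-9 ||
      f + half_width > spec$freqs[length(spec$freqs)] + 1e-9) {
    stop_invalid("+-%g Hz neighborhood of %g Hz outside the spectral grid",
                 half_width, f)
  }
  nb <- which(spec$freqs >= f - half_width - 1e-9 &
                spec$freqs <= f + half_width + 1e-9)
  nb <- setdiff(nb, i)
  if (!length(nb)) stop_invalid("no neighborhood bins at this resolution")
  related <- p[i]
  unrelated <- mean(p[nb])
  list(task_related = related, task_unrelated = unrelated,
       snr_db = 10 * log10(related / unrelated))
}

#' Wide-band harmonic SNR
#'
#' SNR over the full harmonic series: summed power at harmonics `1..Nh` of
#' `f` relative to the summed expected background in the same bins, where the
#' background is estimated per harmonic as the mean power within
#' `+- half_width` Hz of that harmonic excluding all harmonic bins. Reduces
#' to the narrow-band SNR of [task_component_powers()] when `Nh = 1`, and is
#' 0 dB for a flat spectrum.
#'
#' @param spec an [compute_spectrum()] result.
#' @param f fundamental frequency in Hz.
#' @param Nh number of harmonics.
#' @param half_width background neighborhood half-width in Hz.
#' @return SNR in dB.
#' @export
wide_snr <- function(spec, f, Nh, half_width = 1) {
  if (Nh < 1) stop_invalid("Nh must be >= 1")
  p <- spec_power_vec(spec)
  hbins <- vapply(seq_len(Nh) * f, function(h) spectrum_bin(spec, h),
                  integer(1))
  bg <- vapply(seq_len(Nh), function(h) {
    fh <- h * f
    nb <- which(spec$freqs >= fh - half_width - 1e-9 &
                  spec$freqs <= fh + half_width + 1e-9)
    nb <- setdiff(nb, hbins)
    if (!length(nb)) stop_invalid("no background bins around harmonic %d", h)
    mean(p[nb])
  }, numeric(1))
  10 * log10(sum(p[hbins]) / sum(bg))
}

#' Band power
#'
#' Integrated spectral power per channel within `[lo, hi]` Hz. For a spectrum
#' input, bins are summed directly; for a recording, Welch-style averaging is
#' used (2-s Hann segments, 50% overlap).
#'
#' @param x an `eeg_spectrum`, `eeg_recording`, or channels x samples matrix.
#' @param lo,hi band edges in Hz.
#' @param fs sampling rate (recordings/matrices only).
#' @param channels channel subset (`NULL` = all).
#' @param seg_s Welch segment length in seconds.
#' @return Named numeric vector, uV^2 per channel (single value for averaged
#'   spectra).
#' @export
band_power <- function(x, lo, hi, fs = NULL, channels = NULL, seg_s = 2) {
  if (lo >= hi) stop_invalid("lo must be < hi")
  if (inherits(x, "eeg_spectrum")) {
    sel <- which(x$freqs >= lo - 1e-9 & x$freqs <= hi + 1e-9)
    if (!length(sel)) stop_invalid("no spectral bins in [%g, %g] Hz", lo, hi)
    if (is.matrix(x$power)) return(rowSums(x$power[, sel, drop = FALSE]))
    return(sum(x$power[sel]))
  }
  data <- if (is.list(x)) x$data else x
  if (is.null(fs)) fs <- if (is.list(x)) x$fs else stop_invalid("fs required")
  if (!is.null(channels) && !is.null(rownames(data))) {
    data <- data[intersect(channels, rownames(data)), , drop = FALSE]
  }
  psd <- welch_psd(data, fs, seg_s = seg_s)
  sel <- which(psd$freqs >= lo - 1e-9 & psd$freqs <= hi + 1e-9)
  if (!length(sel)) stop_invalid("no spectral bins in [%g, %g] Hz", lo, hi)
  out <- rowSums(psd$power[, sel, drop = FALSE])
  names(out) <- rownames(data)
  out
}

# Welch-averaged one-sided periodogram: Hann window, 50% overlap,
# Parseval-consistent per segment.
welch_psd <- function(data, fs, seg_s = 2, overlap = 0.5) {
  if (!is.matrix(data)) data <- matrix(data, 1)
  n <- ncol(data)
  nseg <- min(round(seg_s * fs), n)
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, n - nseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nseg) - 1) / (nseg - 1))
  wnorm <- mean(w^2)
  nf <- floor(nseg / 2) + 1L
  scale <- rep(2, nf)
  scale[1] <- 1
  if (nseg %% 2 == 0) scale[nf] <- 1
  P <- matrix(0, nrow(data), nf)
  for (s in starts) {
    seg <- data[, s:(s + nseg - 1), drop = FALSE]
    seg <- seg - rowMeans(seg)
    for (ch in seq_len(nrow(data))) {
      X <- stats::fft(seg[ch, ] * w)
      P[ch, ] <- P[ch, ] + Mod(X[seq_len(nf)])^2 / nseg^2 / wnorm * scale
    }
  }
  list(freqs = (seq_len(nf) - 1) * fs / nseg, power = P / length(starts))
}

#' Canonical-correlation similarity score of a trial
#'
#' First canonical correlation between the multichannel trial and the
#' sine-cosine pair at the fundamental frequency (or at the second harmonic
#' only), quantifying how strongly the stimulus-locked component is expressed.
#'
#' @param trial an `ssvep_trial` or channels x samples matrix.
#' @param f fundamental stimulation frequency in Hz.
#' @param order `"fundamental"` or `"second_harmonic"`.
#' @param fs sampling rate (from the trial object if present).
#' @param channels decoding channels.
#' @return Correlation in \[0, 1\].
#' @export
similarity_score <- function(trial, f, order = c("fundamental", "second_harmonic"),
                             fs = NULL, channels = occipital_montage()) {
  order <- match.arg(order)
  X <- decoding_matrix(trial, channels)
  if (is.null(fs)) fs <- trial_fs(trial)
  fr <- if (order == "fundamental") f else 2 * f
  if (fr >= fs / 2) stop_invalid("%s frequency %g Hz at or above Nyquist", order, fr)
  Y <- harmonic_reference(fr, nrow(X), fs, 1)
  cca_max_cor(X, Y)
}
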