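#' Continuous multichannel EEG recording
#'
#' Lightweight container for continuous EEG: a channels x samples matrix in
#' microvolts, a sampling rate, channel labels and an optional event table
#' (0-based sample indices with integer codes).
#'
#' @param data channels x samples numeric matrix, uV.
#' @param fs sampling rate in Hz.
#' @param channel_names one label per row of `data`.
#' @param events data.frame with columns `sample` (0-based) and `code`.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names = rownames(data),
                          events = data.frame(sample = integer(),
                                              code = integer())) {
  if (!is.matrix(data)) data <- as.matrix(data)
  if (any(!is.finite(data))) stop_invalid("recording contains NaN/Inf")
  if (length(channel_names) != nrow(data)) {
    stop_invalid("channel count (%d) != number of labels (%d)",
                 nrow(data), length(channel_names))
  }
  assert_scalar_pos(fs, "fs")
  if (nrow(events) && (any(events$sample < 0) ||
                       any(events$sample >= ncol(data)))) {
    stop_invalid("event sample index out of bounds")
  }
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$events)))
  invisible(x)
}

#' Write a recording as a BrainVision triplet
#'
#' Writes `<stem>.vhdr` (header), `<stem>.vmrk` (markers) and `<stem>.eeg`
#' (multiplexed little-endian INT_16 payload at 0.1 uV resolution, so the
#' round-trip quantization error is at most 0.05 uV).
#'
#' @param rec an [eeg_recording()].
#' @param path output path; the `.vhdr`/`.vmrk`/`.eeg` extensions are added
#'   to its stem.
#' @return The `.vhdr` path, invisibly.
#' @export
save_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  stem <- sub("\\.(vhdr|vmrk|eeg)$", "", path)
  base <- basename(stem)
  res <- 0.1   # uV per LSB
  vals <- round(rec$data / res)
  if (any(abs(vals) > 32767)) {
    stop_invalid("amplitude exceeds +-%.0f uV INT_16 range", 32767 * res)
  }
  nch <- nrow(rec$data)
  hdr <- c(
    "BrainVision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    sprintf("DataFile=%s.eeg", base),
    sprintf("MarkerFile=%s.vmrk", base),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", nch),
    sprintf("SamplingInterval=%.6f", 1e6 / rec$fs),
    "[Binary Infos]",
    "BinaryFormat=INT_16",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,%g,µV", seq_len(nch), rec$channel_names, res)
  )
  writeLines(hdr, paste0(stem, ".vhdr"), useBytes = TRUE)
  mrk <- c(
    "BrainVision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    sprintf("DataFile=%s.eeg", base),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0"
  )
  if (nrow(rec$events)) {
    mrk <- c(mrk, sprintf("Mk%d=Stimulus,S%3d,%d,1,0",
                          seq_len(nrow(rec$events)) + 1L,
                          rec$events$code, rec$events$sample + 1L))
  }
  writeLines(mrk, paste0(stem, ".vmrk"))
  con <- file(paste0(stem, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.integer(vals), con, size = 2L, endian = "little")
  invisible(paste0(stem, ".vhdr"))
}

# Parse key=value lines of a named section of a BrainVision INI file.
bv_section <- function(lines, section, file) {
  hits <- grep(sprintf("^\\[%s\\]", section), lines)
  if (!length(hits)) {
    stop_invalid("format-error in %s: missing [%s] section", file, section)
  }
  out <- character(); nms <- character()
  for (i in seq(hits[1] + 1L, length(lines))) {
    ln <- lines[i]
    if (grepl("^\\[", ln)) break
    if (!grepl("=", ln, fixed = TRUE)) next
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    nms <- c(nms, trimws(kv[1]))
    out <- c(out, trimws(paste(kv[-1], collapse = "=")))
  }
  names(out) <- nms
  out
}

#' Load a BrainVision recording
#'
#' @param path path to the `.vhdr` header.
#' @return An [eeg_recording()].
#' @export
load_recording <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  common <- bv_section(lines, "Common Infos", path)
  binfo <- bv_section(lines, "Binary Infos", path)
  if (!identical(binfo[["BinaryFormat"]], "INT_16")) {
    stop_invalid("format-error in %s: unsupported BinaryFormat %s",
                 path, binfo[["BinaryFormat"]])
  }
  if (!identical(common[["DataOrientation"]], "MULTIPLEXED")) {
    stop_invalid("format-error in %s: unsupported orientation", path)
  }
  nch <- as.integer(common[["NumberOfChannels"]])
  fs <- 1e6 / as.numeric(common[["SamplingInterval"]])
  chinfo <- bv_section(lines, "Channel Infos", path)
  names_res <- t(vapply(chinfo, function(v) {
    parts <- strsplit(v, ",")[[1]]
    c(parts[1], parts[3])
  }, character(2)))
  ch_names <- unname(names_res[, 1])
  res <- unname(as.numeric(names_res[, 2]))
  if (length(ch_names) != nch) {
    stop_invalid("format-error in %s: %d channel entries, header says %d",
                 path, length(ch_names), nch)
  }
  eeg_path <- file.path(dirname(path), common[["DataFile"]])
  nbytes <- file.size(eeg_path)
  if (is.na(nbytes)) stop_invalid("format-error: payload %s missing", eeg_path)
  if (nbytes %% (2L * nch) != 0) {
    stop_invalid("format-error in %s: truncated payload (%d bytes, %d channels)",
                 eeg_path, nbytes, nch)
  }
  nsamp <- nbytes / (2L * nch)
  con <- file(eeg_path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "integer", n = nch * nsamp, size = 2L, signed = TRUE,
                 endian = "little")
  data <- matrix(as.numeric(raw), nrow = nch) * res
  rownames(data) <- ch_names
  events <- data.frame(sample = integer(), code = integer())
  mrk_path <- file.path(dirname(path), common[["MarkerFile"]])
  if (file.exists(mrk_path)) {
    mk <- bv_section(readLines(mrk_path, warn = FALSE), "Marker Infos", mrk_path)
    stim <- mk[grepl("^Stimulus", mk)]
    if (length(stim)) {
      parts <- strsplit(stim, ",")
      events <- data.frame(
        sample = vapply(parts, function(p) as.integer(p[3]) - 1L, integer(1)),
        code = vapply(parts, function(p) {
          as.integer(sub("^S\\s*", "", p[2]))
        }, integer(1)), row.names = NULL)
      rownames(events) <- NULL
    }
  }
  eeg_recording(data, fs, ch_names, events)
}

#' Bandpass-filter and resample a recording
#'
#' Standard preprocessing: zero-phase Butterworth bandpass (4th-order
#' high-pass and low-pass applied forward-backward in cascade) followed by
#' polyphase anti-aliased resampling. Defaults implement the 1-90 Hz bandpass
#' with down-sampling to 250 Hz.
#'
#' @param rec an [eeg_recording()].
#' @param low,high bandpass corner frequencies in Hz.
#' @param fs_out output sampling rate in Hz.
#' @param order Butterworth order per section.
#' @return Filtered, resampled [eeg_recording()]; event sample indices are
#'   rescaled to the new rate.
#' @export
preprocess_recording <- function(rec, low = 1, high = 90, fs_out = 250,
                                 order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (low >= high) stop_invalid("low must be < high")
  if (high >= rec$fs / 2) stop_invalid("high >= input Nyquist")
  if (high >= fs_out / 2) {
    stop_invalid("high (%g Hz) at or above output Nyquist (%g Hz)",
                 high, fs_out / 2)
  }
  hp <- signal::butter(order, low / (rec$fs / 2), type = "high")
  lp <- signal::butter(order, high / (rec$fs / 2), type = "low")
  filt <- t(apply(rec$data, 1, function(x) {
    signal::filtfilt(lp, signal::filtfilt(hp, x))
  }))
  if (fs_out != rec$fs) {
    ratio <- fs_out / rec$fs
    frac <- as.integer(c(round(ratio * 1e6), 1e6))
    g <- frac[1]
    q <- frac[2]
    while (q != 0) { r <- g %% q; g <- q; q <- r }
    p <- frac[1] / g; q <- frac[2] / g
    filt <- t(apply(filt, 1, function(x) signal::resample(x, p, q)))
    events <- rec$events
    if (nrow(events)) events$sample <- round(events$sample * ratio)
  } else {
    events <- rec$events
  }
  eeg_recording(filt, fs_out, rec$channel_names, events)
}

#' Extract fixed-length epochs around events
#'
#' Cuts `[tmin, tmax)` windows (seconds, half-open, 0-based sample indexing)
#' around each onset, optionally shifted by a visual-response latency offset.
#'
#' @param rec an [eeg_recording()].
#' @param onsets 0-based onset samples, or a subset of `rec$events` (a
#'   data.frame with a `sample` column).
#' @param tmin,tmax epoch window in seconds relative to onset.
#' @param latency_offset additional shift in seconds applied to every epoch.
#' @param info optional data.frame of per-epoch labels (one row per onset).
#' @return A `trial_set` (see [generate_session()]).
#' @export
extract_epochs <- function(rec, onsets, tmin = 0, tmax = 4,
                           latency_offset = 0, info = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.data.frame(onsets)) onsets <- onsets$sample
  if (tmax <= tmin) stop_invalid("tmax must be > tmin")
  n <- round((tmax - tmin) * rec$fs)
  starts <- onsets + round((tmin + latency_offset) * rec$fs)
  for (i in seq_along(starts)) {
    if (starts[i] < 0 || starts[i] + n > ncol(rec$data)) {
      stop_invalid("epoch %d (onset sample %d) out of recording bounds",
                   i, onsets[i])
    }
  }
  data <- array(0, dim = c(nrow(rec$data), n, length(starts)),
                dimnames = list(rec$channel_names, NULL, NULL))
  for (i in seq_along(starts)) {
    data[, , i] <- rec$data[, (starts[i] + 1):(starts[i] + n)]
  }
  if (is.null(info)) info <- data.frame(onset = onsets)
  structure(list(data = data, info = info, fs = rec$fs,
                 channel_names = rec$channel_names),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials, %d channels x %d samples @ %g Hz\n",
              dim(x$data)[3], dim(x$data)[1], dim(x$data)[2], x$fs))
  invisible(x)
}

#' Persist a trial set as plain-text files
#'
#' Writes `labels.tsv` (the `info` table plus `fs`) and one
#' `trial_<i>.tsv` data matrix per trial into `dir`.
#'
#' @param ts a `trial_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_trialset <- function(ts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  info <- ts$info
  info$.fs <- ts$fs
  utils::write.table(info, file.path(dir, "labels.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (i in seq_len(dim(ts$data)[3])) {
    m <- ts$data[, , i]
    utils::write.table(cbind(channel = ts$channel_names, format(m, digits = 9)),
                       file.path(dir, sprintf("trial_%04d.tsv", i)),
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(dir)
}

#' Load a trial set saved by [save_trialset()]
#' @param dir directory written by [save_trialset()].
#' @return A `trial_set`.
#' @export
load_trialset <- function(dir) {
  info <- utils::read.table(file.path(dir, "labels.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  fs <- info$.fs[1]
  info$.fs <- NULL
  files <- sort(list.files(dir, "^trial_\\d+\\.tsv$", full.names = TRUE))
  if (length(files) != nrow(info)) {
    stop_invalid("trial file count (%d) != label rows (%d)",
                 length(files), nrow(info))
  }
  first <- utils::read.table(files[1], sep = "\t", stringsAsFactors = FALSE)
  ch <- first[[1]]
  data <- array(0, dim = c(length(ch), ncol(first) - 1L, length(files)),
                dimnames = list(ch, NULL, NULL))
  for (i in seq_along(files)) {
    m <- utils::read.table(files[i], sep = "\t")
    data[, , i] <- as.matrix(m[, -1])
  }
  structure(list(data = data, info = info, fs = fs, channel_names = ch),
            class = "trial_set")
}

#' Hook for ocular-artifact removal
#'
#' The synthetic generator produces no ocular artifacts, so this stage is a
#' documented pass-through kept so real-data pipelines can swap in an ICA
#' cleaning step.
#'
#' @param rec an [eeg_recording()].
#' @param method only `"none"` is implemented.
#' @return `rec`, unchanged.
#' @export
remove_artifacts <- function(rec, method = "none") {
  if (!identical(method, "none")) {
    stop_invalid("artifact removal method '%s' not implemented", method)
  }
  rec
}
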