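#' First canonical correlation between two multivariate time series
#'
#' Computes the largest canonical correlation between column-centered `X`
#' (time x channels) and `Y` (time x references) via QR decomposition and the
#' SVD of the cross-product of the orthonormal bases. Rank-deficient inputs
#' are handled through pivoted QR.
#'
#' @param X,Y numeric matrices with time in rows.
#' @return First canonical correlation in \[0, 1\].
#' @export
cca_max_cor <- function(X, Y) {
  X <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  Y <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  if (nrow(X) != nrow(Y)) stop_invalid("X and Y must share the time axis")
  qx <- qr(X)
  qy <- qr(Y)
  if (qx$rank == 0 || qy$rank == 0) return(0)
  Qx <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  Qy <- qr.Q(qy)[, seq_len(qy$rank), drop = FALSE]
  s <- svd(crossprod(Qx, Qy), nu = 0, nv = 0)$d
  min(1, max(0, s[1]))
}

#' Harmonic sine-cosine reference matrix
#'
#' Reference signals for frequency `f`: sine/cosine pairs at harmonics
#' `1..Nh`, sampled at `fs` over `n` samples (time x 2Nh). Harmonics at or
#' above Nyquist are dropped with a warning rather than silently aliased.
#'
#' @param f candidate frequency in Hz.
#' @param n number of samples.
#' @param fs sampling rate in Hz.
#' @param Nh number of harmonics.
#' @return Matrix n x (2 * kept harmonics).
#' @export
harmonic_reference <- function(f, n, fs, Nh) {
  if (Nh < 1) stop_invalid("Nh must be >= 1")
  keep <- which(seq_len(Nh) * f < fs / 2)
  if (length(keep) < Nh) {
    warning(sprintf("dropping %d reference harmonic(s) of %g Hz at/above Nyquist",
                    Nh - length(keep), f))
  }
  if (!length(keep)) stop_invalid("no reference harmonic of %g Hz below Nyquist", f)
  tt <- (seq_len(n) - 1) / fs
  do.call(cbind, lapply(keep, function(h) {
    cbind(sin(2 * pi * h * f * tt), cos(2 * pi * h * f * tt))
  }))
}

# Default harmonic budget for references: harmonics inside the 95 Hz analysis
# band, at most 5 (and always at least 1).
default_nh <- function(f, cap = 5, band_edge = 95) {
  max(1L, min(cap, as.integer(floor(band_edge / f))))
}

#' Filter-bank configuration for FBCCA
#'
#' Sub-band layout and weighting of the filter-bank CCA decoder. Sub-band `n`
#' spans `[n * band_lo, 95]` Hz (capped below Nyquist), following the
#' harmonic sub-band convention; sub-band weights are
#' `w(n) = n^(-a) + b`.
#'
#' @param band_lo lower edge of the stimulation band in Hz.
#' @param N number of sub-bands (defaults per band: LF 7, MF 5, HF 3, SHF 2).
#' @param a,b weight parameters.
#' @param Nh reference harmonics (default `min(5, floor(95 / f))` per
#'   candidate).
#' @param upper_edge common upper sub-band edge in Hz.
#' @param filter_order Butterworth order of the sub-band filters.
#' @return Object of class `fbcca_config`.
#' @export
fbcca_config <- function(band_lo, N = NULL, a = 1.25, b = 0.25, Nh = NULL,
                         upper_edge = 95, filter_order = 4) {
  if (is.null(N)) {
    N <- c(`8` = 7L, `18` = 5L, `28` = 3L, `38` = 2L)[as.character(band_lo)]
    if (is.na(N)) stop_invalid("no default N for band_lo = %g; pass N", band_lo)
  }
  if (N < 1) stop_invalid("N must be >= 1")
  edges <- lapply(seq_len(N), function(n) c(n * band_lo, upper_edge))
  bad <- vapply(edges, function(e) e[1] >= e[2], logical(1))
  if (any(bad)) stop_invalid("sub-band %d lower edge >= %g Hz; reduce N",
                             which(bad)[1], upper_edge)
  structure(list(N = as.integer(N), a = a, b = b, Nh = Nh,
                 subband_edges = edges, upper_edge = upper_edge,
                 filter_order = filter_order),
            class = "fbcca_config")
}

#' Sub-band weight of the filter-bank combination
#'
#' `w(n) = n^(-a) + b`, strictly decreasing in the sub-band index for
#' `a > 0`, so lower sub-bands (which carry the fundamental) dominate.
#'
#' @param n sub-band index (>= 1).
#' @param a,b weight parameters.
#' @return Weight value.
#' @export
#' @examples
#' subband_weight(1)  # 1.25
subband_weight <- function(n, a = 1.25, b = 0.25) {
  if (any(n < 1)) stop_invalid("sub-band index must be >= 1")
  n^(-a) + b
}

# Zero-phase sub-band bandpass, capped below Nyquist.
subband_filter <- function(X, lo, hi, fs, order) {
  hi <- min(hi, 0.95 * fs / 2)
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  apply(X, 2, function(x) signal::filtfilt(bf, x))
}

#' Classify one SSVEP trial with filter-bank CCA
#'
#' Decomposes the trial into sub-bands, computes the first canonical
#' correlation between each sub-band and the harmonic reference of every
#' candidate frequency, and combines them as
#' `rho_bar_k = sum_n w(n) * rho_kn^2`. The predicted target is the candidate
#' with maximal feature; ties break toward the lowest frequency.
#'
#' @param trial an `ssvep_trial`, or a channels x samples matrix.
#' @param candidates candidate frequencies in Hz.
#' @param cfg an [fbcca_config()].
#' @param fs sampling rate (taken from the trial object if present).
#' @param channels channel labels to decode from (default the occipital
#'   montage when labels are available).
#' @return List with `predicted` (Hz) and `features` (named `rho_bar` per
#'   candidate).
#' @export
fbcca_classify <- function(trial, candidates, cfg, fs = NULL,
                           channels = occipital_montage()) {
  X <- decoding_matrix(trial, channels)
  if (is.null(fs)) fs <- trial_fs(trial)
  if (!length(candidates)) stop_invalid("no candidate frequencies")
  n <- nrow(X)
  if (n < 0.5 * fs) stop_invalid("trial shorter than 0.5 s")
  refs <- lapply(candidates, function(f) {
    Nh <- if (is.null(cfg$Nh)) default_nh(f, band_edge = cfg$upper_edge) else cfg$Nh
    harmonic_reference(f, n, fs, Nh)
  })
  w <- subband_weight(seq_len(cfg$N), cfg$a, cfg$b)
  rho_bar <- numeric(length(candidates))
  for (nb in seq_len(cfg$N)) {
    e <- cfg$subband_edges[[nb]]
    Xn <- subband_filter(X, e[1], e[2], fs, cfg$filter_order)
    for (k in seq_along(candidates)) {
      rho <- cca_max_cor(Xn, refs[[k]])
      rho_bar[k] <- rho_bar[k] + w[nb] * rho^2
    }
  }
  names(rho_bar) <- as.character(candidates)
  best <- which(rho_bar == max(rho_bar))
  predicted <- candidates[best[which.min(candidates[best])]]
  list(predicted = predicted, features = rho_bar)
}

# Accept trial objects, trial_set slices, or raw matrices; returns time x ch.
decoding_matrix <- function(trial, channels) {
  data <- if (is.list(trial)) trial$data else trial
  if (!is.null(rownames(data)) && !is.null(channels)) {
    miss <- setdiff(channels, rownames(data))
    if (length(miss)) stop_invalid("channels not in trial: %s",
                                   paste(miss, collapse = ", "))
    data <- data[channels, , drop = FALSE]
  }
  t(data)
}

trial_fs <- function(trial) {
  if (is.list(trial) && !is.null(trial$fs)) trial$fs
  else stop_invalid("sampling rate not available; pass `fs`")
}

# Delay-augment a channels x T trial: stack n_delays shifted copies
# (future samples, zero-padded at the end).
delay_augment <- function(X, n_delays) {
  Tn <- ncol(X)
  out <- vector("list", n_delays + 1L)
  out[[1]] <- X
  for (d in seq_len(n_delays)) {
    out[[d + 1]] <- cbind(X[, (d + 1):Tn, drop = FALSE],
                          matrix(0, nrow(X), d))
  }
  do.call(rbind, out)
}

#' Fit a task-discriminant component analysis (TDCA) model
#'
#' Calibration-based SSVEP decoder: each training trial is delay-augmented
#' (`n_delays` shifted copies) and concatenated with its projection onto the
#' sine-cosine reference subspace of its class; discriminant spatial filters
#' are the leading generalized eigenvectors of between-class versus
#' within-class scatter (ridge-regularized when near-singular); class
#' templates are the filtered class means.
#'
#' @param train a `trial_set` with `info$f_target`.
#' @param n_delays number of delayed copies appended to each trial.
#' @param n_components number of discriminant filters kept. The default of 2
#'   suits small calibration sets (a handful of trials per class on a
#'   9-channel montage); more components overfit the within-class scatter.
#' @param Nh reference harmonics per class (default `min(5, floor(95/f))`).
#' @param ridge relative ridge added to the within-class scatter.
#' @param channels channel labels used for decoding.
#' @return Object of class `tdca_model`.
#' @export
tdca_fit <- function(train, n_delays = 3, n_components = 2, Nh = NULL,
                     ridge = 1e-6, channels = occipital_montage()) {
  classes <- sort(unique(train$info$f_target))
  if (any(table(train$info$f_target) < 2)) {
    stop_invalid("need >= 2 training trials per target")
  }
  fs <- train$fs
  Tn <- dim(train$data)[2]
  proj <- lapply(classes, function(f) {
    nh <- if (is.null(Nh)) default_nh(f) else Nh
    Y <- harmonic_reference(f, Tn, fs, nh)
    Q <- qr.Q(qr(Y))
    tcrossprod(Q)            # T x T projector onto the reference subspace
  })
  names(proj) <- as.character(classes)
  aug <- function(data, f) {
    Xa <- delay_augment(t(decoding_matrix(list(data = data), channels)), n_delays)
    cbind(Xa, Xa %*% proj[[as.character(f)]])
  }
  n_tr <- dim(train$data)[3]
  A <- vector("list", n_tr)
  for (i in seq_len(n_tr)) {
    A[[i]] <- aug(train$data[, , i], train$info$f_target[i])
  }
  Cp <- nrow(A[[1]])
  means <- lapply(classes, function(f) {
    idx <- which(train$info$f_target == f)
    Reduce(`+`, A[idx]) / length(idx)
  })
  names(means) <- as.character(classes)
  grand <- Reduce(`+`, means) / length(means)
  Sb <- matrix(0, Cp, Cp)
  for (m in means) {
    d <- m - grand
    Sb <- Sb + tcrossprod(d)
  }
  Sw <- matrix(0, Cp, Cp)
  for (i in seq_len(n_tr)) {
    d <- A[[i]] - means[[as.character(train$info$f_target[i])]]
    Sw <- Sw + tcrossprod(d)
  }
  lam <- ridge * mean(diag(Sw))
  if (lam == 0 || kappa(Sw) > 1e10) {
    lam <- max(lam, 1e-10 * max(1, mean(diag(Sw))))
    warning("within-class scatter near-singular; ridge-regularizing")
  }
  Sw <- Sw + diag(lam, Cp)
  eg <- eigen(solve(Sw, Sb))
  W <- Re(eg$vectors[, seq_len(min(n_components, Cp)), drop = FALSE])
  templates <- lapply(means, function(m) crossprod(W, m))
  structure(list(W = W, templates = templates, proj = proj,
                 classes = classes, n_delays = n_delays, fs = fs,
                 channels = channels, n_samples = Tn),
            class = "tdca_model")
}

#' Classify a trial with a fitted TDCA model
#'
#' The trial is augmented with each class's reference projection in turn and
#' scored by the Pearson correlation between its filtered feature matrix and
#' that class's template; the prediction is the best-correlated class (ties
#' toward the lowest frequency).
#'
#' @param model a [tdca_fit()] model.
#' @param trial an `ssvep_trial` or channels x samples matrix; must match the
#'   channel set and sample count the model was fitted on.
#' @return List with `predicted` (Hz) and `scores` per class.
#' @export
tdca_classify <- function(model, trial) {
  data <- if (is.list(trial)) trial$data else trial
  if (ncol(data) != model$n_samples) {
    stop_invalid("trial has %d samples, model expects %d (train and test at the same segment length)",
                 ncol(data), model$n_samples)
  }
  X <- t(decoding_matrix(list(data = data), model$channels))
  if (nrow(X) != length(model$channels)) {
    stop_invalid("trial channel set does not match model")
  }
  Xa <- delay_augment(X, model$n_delays)
  scores <- vapply(seq_along(model$classes), function(k) {
    key <- as.character(model$classes[k])
    Ak <- cbind(Xa, Xa %*% model$proj[[key]])
    Fk <- crossprod(model$W, Ak)
    stats::cor(as.vector(Fk), as.vector(model$templates[[key]]))
  }, numeric(1))
  names(scores) <- as.character(model$classes)
  best <- which(scores == max(scores))
  list(predicted = model$classes[best[which.min(model$classes[best])]],
       scores = scores)
}

#' Leave-one-block-out TDCA accuracy
#'
#' Cross-validated decoding: each block is tested with a model fitted on the
#' remaining blocks, as in standard calibration-based SSVEP evaluation.
#'
#' @param trials a `trial_set` with `info$block` and `info$f_target`.
#' @param duration decoded segment length in seconds (leading segment).
#' @param ... passed to [tdca_fit()].
#' @return Fraction correct in \[0, 1\].
#' @export
tdca_lobo_accuracy <- function(trials, duration = NULL, ...) {
  blocks <- sort(unique(trials$info$block))
  n_keep <- if (is.null(duration)) dim(trials$data)[2] else
    round(duration * trials$fs)
  correct <- 0L
  total <- 0L
  for (b in blocks) {
    te <- which(trials$info$block == b)
    tr <- which(trials$info$block != b)
    sub <- list(data = trials$data[, seq_len(n_keep), tr, drop = FALSE],
                info = trials$info[tr, , drop = FALSE],
                fs = trials$fs, channel_names = trials$channel_names)
    class(sub) <- "trial_set"
    model <- tdca_fit(sub, ...)
    for (i in te) {
      pred <- tdca_classify(model,
                            trials$data[, seq_len(n_keep), i, drop = FALSE][, , 1])
      correct <- correct + (pred$predicted == trials$info$f_target[i])
      total <- total + 1L
    }
  }
  correct / total
}
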