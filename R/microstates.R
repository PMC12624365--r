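# Average-reference a channels x samples matrix.
average_reference <- function(data) {
  sweep(data, 2, colMeans(data))
}

# Global field power: spatial SD of each sample's scalp map.
gfp <- function(data) {
  apply(data, 2, stats::sd)
}

# Indices of local GFP maxima (strictly greater than both neighbors).
gfp_peaks <- function(g) {
  n <- length(g)
  which(g[2:(n - 1)] > g[1:(n - 2)] & g[2:(n - 1)] >= g[3:n]) + 1L
}

#' Polarity-invariant spatial correlation between two scalp maps
#'
#' Absolute Pearson correlation across channels; microstate topographies are
#' polarity-invariant, so map and -map are identical.
#'
#' @param map1,map2 numeric vectors, one value per channel.
#' @return |r| in \[0, 1\].
#' @export
spatial_correlation <- function(map1, map2) {
  if (stats::sd(map1) == 0 || stats::sd(map2) == 0) {
    stop_invalid("zero-variance map")
  }
  abs(stats::cor(map1, map2))
}

#' Fit microstate topographies by modified k-means
#'
#' Segments EEG into `k` quasi-stable scalp topographies: recordings are
#' average-referenced, maps are fitted on the topographies at global field
#' power (GFP) peaks with polarity-invariant assignment (squared spatial
#' projection), and each map update is the principal eigenvector of the
#' assigned maps' outer-product sum. The best of `n_restarts` seeded random
#' initializations by global explained variance (GEV) is returned, and fitted
#' maps are named A-D by matching them to the canonical template
#' topographies.
#'
#' @param recordings an [eeg_recording()], matrix, or list of either.
#' @param k number of classes (default 4).
#' @param n_restarts random restarts (default 50).
#' @param seed RNG seed.
#' @param max_iter,tol convergence controls (GEV change below `tol` stops).
#' @return Object of class `microstate_model`: `maps` (k x channels, unit
#'   norm, rows named by class), `gev`, `k`, `channel_names`.
#' @export
fit_microstates <- function(recordings, k = 4, n_restarts = 50, seed = 1,
                            max_iter = 100, tol = 1e-6) {
  if (k < 2) stop_invalid("k must be >= 2")
  recs <- if (inherits(recordings, "eeg_recording") || is.matrix(recordings)) {
    list(recordings)
  } else {
    recordings
  }
  ch_names <- NULL
  V <- list()
  for (r in recs) {
    data <- if (is.list(r)) r$data else r
    if (is.null(ch_names)) ch_names <- rownames(data)
    data <- average_reference(data)
    g <- gfp(data)
    pk <- gfp_peaks(g)
    if (length(pk)) V[[length(V) + 1L]] <- t(data[, pk, drop = FALSE])
  }
  V <- do.call(rbind, V)        # n_peaks x channels
  if (is.null(V) || nrow(V) < k) {
    stop_invalid("fewer GFP peaks (%d) than classes (%d)",
                 if (is.null(V)) 0L else nrow(V), k)
  }
  gfp_v <- sqrt(rowSums(V^2))   # proportional to GFP at peaks
  denom <- sum(gfp_v^2)
  best <- NULL
  best_gev <- -Inf
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      maps <- V[sample.int(nrow(V), k), , drop = FALSE]
      maps <- maps / sqrt(rowSums(maps^2))
      prev_gev <- -Inf
      for (it in seq_len(max_iter)) {
        proj <- V %*% t(maps)           # n x k signed projections
        lab <- max.col(proj^2, ties.method = "first")
        for (j in seq_len(k)) {
          idx <- which(lab == j)
          if (!length(idx)) {
            vi <- V[sample.int(nrow(V), 1), ]
            maps[j, ] <- vi / sqrt(sum(vi^2))
            next
          }
          S <- crossprod(V[idx, , drop = FALSE])
          ev <- eigen(S, symmetric = TRUE)
          maps[j, ] <- ev$vectors[, 1]
        }
        num <- rowSums((V * maps[lab, , drop = FALSE]))^2
        gev_now <- sum(num) / denom
        if (abs(gev_now - prev_gev) < tol) break
        prev_gev <- gev_now
      }
      if (gev_now > best_gev) {
        best_gev <- gev_now
        best <- maps
      }
    }
  })
  model <- structure(list(maps = best, gev = best_gev, k = k,
                          channel_names = ch_names),
                     class = "microstate_model")
  if (k == 4 && !is.null(ch_names)) model <- name_microstates(model)
  model
}

# Assign labels A-D by maximizing total |spatial r| to the canonical
# templates over all k! permutations (k = 4 -> 24).
name_microstates <- function(model) {
  tmpl <- canonical_microstate_templates(model$channel_names)
  k <- model$k
  simmat <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      simmat[i, j] <- spatial_correlation(model$maps[i, ], tmpl[j, ])
    }
  }
  perms <- permutations_of(k)
  scores <- vapply(perms, function(p) sum(simmat[cbind(seq_len(k), p)]),
                   numeric(1))
  assign <- perms[[which.max(scores)]]
  ord <- order(assign)
  model$maps <- model$maps[ord, , drop = FALSE]
  rownames(model$maps) <- rownames(tmpl)
  model
}

permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (p in permutations_of(k - 1L)) {
      rest <- seq_len(k)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

#' Backfit microstate labels to a recording
#'
#' Labels every sample with the class whose map has the largest absolute
#' spatial correlation with the instantaneous (average-referenced)
#' topography. An optional minimum-duration rule reassigns runs shorter than
#' `min_duration_ms` to the neighboring class with the higher correlation
#' (off by default).
#'
#' @param model a [fit_microstates()] model.
#' @param rec an [eeg_recording()] or channels x samples matrix.
#' @param min_duration_ms temporal smoothing threshold; 0 disables.
#' @return A `label_sequence` (see [generate_microstate_recording()]).
#' @export
backfit_labels <- function(model, rec, min_duration_ms = 0) {
  data <- if (is.list(rec)) rec$data else rec
  fs <- if (is.list(rec)) rec$fs else stop_invalid("recording must carry fs")
  if (nrow(data) != ncol(model$maps)) {
    stop_invalid("channel count mismatch: recording %d, model %d",
                 nrow(data), ncol(model$maps))
  }
  data <- average_reference(data)
  # |corr| maximization == squared-projection maximization after norming rows
  Vn <- sweep(data, 2, sqrt(colSums(data^2)), `/`)
  M <- model$maps - rowMeans(model$maps)
  Mn <- M / sqrt(rowSums(M^2))
  proj <- crossprod(Vn, t(Mn))    # samples x k
  lab <- max.col(proj^2, ties.method = "first")
  if (min_duration_ms > 0) {
    min_len <- max(1L, round(min_duration_ms / 1000 * fs))
    r <- rle(lab)
    repeat {
      short <- which(r$lengths < min_len)
      short <- setdiff(short, c(1L, length(r$lengths)))
      if (!length(short)) break
      s <- short[1]
      ends <- cumsum(r$lengths)
      idx <- (ends[s] - r$lengths[s] + 1L):ends[s]
      left <- r$values[s - 1]
      right <- r$values[s + 1]
      better <- ifelse(proj[idx, left]^2 >= proj[idx, right]^2, left, right)
      lab[idx] <- better
      r <- rle(lab)
    }
  }
  structure(list(labels = lab, fs = fs, k = model$k,
                 names = rownames(model$maps)),
            class = "label_sequence")
}

label_runs <- function(ls) {
  r <- rle(ls$labels)
  n <- length(r$lengths)
  data.frame(class = r$values, length = r$lengths,
             edge = seq_len(n) %in% c(1L, n))
}

#' Microstate dynamics metrics
#'
#' Per-class mean duration (ms), occurrence (segments per second) and
#' contribution (fraction of samples), plus the between-class transition
#' matrix. Runs truncated by the recording edges are excluded from the mean
#' duration (unless a class occurs only in edge runs) but counted in
#' occurrence and contribution.
#'
#' @param ls a `label_sequence`.
#' @return Object of class `microstate_metrics`: data.frame `per_class`
#'   (`class`, `mean_duration_ms`, `occurrence_per_s`, `contribution`) and
#'   `transition_matrix`.
#' @export
microstate_metrics <- function(ls) {
  if (!length(ls$labels)) stop_invalid("empty label sequence")
  k <- ls$k
  runs <- label_runs(ls)
  total_s <- length(ls$labels) / ls$fs
  per <- lapply(seq_len(k), function(j) {
    rj <- runs[runs$class == j, , drop = FALSE]
    interior <- rj[!rj$edge, , drop = FALSE]
    dur_runs <- if (nrow(interior)) interior else rj
    data.frame(
      class = if (is.null(ls$names)) as.character(j) else ls$names[j],
      mean_duration_ms = if (nrow(rj)) mean(dur_runs$length) / ls$fs * 1000 else 0,
      occurrence_per_s = nrow(rj) / total_s,
      contribution = sum(rj$length) / length(ls$labels),
      stringsAsFactors = FALSE)
  })
  structure(list(per_class = do.call(rbind, per),
                 transition_matrix = transition_matrix(ls)),
            class = "microstate_metrics")
}

#' Microstate transition probability matrix
#'
#' Transitions are counted at run boundaries only (self-transitions are
#' undefined for microstate sequences); rows are normalized to 1 for classes
#' that leave at least one run, and are `NA` otherwise.
#'
#' @param ls a `label_sequence`.
#' @return k x k matrix of transition probabilities.
#' @export
transition_matrix <- function(ls) {
  k <- ls$k
  r <- rle(ls$labels)$values
  tm <- matrix(0, k, k)
  if (length(r) >= 2) {
    for (i in seq_len(length(r) - 1)) {
      tm[r[i], r[i + 1]] <- tm[r[i], r[i + 1]] + 1
    }
  }
  rs <- rowSums(tm)
  tm <- tm / ifelse(rs > 0, rs, NA)
  if (!is.null(ls$names)) dimnames(tm) <- list(ls$names, ls$names)
  tm
}

#' Global explained variance of a microstate model
#'
#' GFP^2-weighted squared spatial correlation between every sample's
#' topography and its assigned map, relative to total GFP^2, over one or more
#' recordings.
#'
#' @param model a [fit_microstates()] model.
#' @param recordings recording(s) as in [fit_microstates()].
#' @return GEV fraction in \[0, 1\].
#' @export
gev <- function(model, recordings) {
  recs <- if (inherits(recordings, "eeg_recording") || is.matrix(recordings)) {
    list(recordings)
  } else {
    recordings
  }
  num <- 0
  den <- 0
  M <- model$maps - rowMeans(model$maps)
  Mn <- M / sqrt(rowSums(M^2))
  for (r in recs) {
    data <- if (is.list(r)) r$data else r
    data <- average_reference(data)
    g <- gfp(data)
    # after average reference, Pearson r(v, m) = (v/||v||) . (m/||m||)
    Vn <- sweep(data, 2, sqrt(colSums(data^2)), `/`)
    corr2 <- apply(crossprod(Vn, t(Mn))^2, 1, max)
    num <- num + sum(g^2 * corr2)
    den <- den + sum(g^2)
  }
  num / den
}
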