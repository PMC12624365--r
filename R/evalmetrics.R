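#' Decoding accuracy as a function of analyzed data length
#'
#' Runs a decoder on the leading segment of every trial at each duration and
#' records the percentage of correct target identifications.
#'
#' @param decoder function `(data, i) -> predicted frequency`, where `data` is
#'   the channels x samples leading segment of trial `i`. See
#'   [fbcca_decoder()] for a ready-made closure.
#' @param trials a `trial_set` with `info$f_target`.
#' @param durations analysis durations in seconds, strictly increasing
#'   (default 0.5 to 4 s in 0.5 s steps).
#' @return Object of class `accuracy_curve`: data.frame-like list with
#'   `durations` (s), `accuracy` (%), and `n_trials`.
#' @export
accuracy_curve <- function(decoder, trials, durations = seq(0.5, 4, by = 0.5)) {
  if (any(diff(durations) <= 0)) stop_invalid("durations must be strictly increasing")
  n_total <- dim(trials$data)[2]
  n_trials <- dim(trials$data)[3]
  acc <- vapply(durations, function(d) {
    n <- round(d * trials$fs)
    if (n > n_total) {
      stop_invalid("duration %.2f s exceeds trial length %.2f s",
                   d, n_total / trials$fs)
    }
    correct <- 0L
    for (i in seq_len(n_trials)) {
      pred <- decoder(trials$data[, seq_len(n), i, drop = FALSE][, , 1], i)
      correct <- correct + (pred == trials$info$f_target[i])
    }
    100 * correct / n_trials
  }, numeric(1))
  structure(list(durations = durations, accuracy = acc, n_trials = n_trials),
            class = "accuracy_curve")
}

#' FBCCA decoder closure for [accuracy_curve()]
#'
#' @param candidates candidate frequencies in Hz.
#' @param cfg an [fbcca_config()].
#' @param fs sampling rate in Hz.
#' @param channels decoding channels.
#' @return A function `(data, i) -> predicted frequency`.
#' @export
fbcca_decoder <- function(candidates, cfg, fs, channels = occipital_montage()) {
  function(data, i) {
    fbcca_classify(data, candidates, cfg, fs = fs, channels = channels)$predicted
  }
}

#' Cumulative decoding effect (CDE)
#'
#' Reduces an accuracy-versus-duration curve to the ratio of the area under
#' the curve to the total attainable area, in percent (range 0-100). With the
#' default rectangle rule over equal-width duration bins this equals the mean
#' of the accuracy values; trapezoidal quadrature is available behind
#' `method`.
#'
#' @param curve an [accuracy_curve()], or a numeric vector of accuracies in
#'   percent at equally spaced durations.
#' @param method `"rectangle"` (mean; default) or `"trapezoid"`.
#' @return CDE in percent.
#' @export
#' @examples
#' compute_cde(c(50, 60, 70, 80, 90, 100, 100, 100))  # 81.25
compute_cde <- function(curve, method = c("rectangle", "trapezoid")) {
  method <- match.arg(method)
  acc <- if (inherits(curve, "accuracy_curve")) curve$accuracy else as.numeric(curve)
  if (length(acc) < 2) stop_invalid("need >= 2 curve points")
  if (any(!is.finite(acc)) || any(acc < 0) || any(acc > 100)) {
    stop_invalid("accuracies must lie in [0, 100]")
  }
  switch(method,
         rectangle = mean(acc),
         trapezoid = {
           n <- length(acc)
           (sum(acc) - (acc[1] + acc[n]) / 2) / (n - 1)
         })
}
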