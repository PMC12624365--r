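#' Standard 64-channel EEG montage
#'
#' Template 3D electrode positions (meters, head-centered) for the 64-channel
#' 10-20/10-5 layout used throughout the package (FCz reference, so FCz itself
#' carries no data channel). Coordinates are the standard 10-05 template
#' positions.
#'
#' @return A data.frame with columns `label`, `x`, `y`, `z`.
#' @export
#' @examples
#' head(standard_montage_64())
standard_montage_64 <- function() {
  m <- matrix(c(
    -0.02944, 0.08392, -0.00699,   # Fp1
     0.02987, 0.08490, -0.00708,   # Fp2
    -0.05484, 0.06857, -0.01059,   # AF7
    -0.03370, 0.07684,  0.02123,   # AF3
     0.00023, 0.08077,  0.03542,   # AFz
     0.03571, 0.07773,  0.02196,   # AF4
     0.05574, 0.06966, -0.01076,   # AF8
    -0.07026, 0.04247, -0.01142,   # F7
    -0.06447, 0.04804,  0.01692,   # F5
    -0.05024, 0.05311,  0.04219,   # F3
    -0.02750, 0.05693,  0.06034,   # F1
     0.00031, 0.05851,  0.06646,   # Fz
     0.02951, 0.05760,  0.05954,   # F2
     0.05184, 0.05430,  0.04081,   # F4
     0.06791, 0.04983,  0.01637,   # F6
     0.07304, 0.04442, -0.01200,   # F8
    -0.08077, 0.01412, -0.01113,   # FT7
    -0.07721, 0.01864,  0.02446,   # FC5
    -0.06018, 0.02272,  0.05554,   # FC3
    -0.03406, 0.02601,  0.07999,   # FC1
     0.03478, 0.02644,  0.07881,   # FC2
     0.06229, 0.02372,  0.05563,   # FC4
     0.07953, 0.01994,  0.02444,   # FC6
     0.08182, 0.01542, -0.01133,   # FT8
    -0.08416, -0.01602, -0.00935,  # T7
    -0.08028, -0.01376,  0.02916,  # C5
    -0.06536, -0.01163,  0.06436,  # C3
    -0.03616, -0.00998,  0.08975,  # C1
     0.00040, -0.00917,  0.10024,  # Cz
     0.03767, -0.00962,  0.08841,  # C2
     0.06712, -0.01090,  0.06358,  # C4
     0.08346, -0.01278,  0.02921,  # C6
     0.08508, -0.01502, -0.00949,  # T8
    -0.08483, -0.04602, -0.00706,  # TP7
    -0.07959, -0.04655,  0.03095,  # CP5
    -0.06356, -0.04701,  0.06562,  # CP3
    -0.03551, -0.04729,  0.09131,  # CP1
     0.00039, -0.04732,  0.09943,  # CPz
     0.03838, -0.04707,  0.09069,  # CP2
     0.06661, -0.04664,  0.06558,  # CP4
     0.08332, -0.04610,  0.03121,  # CP6
     0.08555, -0.04555, -0.00713,  # TP8
    -0.07243, -0.07345, -0.00249,  # P7
    -0.06727, -0.07629,  0.02838,  # P5
    -0.05301, -0.07879,  0.05594,  # P3
    -0.02862, -0.08052,  0.07544,  # P1
     0.00032, -0.08111,  0.08261,  # Pz
     0.03192, -0.08049,  0.07672,  # P2
     0.05567, -0.07856,  0.05656,  # P4
     0.06789, -0.07590,  0.02809,  # P6
     0.07306, -0.07307, -0.00254,  # P8
    -0.05484, -0.09753,  0.00279,  # PO7
    -0.04842, -0.09934,  0.02160,  # PO5
    -0.03651, -0.10085,  0.03717,  # PO3
     0.00022, -0.10218,  0.05061,  # POz
     0.03678, -0.10085,  0.03640,  # PO4
     0.04982, -0.09945,  0.02173,  # PO6
     0.05567, -0.09763,  0.00273,  # PO8
    -0.02941, -0.11245,  0.00884,  # O1
     0.00011, -0.11489,  0.01466,  # Oz
     0.02984, -0.11216,  0.00880,  # O2
     0.00000, -0.11857, -0.02308,  # Iz
    -0.08562, -0.04651, -0.04571,  # TP9
     0.08616, -0.04704, -0.04587   # TP10
  ), ncol = 3, byrow = TRUE)
  labels <- c(
    "Fp1", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8", "F7", "F5", "F3", "F1",
    "Fz", "F2", "F4", "F6", "F8", "FT7", "FC5", "FC3", "FC1", "FC2", "FC4",
    "FC6", "FT8", "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8", "TP7",
    "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "P7", "P5", "P3",
    "P1", "Pz", "P2", "P4", "P6", "P8", "PO7", "PO5", "PO3", "POz", "PO4",
    "PO6", "PO8", "O1", "Oz", "O2", "Iz", "TP9", "TP10"
  )
  data.frame(label = labels, x = m[, 1], y = m[, 2], z = m[, 3],
             stringsAsFactors = FALSE)
}

#' Default occipital decoding montage
#'
#' The nine occipito-parietal channels used for SSVEP decoding and spectral
#' analysis. The exact channel identity is a configurable convention of this
#' package.
#'
#' @return Character vector of channel labels.
#' @export
occipital_montage <- function() {
  c("Pz", "PO3", "POz", "PO4", "PO5", "PO6", "O1", "Oz", "O2")
}

# Euclidean inter-electrode distance matrix in meters for the given labels.
montage_distances <- function(labels = standard_montage_64()$label) {
  mon <- standard_montage_64()
  idx <- match(labels, mon$label)
  if (anyNA(idx)) {
    stop_invalid("unknown channel label(s): %s",
                 paste(labels[is.na(idx)], collapse = ", "))
  }
  d <- as.matrix(stats::dist(mon[idx, c("x", "y", "z")]))
  dimnames(d) <- list(labels, labels)
  d
}

#' Channel neighborhood from template montage coordinates
#'
#' Builds the symmetric channel adjacency used by the cluster-based permutation
#' test: two channels are neighbors when their template scalp distance is at
#' most `max_dist` meters (default 4 cm).
#'
#' @param labels channel labels, a subset of [standard_montage_64()].
#' @param max_dist neighborhood distance criterion in meters.
#' @return Object of class `channel_neighborhood`: list with the boolean
#'   `adjacency` matrix, `labels`, and `criterion`.
#' @export
channel_neighborhood <- function(labels = standard_montage_64()$label,
                                 max_dist = 0.04) {
  assert_scalar_pos(max_dist, "max_dist")
  d <- montage_distances(labels)
  adj <- d <= max_dist
  diag(adj) <- FALSE
  structure(list(adjacency = adj, labels = labels, criterion = max_dist),
            class = "channel_neighborhood")
}

#' Occipital scalp topography
#'
#' Per-channel weights for the SSVEP source projection: a Gaussian over the
#' scalp distance from Oz, maximum normalized to 1. A crude but monotone stand-in
#' for a volume-conduction forward model.
#'
#' @param labels channel labels.
#' @param sigma Gaussian width in meters.
#' @param center label of the topography peak.
#' @return Named numeric vector of weights in (0, 1].
#' @export
occipital_topography <- function(labels = standard_montage_64()$label,
                                 sigma = 0.05, center = "Oz") {
  assert_scalar_pos(sigma, "sigma")
  d <- montage_distances(labels)
  if (!center %in% labels) stop_invalid("center channel %s not in montage", center)
  w <- exp(-(d[, center]^2) / (2 * sigma^2))
  w <- w / max(w)
  names(w) <- labels
  w
}
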