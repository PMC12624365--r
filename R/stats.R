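# Connected components of the supra-threshold channel set under `adj`.
adjacency_clusters <- function(members, adj) {
  out <- list()
  remaining <- members
  while (length(remaining)) {
    queue <- remaining[1]
    comp <- integer()
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      nbrs <- intersect(which(adj[v, ]), remaining)
      queue <- c(queue, setdiff(nbrs, comp))
    }
    out[[length(out) + 1L]] <- sort(comp)
    remaining <- setdiff(remaining, comp)
  }
  out
}

# Per-channel paired t statistics for difference matrix d (subjects x ch).
paired_t_channels <- function(d) {
  n <- nrow(d)
  m <- colMeans(d)
  s <- sqrt(pmax(colSums(d^2) - n * m^2, 0) / (n - 1))
  sqrt(n) * m / s    # zero-variance nonzero difference maps to +-Inf
}

# Max cluster mass in one t-vector, given threshold/tail.
max_cluster_mass <- function(tvals, thr, adj, tail) {
  mass <- 0
  pos <- which(tvals > thr)
  if (length(pos)) {
    for (cl in adjacency_clusters(pos, adj)) {
      mass <- max(mass, sum(tvals[cl]))
    }
  }
  if (tail == "two") {
    neg <- which(tvals < -thr)
    if (length(neg)) {
      for (cl in adjacency_clusters(neg, adj)) {
        mass <- max(mass, abs(sum(tvals[cl])))
      }
    }
  }
  mass
}

#' Channel-space cluster-based permutation test
#'
#' Nonparametric paired comparison of two conditions over channels with
#' cluster correction for multiple comparisons: per-channel paired t-values
#' are thresholded at the critical t of `alpha`, supra-threshold channels are
#' clustered by scalp adjacency (sign-consistent for two-tailed tests), each
#' cluster is scored by its summed t (cluster mass), and Monte-Carlo p-values
#' are obtained from the maximum cluster mass under random within-subject
#' condition sign flips (plus-one corrected).
#'
#' @param a,b subjects x channels matrices, paired by row.
#' @param neighborhood a [channel_neighborhood()] matching the columns.
#' @param n_perm number of permutations (default 1000).
#' @param alpha cluster-forming threshold probability.
#' @param tail `"two"` or `"one"` (one-tailed: a > b).
#' @param seed RNG seed for the permutation draw.
#' @return Object of class `cluster_result`: list of `clusters` (each with
#'   `channels`, `labels`, `mass`, `p`), `t_obs` per channel, `threshold`,
#'   `n_perm`.
#' @export
cluster_permutation_test <- function(a, b, neighborhood, n_perm = 1000,
                                     alpha = 0.05, tail = c("two", "one"),
                                     seed = 1) {
  tail <- match.arg(tail)
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop_invalid("a and b must have equal dimensions")
  n <- nrow(a)
  if (n < 3) stop_invalid("need >= 3 subjects")
  adj <- neighborhood$adjacency
  if (ncol(a) != ncol(adj)) {
    stop_invalid("channel count (%d) does not match neighborhood (%d)",
                 ncol(a), ncol(adj))
  }
  d <- a - b
  tobs <- paired_t_channels(d)
  df <- n - 1
  thr <- if (tail == "two") stats::qt(1 - alpha / 2, df) else
    stats::qt(1 - alpha, df)

  clusters <- list()
  pos <- which(tobs > thr)
  for (cl in adjacency_clusters(pos, adj)) {
    clusters[[length(clusters) + 1L]] <-
      list(channels = cl, labels = neighborhood$labels[cl],
           mass = sum(tobs[cl]), sign = 1L)
  }
  if (tail == "two") {
    neg <- which(tobs < -thr)
    for (cl in adjacency_clusters(neg, adj)) {
      clusters[[length(clusters) + 1L]] <-
        list(channels = cl, labels = neighborhood$labels[cl],
             mass = sum(tobs[cl]), sign = -1L)
    }
  }

  if (length(clusters)) {
    # batched sign-flip null: the per-subject squared differences are flip
    # invariant, so only the flipped means need recomputation
    css <- colSums(d^2)
    null_max <- with_seed(seed, {
      flips <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
      M <- flips %*% d / n
      vapply(seq_len(n_perm), function(p) {
        m <- M[p, ]
        s <- sqrt((css - n * m^2) / (n - 1))
        max_cluster_mass(sqrt(n) * m / s, thr, adj, tail)
      }, numeric(1))
    })
    for (i in seq_along(clusters)) {
      obs <- abs(clusters[[i]]$mass)
      clusters[[i]]$p <- (1 + sum(null_max >= obs)) / (n_perm + 1)
    }
  }
  structure(list(clusters = clusters, t_obs = tobs, threshold = thr,
                 n_perm = n_perm, tail = tail,
                 labels = neighborhood$labels),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), |t| threshold %.3f, %d permutations\n",
              length(x$clusters), x$threshold, x$n_perm))
  for (cl in x$clusters) {
    cat(sprintf("  mass %8.2f  p = %.4f  channels: %s\n", cl$mass, cl$p,
                paste(cl$labels, collapse = " ")))
  }
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR procedure: returns adjusted p-values (via
#' [stats::p.adjust()]) and rejection flags at level `q`.
#'
#' @param pvals p-values in \[0, 1\].
#' @param q FDR level.
#' @return List with `rejected` (logical) and `adjusted` p-values.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop_invalid("p-values must lie in [0, 1]")
  }
  adjusted <- stats::p.adjust(pvals, method = "BH")
  list(rejected = adjusted <= q, adjusted = adjusted)
}

#' Paired t-test
#'
#' @param x,y paired samples (length >= 3).
#' @param tail `"two"`, `"greater"` (x > y) or `"less"`.
#' @return List with `t`, `df`, `p`.
#' @export
paired_t <- function(x, y, tail = c("two", "greater", "less")) {
  tail <- match.arg(tail)
  if (length(x) != length(y) || length(x) < 3) {
    stop_invalid("x and y must be paired with length >= 3")
  }
  alt <- c(two = "two.sided", greater = "greater", less = "less")[[tail]]
  if (stats::sd(x - y) == 0) {
    # identical pairs: t = 0 by convention, otherwise the statistic is
    # undefined (constant nonzero difference)
    if (mean(x - y) != 0) stop_invalid("zero-variance paired differences")
    return(list(t = 0, df = length(x) - 1,
                p = if (tail == "two") 1 else 0.5))
  }
  ht <- stats::t.test(x, y, paired = TRUE, alternative = alt)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Pearson correlation with test
#'
#' @param x,y numeric vectors (length >= 3).
#' @return List with `r`, `df`, `p`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop_invalid("x and y must be equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop_invalid("zero-variance input")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Linear mixed-model adapter for effect tables
#'
#' Thin wrapper fitting `response ~ Condition * Time + (1 | Subject)` with
#' `lmerTest` on a long-format feature table; the mixed-model machinery
#' itself is deliberately delegated, not re-implemented.
#'
#' @param data data.frame with columns `Condition`, `Time`, `Subject` and the
#'   response.
#' @param response name of the response column.
#' @return List with the fitted model (`fit`) and its fixed-effect
#'   coefficient table (`coefficients`).
#' @export
fit_effect_lmm <- function(data, response) {
  if (!requireNamespace("lmerTest", quietly = TRUE)) {
    stop_invalid("fit_effect_lmm requires the lmerTest package")
  }
  fml <- stats::as.formula(
    paste(response, "~ Condition * Time + (1 | Subject)"))
  fit <- lmerTest::lmer(fml, data = data)
  list(fit = fit, coefficients = stats::coef(summary(fit)))
}
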