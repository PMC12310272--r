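#' Peak latency per electrode
#'
#' Latency is the time of the global absolute extremum of the per-electrode
#' mean evoked waveform after the blank window (ties resolved to the earlier
#' sample). Activity is decided by the across-trial max-z statistic of
#' [extractFeatures()].
#'
#' @param epochs a blanked, centered [EvokedEpochSet-class].
#' @param activityThresholdSd activity threshold (standard errors).
#' @param features optionally, a precomputed `WaveformFeatureTable` for
#'   these epochs (avoids recomputation).
#' @return a `LatencyTable`: data frame with `channel`, `latencyMs` (NA for
#'   inactive electrodes), `amplitudeUv` (signed value at the peak),
#'   `active`, `distanceUm` (to the stimulation site), plus attributes
#'   `phase` and `thresholdSd`.
#' @export
peakLatency <- function(epochs, activityThresholdSd = 6, features = NULL) {
  ft <- (features %||%
    extractFeatures(epochs, activityThresholdSd = activityThresholdSd))$features
  dist <- rep(NA_real_, nrow(ft))
  g <- epochs@provenance$geometry
  ev <- epochs@events
  if (!is.null(g) && nrow(ev)) {
    pos <- electrodePositions(g)
    dist <- sqrt((pos$x - ev$site_x[1])^2 + (pos$y - ev$site_y[1])^2)
  }
  out <- data.frame(channel = ft$channel, latencyMs = ft$latencyMs,
                    amplitudeUv = ft$amplitudeUv, active = ft$active,
                    distanceUm = dist)
  attr(out, "phase") <- epochs@phase
  attr(out, "thresholdSd") <- activityThresholdSd
  class(out) <- c("LatencyTable", "data.frame")
  out
}

#' Cluster peak latencies into initial/central/terminal groups
#'
#' Agglomerative hierarchical clustering (Ward linkage, `ward.D2`) of the
#' one-dimensional active-electrode latencies, cut at `k` clusters,
#' followed by a local boundary refinement: optimal 1-D clusters are
#' contiguous in sorted order, so the cut boundaries are hill-climbed to a
#' local within-cluster-SSE optimum (Ward's greedy merges alone are
#' measurably sub-optimal on small unstructured sets). Clusters are renamed
#' by ascending mean latency.
#'
#' @param table a `LatencyTable` from [peakLatency()].
#' @param k number of temporal clusters (default 3).
#' @return a `TemporalClusterAssignment`: list with `assignment` (data
#'   frame: `channel`, `latencyMs`, `cluster`) and `summary` (per-cluster
#'   `n` and `meanLatencyMs`, strictly ordered), plus the phase tag.
#' @export
clusterLatencies <- function(table, k = 3) {
  act <- table[table$active & !is.na(table$latencyMs), , drop = FALSE]
  lat <- act$latencyMs
  if (length(unique(lat)) < k)
    stopf("need at least %d distinct latencies, have %d", k, length(unique(lat)))
  hc <- stats::hclust(stats::dist(lat), method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  means <- vapply(seq_len(k), function(c) mean(lat[raw == c]), numeric(1))
  ordC <- order(means)
  relabel <- integer(k); relabel[ordC] <- seq_len(k)
  memb <- relabel[raw]                     # 1..k by ascending mean
  # contiguous representation in sorted order + boundary hill-climb
  ordX <- order(lat)
  counts <- tabulate(memb, k)
  memb[ordX] <- refineBoundaries(lat[ordX], counts)
  names <- if (k == 3) c("initial", "central", "terminal")
           else paste0("cluster", seq_len(k))
  cl <- factor(names[memb], levels = names)
  assignment <- data.frame(channel = act$channel, latencyMs = lat, cluster = cl)
  summary <- data.frame(cluster = names,
                        n = as.integer(table(cl)),
                        meanLatencyMs = vapply(seq_len(k), function(c)
                          mean(lat[memb == c]), numeric(1)))
  structure(list(assignment = assignment, summary = summary,
                 phase = attr(table, "phase")),
            class = c("TemporalClusterAssignment", "list"))
}

# Hill-climb the k-1 boundaries of a contiguous partition of sorted values
# to a local within-cluster-SSE optimum. `counts` gives the initial sizes.
refineBoundaries <- function(xs, counts) {
  n <- length(xs)
  k <- length(counts)
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  seg <- function(i, j) {                  # SSE of xs[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  b <- cumsum(counts)[-k]                  # boundary = last index of cluster
  total <- function(b) {
    lo <- c(1L, b + 1L); hi <- c(b, n)
    sum(vapply(seq_len(k), function(j) seg(lo[j], hi[j]), numeric(1)))
  }
  cur <- total(b)
  # coordinate descent: each boundary in turn is placed optimally within
  # the span of its two adjacent clusters
  repeat {
    improved <- FALSE
    for (j in seq_len(k - 1)) {
      lo <- if (j == 1) 1L else b[j - 1] + 1L
      hi <- if (j == k - 1) n else b[j + 1]
      splits <- lo:(hi - 1L)
      costs <- vapply(splits, function(s) seg(lo, s) + seg(s + 1L, hi),
                      numeric(1))
      best <- splits[which.min(costs)]
      if (best != b[j]) {
        cand <- b; cand[j] <- best
        val <- total(cand)
        if (val < cur - 1e-12) { b <- cand; cur <- val; improved <- TRUE }
      }
    }
    if (!improved) break
  }
  rep(seq_len(k), diff(c(0L, b, n)))
}

#' Percent latency change per temporal cluster
#'
#' Clusters are matched across phases by rank (initial to initial, and so
#' on). Change is `100 * (mean_post - mean_base) / mean_base`; negative
#' values mean faster post-tetanic responses.
#'
#' @param base,post `TemporalClusterAssignment`s for the two phases.
#' @return named numeric vector, percent change per cluster.
#' @export
latencyChange <- function(base, post) {
  stopifnot(inherits(base, "TemporalClusterAssignment"),
            inherits(post, "TemporalClusterAssignment"))
  if (!identical(base$summary$cluster, post$summary$cluster))
    stopf("cluster names differ between phases")
  if (any(base$summary$n == 0) || any(post$summary$n == 0))
    stopf("empty temporal cluster in one phase")
  ch <- 100 * (post$summary$meanLatencyMs - base$summary$meanLatencyMs) /
    base$summary$meanLatencyMs
  stats::setNames(ch, base$summary$cluster)
}

#' Fold change in active-electrode counts per temporal cluster
#'
#' @param base,post `TemporalClusterAssignment`s, or named numeric vectors
#'   of counts.
#' @return named numeric vector of fold changes (`post / base`); clusters
#'   with zero baseline count yield `NA` (undefined).
#' @export
recruitment <- function(base, post) {
  getCounts <- function(x) {
    if (inherits(x, "TemporalClusterAssignment"))
      stats::setNames(x$summary$n, x$summary$cluster)
    else unlist(x)
  }
  b <- getCounts(base); p <- getCounts(post)
  if (!identical(names(b), names(p))) stopf("cluster names differ")
  fold <- ifelse(b > 0, p / b, NA_real_)
  if (any(b == 0))
    warning("zero baseline count in cluster(s): ",
            paste(names(b)[b == 0], collapse = ", "), "; fold undefined")
  stats::setNames(fold, names(b))
}
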