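#' Classify evoked waveforms by PCA + k-means
#'
#' Builds the feature space `[z-scored scalar features || peak-aligned mean
#' waveform]`, reduces it by PCA to the smallest number of components
#' explaining at least `varianceThreshold` of the variance (capped at
#' `maxComponents`), and clusters the scores with k-means (k-means++ style
#' seeding, `nRestarts` seeded restarts, best total within-cluster sum of
#' squares kept; inertia ties broken by lowest restart index). Use k = 4 for
#' CA networks and k = 3 for DG.
#'
#' @param features a `WaveformFeatureTable` from [extractFeatures()].
#' @param k number of clusters.
#' @param seed integer seed; labels are deterministic given the seed.
#' @param nRestarts number of k-means restarts.
#' @param varianceThreshold PCA explained-variance threshold.
#' @param maxComponents PCA component cap.
#' @return a `ClassificationResult`: list with `channel` (active electrode
#'   ids), `cluster` (integer labels), `scores`, `explainedVar`,
#'   `nComponents`, `k`, `seed`, `varianceThreshold`.
#' @export
classifyWaveforms <- function(features, k, seed = 1L, nRestarts = 20,
                              varianceThreshold = 0.9, maxComponents = 10) {
  stopifnot(inherits(features, "WaveformFeatureTable"))
  ft <- features$features
  act <- which(ft$active)
  if (length(act) < k)
    stopf("only %d active electrodes for k = %d clusters", length(act), k)
  zscore <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(x * 0)
    (x - mean(x)) / s
  }
  X <- cbind(zscore(ft$p2pUv[act]), zscore(ft$slopeUvMs[act]),
             zscore(ft$latencyMs[act]), features$waveforms)
  if (all(apply(X, 2, function(col) max(col) - min(col)) < 1e-12))
    stopf("degenerate input: all active electrodes have identical features")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  evar <- pc$sdev^2 / sum(pc$sdev^2)
  nComp <- min(which(cumsum(evar) >= varianceThreshold)[1], maxComponents,
               ncol(pc$x))
  if (is.na(nComp)) nComp <- min(maxComponents, ncol(pc$x))
  scores <- pc$x[, seq_len(nComp), drop = FALSE]

  best <- NULL
  withLocalSeed(seed, {
    for (r in seq_len(nRestarts)) {
      centers <- kmeansPlusPlusInit(scores, k)
      km <- suppressWarnings(stats::kmeans(scores, centers = centers,
                                           iter.max = 100))
      if (is.null(best) || km$tot.withinss < best$tot.withinss - 1e-12)
        best <- km
    }
  })
  structure(list(channel = act, cluster = best$cluster, scores = scores,
                 explainedVar = evar[seq_len(nComp)], nComponents = nComp,
                 k = k, seed = seed, varianceThreshold = varianceThreshold,
                 phase = features$phase),
            class = c("ClassificationResult", "list"))
}

# k-means++ style seeding: first center uniform, then D^2-weighted draws
kmeansPlusPlusInit <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    tot <- sum(d2)
    i <- if (tot <= 0) sample.int(n, 1) else sample.int(n, 1, prob = d2 / tot)
    centers[j + 1, ] <- x[i, ]
    d2 <- pmin(d2, rowSums((x - matrix(x[i, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

permutationsOf <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutationsOf(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Score a classification against the anatomical layer map
#'
#' Clusters are mapped to layers by the one-to-one assignment maximizing the
#' total row-normalized diagonal mass (optimal over all permutations, i.e.
#' a Hungarian-equivalent search at these sizes), then accuracy is the mean
#' over true-layer rows of the row-normalized confusion diagonal.
#'
#' @param result a `ClassificationResult`.
#' @param layers a [LayerMap-class]; electrodes labelled `none` are excluded
#'   from scoring.
#' @return list with `confusion` (row-normalized, rows = true layers,
#'   columns reordered to the assigned layers), `counts` (raw counts),
#'   `accuracy` (mean diagonal probability in \[0, 1\]), `assignment`.
#' @export
scoreClassification <- function(result, layers) {
  stopifnot(inherits(result, "ClassificationResult"), is(layers, "LayerMap"))
  lab <- as.character(layerLabels(layers))[result$channel]
  keep <- lab != "none"
  lab <- lab[keep]
  cl <- result$cluster[keep]
  layerOrder <- intersect(c(CA_LAYERS, DG_LAYERS), unique(lab))
  if (length(layerOrder) != result$k)
    stopf("%d layers present but k = %d clusters; scoring needs a one-to-one map",
          length(layerOrder), result$k)
  counts <- table(factor(lab, levels = layerOrder),
                  factor(cl, levels = seq_len(result$k)))
  counts <- matrix(as.numeric(counts), nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
  if (any(rowSums(counts) == 0)) stopf("layer absent from the classified set")
  norm <- counts / rowSums(counts)
  perms <- permutationsOf(result$k)
  diagMass <- apply(perms, 1, function(p)
    sum(norm[cbind(seq_len(result$k), p)]))
  p <- perms[which.max(diagMass), ]
  confusion <- norm[, p, drop = FALSE]
  colnames(confusion) <- layerOrder
  list(confusion = confusion, counts = counts[, p, drop = FALSE],
       accuracy = mean(diag(confusion)),
       assignment = stats::setNames(p, layerOrder))
}
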