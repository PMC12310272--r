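#' Band specification for parametric layer maps
#'
#' Ordered laminae as contiguous horizontal bands of given widths (in
#' electrode rows), optionally curved (sinusoidal bow, CA-like) or V-shaped
#' (DG blade vertex at the grid midline), with optional per-column row
#' jitter. Defaults place the CA laminae SO|SP|SR|SLM (widths 6|4|10|6) or
#' the DG laminae ML|GCL|H (widths 12|6|10) centred on the 64-row grid.
#'
#' @param widths named integer vector, band widths in rows, in anatomical
#'   order (top to bottom).
#' @param startRow first row of the first band at zero offset.
#' @param shape `"straight"`, `"curved"` or `"v"`.
#' @param curveAmp bow/blade amplitude in rows (0 = straight).
#' @param jitterSd per-column Gaussian row jitter SD (0 disables).
#' @export
bandSpec <- function(widths, startRow = NULL, shape = c("straight", "curved", "v"),
                     curveAmp = 0, jitterSd = 0) {
  shape <- match.arg(shape)
  stopifnot(!is.null(names(widths)), all(widths >= 1))
  structure(list(widths = widths, startRow = startRow, shape = shape,
                 curveAmp = curveAmp, jitterSd = jitterSd),
            class = c("BandSpec", "list"))
}

#' @rdname bandSpec
#' @param network `"CA"` or `"DG"`.
#' @export
defaultBandSpec <- function(network = c("CA", "DG")) {
  network <- match.arg(network)
  if (network == "CA")
    bandSpec(c(SO = 6, SP = 4, SR = 10, SLM = 6))
  else
    bandSpec(c(ML = 12, GCL = 6, H = 10))
}

#' Generate a parametric layer map
#'
#' Assigns every electrode exactly one anatomical label (or `none`) from a
#' band specification: contiguous, non-overlapping laminae of fixed widths,
#' optionally curved or V-shaped, with optional seeded per-column jitter.
#'
#' @param network `"CA"` or `"DG"`; band names must belong to the network's
#'   laminae.
#' @param geometry a [GridGeometry-class].
#' @param spec a [bandSpec()]; defaults to [defaultBandSpec()] for the
#'   network.
#' @param seed integer seed for the jitter draw (ignored when `jitterSd = 0`).
#' @return a [LayerMap-class].
#' @examples
#' lm <- makeLayerMap("CA", gridGeometry())
#' table(layerLabels(lm))
#' @export
makeLayerMap <- function(network = c("CA", "DG"), geometry = gridGeometry(),
                         spec = NULL, seed = 1L) {
  network <- match.arg(network)
  spec <- spec %||% defaultBandSpec(network)
  admissible <- if (network == "CA") CA_LAYERS else DG_LAYERS
  if (!all(names(spec$widths) %in% admissible))
    stopf("band names must be %s layers", network)
  nr <- geometry@nRows; nc <- geometry@nCols
  total <- sum(spec$widths)
  start <- spec$startRow %||% (floor((nr - total) / 2) + 1L)
  cols <- seq_len(nc)
  offset <- switch(spec$shape,
    straight = rep(0L, nc),
    curved = round(spec$curveAmp * sin(pi * (cols - 1) / max(nc - 1, 1))),
    v = round(spec$curveAmp * abs(cols - (nc + 1) / 2) / max((nc - 1) / 2, 1)))
  if (spec$jitterSd > 0)
    offset <- offset + withLocalSeed(seed, round(stats::rnorm(nc, 0, spec$jitterSd)))
  top <- start + offset
  if (any(top < 1L) || any(top + total - 1L > nr))
    stopf("bands exceed the grid extent (rows %d..%d on a %d-row grid)",
          min(top), max(top) + total - 1L, nr)
  labels <- matrix("none", nr, nc)
  edges <- c(0L, cumsum(spec$widths))
  for (b in seq_along(spec$widths)) {
    for (cc in cols) {
      rows <- (top[cc] + edges[b]):(top[cc] + edges[b + 1L] - 1L)
      labels[rows, cc] <- names(spec$widths)[b]
    }
  }
  # row-major channel order: row varies slowest
  layerMap(as.character(t(labels)), network)
}
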