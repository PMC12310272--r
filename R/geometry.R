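#' Construct a grid geometry
#'
#' @param nRows,nCols grid extent in electrodes.
#' @param pitch inter-electrode pitch in micrometres.
#' @return a [GridGeometry-class] object.
#' @examples
#' g <- gridGeometry()            # the 64 x 64, 42 um platform default
#' head(electrodePositions(g))
#' @export
gridGeometry <- function(nRows = 64L, nCols = 64L, pitch = 42) {
  new("GridGeometry", nRows = as.integer(nRows), nCols = as.integer(nCols),
      pitch = as.numeric(pitch))
}

#' @rdname GridGeometry-class
#' @export
setMethod("nChannels", "GridGeometry", function(object) object@nRows * object@nCols)

#' Electrode coordinates of a grid geometry
#'
#' Channels are row-major: channel 1 is the top-left electrode (row 1,
#' col 1), channel `nCols` ends row 1. Coordinates are in micrometres with
#' `x = (col-1)*pitch`, `y = (row-1)*pitch`.
#'
#' @param geometry a [GridGeometry-class].
#' @return data frame with columns `channel`, `row`, `col`, `x`, `y`.
#' @export
electrodePositions <- function(geometry) {
  stopifnot(is(geometry, "GridGeometry"))
  nr <- geometry@nRows; nc <- geometry@nCols; p <- geometry@pitch
  ch <- seq_len(nr * nc)
  row <- ((ch - 1L) %/% nc) + 1L
  col <- ((ch - 1L) %% nc) + 1L
  data.frame(channel = ch, row = row, col = col,
             x = (col - 1L) * p, y = (row - 1L) * p)
}

#' Map between channel index and grid position
#'
#' @param geometry a [GridGeometry-class].
#' @param row,col grid position (1-based).
#' @return `channelIndex`: the row-major channel index; `channelPosition`:
#'   a data frame with `row` and `col` for each channel.
#' @export
channelIndex <- function(geometry, row, col) {
  stopifnot(all(row >= 1L), all(row <= geometry@nRows),
            all(col >= 1L), all(col <= geometry@nCols))
  (as.integer(row) - 1L) * geometry@nCols + as.integer(col)
}

#' @rdname channelIndex
#' @param channel channel index (1-based, row-major).
#' @export
channelPosition <- function(geometry, channel) {
  stopifnot(all(channel >= 1L), all(channel <= nChannels(geometry)))
  ch <- as.integer(channel)
  data.frame(channel = ch,
             row = ((ch - 1L) %/% geometry@nCols) + 1L,
             col = ((ch - 1L) %% geometry@nCols) + 1L)
}

setMethod("show", "GridGeometry", function(object) {
  cat(sprintf("GridGeometry: %d x %d electrodes, pitch %g um\n",
              object@nRows, object@nCols, object@pitch))
})
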