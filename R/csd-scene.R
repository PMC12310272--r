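#' Forward-model a synthetic CSD scene
#'
#' Builds a ground-truth CSD map from 2-D Gaussian blobs and computes the
#' electrode potentials by direct numerical quadrature of the homogeneous,
#' thickness-integrated forward model
#' `V(x) = (1 / 4 pi sigma) \iint b(x') w(||x - x'||; h) dx'`.
#' The quadrature is polar around each electrode (Gauss-Legendre in a
#' substituted radial variable, trapezoid in angle), which integrates the
#' logarithmic near-field weight accurately; it shares no code with the
#' kernel tabulation in [buildKernels()], so forward-modelled scenes serve
#' as an independent oracle for CSD estimation.
#'
#' @param sources data frame with columns `x`, `y` (centre, um), `width`
#'   (Gaussian SD, um) and `amplitude` (signed CSD peak); centres must lie
#'   inside the grid extent.
#' @param geometry a [GridGeometry-class] (electrode and estimation grid).
#' @param fm a [forwardModel()].
#' @param nRadial,nAngular quadrature resolution.
#' @return list: `trueCsd` (matrix \[nRows x nCols\] on the electrode grid),
#'   `potentials` (uV at the electrodes, row-major channel order),
#'   `sources`, `geometry`, `fm`.
#' @export
simulateCsdScene <- function(sources, geometry = gridGeometry(),
                             fm = forwardModel(), nRadial = 160,
                             nAngular = 128) {
  sources <- as.data.frame(sources)
  stopifnot(all(c("x", "y", "width", "amplitude") %in% names(sources)))
  if (!all(is.finite(sources$amplitude))) stopf("non-finite source amplitude")
  pos <- electrodePositions(geometry)
  xmax <- (geometry@nCols - 1) * geometry@pitch
  ymax <- (geometry@nRows - 1) * geometry@pitch
  if (any(sources$x < 0 | sources$x > xmax | sources$y < 0 | sources$y > ymax))
    stopf("source centre outside the grid extent")

  csd <- numeric(nrow(pos))
  V <- numeric(nrow(pos))
  h <- fm$thicknessUm
  theta <- (seq_len(nAngular) - 1) * 2 * pi / nAngular
  ct <- cos(theta); st <- sin(theta)
  for (s in seq_len(nrow(sources))) {
    src <- sources[s, ]
    d2 <- (pos$x - src$x)^2 + (pos$y - src$y)^2
    csd <- csd + src$amplitude * exp(-d2 / (2 * src$width^2))
    # polar quadrature centred at each electrode, u^2 = radial distance
    dMax <- sqrt(max(d2)) + 10 * src$width
    gl <- pracma::gaussLegendre(nRadial, 0, sqrt(dMax))
    r <- gl$x^2
    wq <- gl$w * 2 * gl$x                      # du -> dr Jacobian
    wt <- thicknessWeight(r, h) * r * wq        # radial weight per node
    # angular mean of the Gaussian at radius r around each electrode
    for (k in seq_len(nRadial)) {
      px <- outer(pos$x - src$x, r[k] * ct, "+")
      py <- outer(pos$y - src$y, r[k] * st, "+")
      bavg <- rowMeans(exp(-(px^2 + py^2) / (2 * src$width^2)))
      V <- V + src$amplitude * wt[k] * bavg * (2 * pi) / (4 * pi * fm$sigma)
    }
  }
  list(trueCsd = matrix(csd, geometry@nRows, geometry@nCols, byrow = TRUE),
       potentials = V, sources = sources, geometry = geometry, fm = fm)
}
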