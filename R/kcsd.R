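#' Thickness-integrated inverse-distance weight
#'
#' `w(d; h) = integral_{-h/2}^{h/2} dz / sqrt(d^2 + z^2) = 2 asinh(h / 2d)`:
#' the potential weight of a unit line of current spanning the slice
#' thickness, in the homogeneous-medium forward model.
#' @param d lateral distance, um (same units as `h`).
#' @param h slice thickness, um.
#' @export
thicknessWeight <- function(d, h) {
  2 * asinh(h / (2 * pmax(d, 1e-9)))
}

#' Radial potential profile of a Gaussian basis source
#'
#' Potential at lateral distance r from the centre of a unit-amplitude 2-D
#' Gaussian source `b(s) = exp(-s^2 / 2R^2)` spread uniformly across the
#' slice thickness, by reducing the forward quadrature to one dimension
#' (the angular integral is `2 pi I0(r s / R^2)`) and integrating with
#' `stats::integrate` to 1e-8 relative tolerance. Returns an interpolating
#' function; far from the source (distance much greater than R and h) it
#' approaches the point source `Q / (4 pi sigma r)` with `Q = 2 pi R^2 h`.
#' @noRd
basisPotentialProfile <- function(R, fm, rMax, nTab = 400) {
  h <- fm$thicknessUm
  phiAt <- function(r) {
    f <- function(s) {
      z <- r * s / R^2
      # scaled I0; asymptotic form where besselI loses accuracy
      i0 <- ifelse(z > 1e5,
                   (1 + 1 / (8 * z)) / sqrt(2 * pi * z),
                   besselI(pmin(z, 1e5), 0, expon.scaled = TRUE))
      exp(-(r - s)^2 / (2 * R^2)) * i0 * thicknessWeight(s, h) * s
    }
    lo <- max(0, r - 12 * R)     # integrand is a Gaussian bump around s = r
    up <- r + 12 * R
    (1 / (2 * fm$sigma)) *
      stats::integrate(f, lo, up, rel.tol = 1e-8, subdivisions = 400L)$value
  }
  rs <- c(seq(0, 4 * R, length.out = nTab %/% 2),
          seq(4 * R, rMax + R, length.out = nTab - nTab %/% 2 + 1)[-1])
  vals <- vapply(rs, phiAt, numeric(1))
  stats::splinefun(rs, vals, method = "natural")
}

basisGrid <- function(positions, M) {
  rx <- range(positions[, 1]); ry <- range(positions[, 2])
  gx <- if (M == 1) mean(rx) else seq(rx[1], rx[2], length.out = M)
  gy <- if (M == 1) mean(ry) else seq(ry[1], ry[2], length.out = M)
  as.matrix(expand.grid(x = gx, y = gy))
}

crossDist <- function(a, b) {
  sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
}

#' Build the kCSD kernel matrices
#'
#' Places `basisM^2` Gaussian basis sources over the electrode extent,
#' forward-models each source's potential at every electrode
#' (`phi[i, j] = phi_j(x_i)`, by quadrature of the homogeneous-medium,
#' thickness-integrated forward model), and assembles the smoothing kernel
#' `K = phi phi^T` (electrode x electrode, symmetric PSD) and cross-kernel
#' `Kcross = B phi^T` with `B[m, j] = b_j(y_m)` the basis amplitudes on the
#' estimation grid.
#'
#' @param positions numeric matrix \[electrodes x 2\], (x, y) in um.
#' @param cfg a [kcsdConfig()].
#' @param fm a [forwardModel()].
#' @param estPositions estimation-grid positions (default: the electrode
#'   positions, i.e. a map aligned with the array).
#' @param estDim `c(rows, cols)` of the estimation grid for map reshaping.
#' @return a `KcsdKernels` list: `K`, `Kcross`, `phi`, `basis`,
#'   `estPositions`, `estDim`, `cfg`, `fm`.
#' @export
buildKernels <- function(positions, cfg = kcsdConfig(), fm = forwardModel(),
                         estPositions = NULL, estDim = NULL) {
  positions <- as.matrix(positions)
  if (is.null(estPositions)) {
    estPositions <- positions
    if (is.null(estDim)) {
      n <- as.integer(round(sqrt(nrow(positions))))
      estDim <- if (n * n == nrow(positions)) c(n, n) else c(nrow(positions), 1L)
    }
  }
  estPositions <- as.matrix(estPositions)
  estDim <- estDim %||% c(nrow(estPositions), 1L)
  basis <- basisGrid(positions, cfg$basisM)
  R <- cfg$basisWidthUm
  rMax <- max(crossDist(rbind(positions, estPositions), basis))
  prof <- basisPotentialProfile(R, fm, rMax)
  dm <- crossDist(positions, basis)
  phi <- matrix(prof(dm), nrow(dm), ncol(dm))     # electrodes x basis
  B <- exp(-crossDist(estPositions, basis)^2 / (2 * R^2))
  K <- phi %*% t(phi)
  K <- (K + t(K)) / 2
  structure(list(K = K, Kcross = B %*% t(phi), phi = phi, basis = basis,
                 estPositions = estPositions, estDim = estDim,
                 kernelScale = mean(diag(K)), cfg = cfg, fm = fm),
            class = c("KcsdKernels", "list"))
}

#' Estimate current source density from electrode potentials
#'
#' Ridge-regularized kernel solution `CSD = Kcross (K + lambda I)^{-1} V`,
#' linear in `V` for fixed `lambda`. Negative values are sinks, positive
#' sources.
#'
#' @param V electrode potentials at one sample (uV), length = electrodes.
#' @param kernels a `KcsdKernels` from [buildKernels()].
#' @param lambda dimensionless ridge parameter (>= 0), applied relative to
#'   the mean diagonal of `K` so candidate grids are geometry-independent;
#'   at 0 a singular kernel raises an error suggesting `lambda > 0`.
#' @param timestamp optional sample/time tag stored in the map metadata.
#' @return a [CSDMap-class].
#' @export
estimateCsd <- function(V, kernels, lambda = NULL, timestamp = NA_real_) {
  lambda <- lambda %||% kernels$cfg$lambda
  n <- nrow(kernels$K)
  stopifnot(length(V) == n, all(is.finite(V)))
  beta <- tryCatch(
    solve(kernels$K + diag(lambda * kernels$kernelScale, n), V),
    error = function(e)
      stopf("kernel system singular at lambda = %g; use lambda > 0 (%s)",
            lambda, conditionMessage(e)))
  vals <- as.numeric(kernels$Kcross %*% beta)
  # estimation positions run x-fastest (row-major grid order)
  new("CSDMap", values = matrix(vals, kernels$estDim[1], kernels$estDim[2],
                                byrow = TRUE),
      lambda = lambda, basisWidth = kernels$cfg$basisWidthUm,
      meta = list(estPositions = kernels$estPositions,
                  sigma = kernels$fm$sigma,
                  thicknessUm = kernels$fm$thicknessUm,
                  basisM = kernels$cfg$basisM, timestamp = timestamp))
}

#' Select the ridge parameter by leave-one-electrode-out cross-validation
#'
#' For each candidate, predicts every electrode's potential from all others
#' under the kernel model (closed-form leave-one-out residuals of the ridge
#' smoother) and picks the candidate minimizing the mean squared prediction
#' error. Deterministic; a flat error curve falls back to the smallest
#' candidate.
#'
#' @param V electrode potentials.
#' @param kernels a `KcsdKernels`.
#' @param candidates candidate lambdas (default from the kernels' config).
#' @return the selected lambda, with the error curve as attribute `cv`.
#' @export
selectLambda <- function(V, kernels, candidates = NULL) {
  candidates <- sort(unique(candidates %||% kernels$cfg$lambdaCandidates))
  if (length(candidates) < 1) stopf("no lambda candidates")
  eig <- eigen(kernels$K, symmetric = TRUE)
  Q <- eig$vectors; ev <- pmax(eig$values, 0)
  Vq <- crossprod(Q, V)
  Q2 <- Q^2
  err <- vapply(candidates, function(l) {
    shrink <- ev / (ev + l * kernels$kernelScale)
    resid <- as.numeric(Q %*% ((1 - shrink) * Vq))
    hdiag <- as.numeric(Q2 %*% shrink)
    mean((resid / pmax(1 - hdiag, 1e-12))^2)
  }, numeric(1))
  rel <- diff(range(err)) / max(abs(err), 1e-300)
  sel <- if (!is.finite(rel) || rel < 1e-10) {
    message("flat cross-validation curve; using smallest candidate")
    candidates[1]
  } else candidates[which.min(err)]
  attr(sel, "cv") <- data.frame(lambda = candidates, looError = err)
  sel
}

# 4-connected component labelling of a logical matrix (flood fill)
labelComponents4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      i <- queue[length(queue)]; queue <- queue[-length(queue)]
      r <- ((i - 1L) %% nr) + 1L; cc <- ((i - 1L) %/% nr) + 1L
      for (nb in list(c(r - 1L, cc), c(r + 1L, cc), c(r, cc - 1L), c(r, cc + 1L))) {
        if (nb[1] >= 1L && nb[1] <= nr && nb[2] >= 1L && nb[2] <= nc) {
          j <- (nb[2] - 1L) * nr + nb[1]
          if (mask[j] && lab[j] == 0L) { lab[j] <- cur; queue <- c(queue, j) }
        }
      }
    }
  }
  lab
}

#' Count and integrate sinks and sources in a spatial map
#'
#' Thresholds the map at `thresholdFraction` of its maximum absolute value;
#' sinks are 4-connected components below the negative threshold, sources
#' components above the positive threshold. Integrated magnitudes are the
#' sums of values over each region times the grid cell area.
#'
#' @param map a [CSDMap-class] or numeric matrix (e.g. a potential map).
#' @param thresholdFraction threshold as a fraction of `max(abs(map))`,
#'   in (0, 1).
#' @param cellArea grid cell area (um^2) for the integrals (default 1).
#' @return list: `nSinks`, `nSources`, `sinkIntegral` (<= 0),
#'   `sourceIntegral` (>= 0), `sinkRegions`, `sourceRegions` (per-region
#'   integrals), `threshold`.
#' @export
quantifySinksSources <- function(map, thresholdFraction = 0.3, cellArea = 1) {
  if (is(map, "CSDMap")) map <- csdValues(map)
  stopifnot(thresholdFraction > 0, thresholdFraction < 1)
  mx <- max(abs(map))
  if (mx == 0)
    return(list(nSinks = 0L, nSources = 0L, sinkIntegral = 0,
                sourceIntegral = 0, sinkRegions = numeric(0),
                sourceRegions = numeric(0), threshold = 0))
  thr <- thresholdFraction * mx
  labNeg <- labelComponents4(map < -thr)
  labPos <- labelComponents4(map > thr)
  regInt <- function(lab) {
    k <- max(lab)
    if (k == 0L) return(numeric(0))
    vapply(seq_len(k), function(i) sum(map[lab == i]) * cellArea, numeric(1))
  }
  sinks <- regInt(labNeg); sources <- regInt(labPos)
  list(nSinks = max(labNeg), nSources = max(labPos),
       sinkIntegral = sum(sinks), sourceIntegral = sum(sources),
       sinkRegions = sinks, sourceRegions = sources, threshold = thr)
}

#' Interpolated potential map on an estimation grid
#'
#' Bilinear interpolation of per-electrode potentials onto a regular
#' estimation grid; the comparison baseline for [quantifySinksSources()].
#' At electrode locations the map equals `V` exactly.
#'
#' @param V electrode potentials (length = electrodes of `geometry`).
#' @param geometry a [GridGeometry-class].
#' @param estRows,estCols estimation grid extent (default: the electrode
#'   grid itself).
#' @return numeric matrix \[estRows x estCols\].
#' @export
potentialMap <- function(V, geometry, estRows = NULL, estCols = NULL) {
  stopifnot(all(is.finite(V)), length(V) == nChannels(geometry))
  nr <- geometry@nRows; nc <- geometry@nCols
  estRows <- estRows %||% nr; estCols <- estCols %||% nc
  Vm <- matrix(V, nr, nc, byrow = TRUE)   # row-major channel order
  if (estRows == nr && estCols == nc) return(Vm)
  p <- geometry@pitch
  xs <- (seq_len(nc) - 1) * p; ys <- (seq_len(nr) - 1) * p
  xe <- seq(0, max(xs), length.out = estCols)
  ye <- seq(0, max(ys), length.out = estRows)
  grid <- expand.grid(x = xe, y = ye)
  vals <- pracma::interp2(xs, ys, Vm, grid$x, grid$y, method = "linear")
  matrix(vals, estRows, estCols, byrow = TRUE)
}
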