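# shared small-geometry kernels (built once; reused across blocks)
kcsdFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- gridGeometry(16, 16)
      pos <- as.matrix(electrodePositions(g)[, c("x", "y")])
      kern <- buildKernels(pos, kcsdConfig(basisM = 16, basisWidthUm = 84),
                          forwardModel())
      cache <<- list(g = g, pos = pos, kern = kern)
    }
    cache
  }
})

test_that("kernel matrices are symmetric and respect radial symmetry", {
  fx <- kcsdFixture()
  K <- fx$kern$K
  expect_lt(max(abs(K - t(K))), 1e-10)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev) / max(ev), -1e-10)            # PSD up to roundoff
  # single basis source: equidistant electrodes see equal potentials
  one <- buildKernels(fx$pos, kcsdConfig(basisM = 1, basisWidthUm = 84),
                      forwardModel())
  ctr <- colMeans(fx$pos)
  d <- sqrt((fx$pos[, 1] - ctr[1])^2 + (fx$pos[, 2] - ctr[2])^2)
  grp <- split(one$phi[, 1], round(d, 6))
  expect_true(all(vapply(grp, function(v) diff(range(v)) < 1e-8 * max(abs(v)),
                         logical(1))))
})

test_that("the basis potential approaches the point source in the far field", {
  fm <- forwardModel()
  R <- 84
  prof <- netLTP:::basisPotentialProfile(R, fm, 2.5e4)
  Q <- 2 * pi * R^2 * fm$thicknessUm
  for (r in c(8000, 15000, 20000)) {
    expect_equal(prof(r), Q / (4 * pi * fm$sigma * r), tolerance = 0.01)
  }
})

test_that("CSD estimation is linear and zero on zero potentials", {
  fx <- kcsdFixture()
  z <- estimateCsd(numeric(256), fx$kern, 1e-6)
  expect_true(all(csdValues(z) == 0))
  set.seed(1)
  V <- rnorm(256)
  m1 <- csdValues(estimateCsd(V, fx$kern, 1e-4))
  m3 <- csdValues(estimateCsd(3 * V, fx$kern, 1e-4))
  expect_equal(m3, 3 * m1, tolerance = 1e-9)
})

test_that("forward-modelled single sources are localized at selected lambda", {
  fx <- kcsdFixture()
  pitch <- 42
  set.seed(21)
  errNF <- errN <- numeric(6)
  for (i in seq_along(errNF)) {
    ctr <- runif(2, 4 * pitch, 11 * pitch)
    amp <- sample(c(-1, 1), 1)
    sc <- simulateCsdScene(data.frame(x = ctr[1], y = ctr[2], width = 70,
                                      amplitude = amp), fx$g, forwardModel())
    locate <- function(V) {
      lam <- as.numeric(selectLambda(V, fx$kern))
      m <- csdValues(estimateCsd(V, fx$kern, lam))
      ix <- which(abs(m) == max(abs(m)), arr.ind = TRUE)[1, ]
      expect_equal(sign(m[ix[1], ix[2]]), amp)
      sqrt(sum((c((ix[2] - 1) * pitch, (ix[1] - 1) * pitch) - ctr)^2))
    }
    errNF[i] <- locate(sc$potentials)
    Vn <- sc$potentials + rnorm(256, 0, max(abs(sc$potentials)) / 10)
    errN[i] <- locate(Vn)
  }
  expect_lte(max(errNF), pitch)
  expect_lte(max(errN), 2 * pitch)
})

test_that("leave-one-out selection reacts to the signal-to-noise regime", {
  fx <- kcsdFixture()
  cands <- 10^seq(-8, 0)
  sc <- simulateCsdScene(data.frame(x = 300, y = 300, width = 70,
                                    amplitude = 1), fx$g, forwardModel())
  lamClean <- as.numeric(selectLambda(sc$potentials, fx$kern, cands))
  expect_lte(lamClean, 1e-6)                    # at/near the smallest
  set.seed(4)
  lamNoise <- as.numeric(selectLambda(rnorm(256), fx$kern, cands))
  expect_gte(lamNoise, 1e-2)                    # at/near the largest
  expect_equal(as.numeric(selectLambda(sc$potentials, fx$kern,
                                       c(1e-3, 1e-3))), 1e-3)
})

test_that("map smoothing energy is non-increasing in lambda", {
  fx <- kcsdFixture()
  sc <- simulateCsdScene(data.frame(x = 280, y = 320, width = 70,
                                    amplitude = 1), fx$g, forwardModel())
  energies <- sapply(10^seq(-8, 0), function(l)
    sum(csdValues(estimateCsd(sc$potentials, fx$kern, l))^2))
  expect_true(all(diff(energies) <= 1e-9 * energies[1]))
})

test_that("sink/source quantification counts 4-connected regions", {
  g <- expand.grid(r = 1:21, c = 1:21)
  blob <- function(r0, c0, s) matrix(exp(-((g$r - r0)^2 + (g$c - c0)^2) / (2 * s^2)),
                                     21, 21)
  one <- blob(11, 11, 2)
  q1 <- quantifySinksSources(one, 0.3)
  expect_equal(c(q1$nSinks, q1$nSources), c(0L, 1L))
  dip <- blob(11, 6, 2) - blob(11, 16, 2)
  q2 <- quantifySinksSources(dip, 0.3, cellArea = 4)
  expect_equal(c(q2$nSinks, q2$nSources), c(1L, 1L))
  expect_equal(abs(q2$sinkIntegral), q2$sourceIntegral,
               tolerance = 0.01 * q2$sourceIntegral)
  qz <- quantifySinksSources(matrix(0, 5, 5), 0.3)
  expect_identical(c(qz$nSinks, qz$nSources), c(0L, 0L))
  expect_identical(qz$sinkIntegral + qz$sourceIntegral, 0)
  # diagonal neighbours are NOT connected under 4-connectivity
  diagm <- matrix(0, 4, 4); diagm[1, 1] <- 1; diagm[2, 2] <- 1
  expect_equal(quantifySinksSources(diagm, 0.3)$nSources, 2L)
})

test_that("potential maps interpolate bilinearly and match V at electrodes", {
  g2 <- gridGeometry(2, 2)
  V <- c(1, 3, 5, 7)
  pm <- potentialMap(V, g2, estRows = 3, estCols = 3)
  expect_equal(pm[2, 2], mean(V))               # centre = mean of corners
  expect_equal(c(pm[1, 1], pm[1, 3], pm[3, 1], pm[3, 3]), V)
  expect_equal(potentialMap(rep(2, 4), g2, 5, 5), matrix(2, 5, 5))
  # identity on the electrode grid itself
  g3 <- gridGeometry(3, 3)
  V9 <- 1:9
  expect_equal(as.numeric(t(potentialMap(V9, g3))), V9)
})

test_that("kCSD separates nearby sources that merge in the potential map", {
  fx <- kcsdFixture()
  kern <- buildKernels(fx$pos, kcsdConfig(basisM = 16, basisWidthUm = 63),
                       forwardModel())
  sep <- 210
  sc <- simulateCsdScene(data.frame(x = 315 + c(-sep / 2, sep / 2),
                                    y = c(315, 315), width = c(42, 42),
                                    amplitude = c(-1, -1)), fx$g, forwardModel())
  qPot <- quantifySinksSources(potentialMap(sc$potentials, fx$g), 0.3)
  lam <- as.numeric(selectLambda(sc$potentials, kern))
  qCsd <- quantifySinksSources(estimateCsd(sc$potentials, kern, lam), 0.3)
  expect_equal(qPot$nSinks, 1L)                  # merged in the potential map
  expect_equal(qCsd$nSinks, 2L)                  # resolved by kCSD
})
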