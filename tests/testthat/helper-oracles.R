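# Independent oracles used across the suite.

# Exact optimal 1-D k-partition (minimum within-cluster SSE) by dynamic
# programming over contiguous segments of the sorted values; optimal 1-D
# clusters are contiguous in sorted order.
oracle1DPartition <- function(x, k) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  segCost <- function(i, j) {            # cost of xs[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  cost <- matrix(Inf, k, n)
  cut <- matrix(0L, k, n)
  for (j in 1:n) cost[1, j] <- segCost(1, j)
  if (k > 1) for (m in 2:k) for (j in m:n) {
    for (i in m:j) {
      c <- cost[m - 1, i - 1] + segCost(i, j)
      if (c < cost[m, j] - 1e-12) { cost[m, j] <- c; cut[m, j] <- i }
    }
  }
  # backtrack
  lab <- integer(n)
  j <- n
  for (m in k:1) {
    i <- if (m == 1) 1L else cut[m, j]
    lab[i:j] <- m
    j <- i - 1L
  }
  out <- integer(n)
  out[ord] <- lab
  list(membership = out, sse = cost[k, n])
}

withinSse <- function(x, membership) {
  sum(vapply(split(x, membership), function(v) sum((v - mean(v))^2), numeric(1)))
}

# Brute-force two-sample KS statistic from explicit ECDFs.
bruteKsD <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  Fa <- vapply(xs, function(x) mean(a <= x), numeric(1))
  Fb <- vapply(xs, function(x) mean(b <= x), numeric(1))
  max(abs(Fa - Fb))
}

# Closed-form magnitude response of the analog Butterworth band-pass
# prototype mapped through the bilinear transform with pre-warping.
analyticBandpassGain <- function(f, order, low, high, rate) {
  fs2 <- 2 * rate
  w1 <- fs2 * tan(pi * low / rate)
  w2 <- fs2 * tan(pi * high / rate)
  w0 <- sqrt(w1 * w2); B <- w2 - w1
  w <- fs2 * tan(pi * f / rate)
  Om <- (w^2 - w0^2) / (B * w)
  1 / sqrt(1 + Om^(2 * order))
}

# Closed-form peak time of the difference-of-exponentials EPSP.
epspPeakTimeClosedForm <- function(rise, decay) {
  log(decay / rise) * rise * decay / (decay - rise)
}
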