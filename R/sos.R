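#' Butterworth band-pass design as second-order sections
#'
#' Designs the digital Butterworth band-pass analytically (analog prototype
#' poles, band transform, bilinear transform with pre-warping) and returns
#' cascaded biquad sections. A direct transfer-function (b, a) realization of
#' this filter is numerically unusable at the default band (1-500 Hz at
#' 14 kHz puts order-8 polynomial roots too close to the unit circle); the
#' cascade keeps every section individually stable.
#'
#' Gain is normalized to exactly 1 at the geometric mid-band
#' `sqrt(low * high)`.
#'
#' @param order prototype order (the band-pass has `2 * order` poles).
#' @param low,high band edges, Hz.
#' @param rate sampling rate, Hz.
#' @return numeric matrix \[order x 6\]: columns `b0 b1 b2 a0 a1 a2`.
#' @export
butterworthSos <- function(order, low, high, rate) {
  if (!(0 < low && low < high && high < rate / 2))
    stopf("need 0 < low < high < rate/2")
  n <- as.integer(order)
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k - 1 + n) / (2 * n))   # Re < 0
  fs2 <- 2 * rate
  w1 <- fs2 * tan(pi * low / rate)
  w2 <- fs2 * tan(pi * high / rate)
  w0 <- sqrt(w1 * w2); B <- w2 - w1
  # band transform: each prototype pole yields two analog poles
  sp <- c(vapply(proto, function(p) {
    d <- sqrt((B * p)^2 - 4 * w0^2)
    (B * p + d) / 2
  }, complex(1)), vapply(proto, function(p) {
    d <- sqrt((B * p)^2 - 4 * w0^2)
    (B * p - d) / 2
  }, complex(1)))
  zd <- (fs2 + sp) / (fs2 - sp)                       # bilinear
  # pair conjugates into sections (take poles with positive imaginary part)
  up <- zd[Im(zd) > 0]
  if (length(up) != n) {       # degenerate real poles: pair by sorting
    re <- sort(Re(zd[abs(Im(zd)) < 1e-12]))
    up <- c(zd[Im(zd) > 1e-12],
            complex(real = re[seq(1, length(re), by = 2)], imaginary = 0))
  }
  sos <- t(vapply(up, function(z)
    c(1, 0, -1, 1, -2 * Re(z), Re(z * Conj(z))), numeric(6)))
  # normalize to unit gain at the geometric mid-band
  wc <- 2 * pi * sqrt(low * high) / rate
  zc <- exp(1i * wc)
  H <- prod(apply(sos, 1, function(s)
    (s[1] + s[2] / zc + s[3] / zc^2) / (s[4] + s[5] / zc + s[6] / zc^2)))
  g <- (1 / Mod(H))^(1 / n)
  sos[, 1:3] <- sos[, 1:3] * g
  sos
}

#' Magnitude response of a second-order-section cascade
#'
#' @param sos section matrix from [butterworthSos()].
#' @param freq frequencies, Hz.
#' @param rate sampling rate, Hz.
#' @return `|H(f)|` of a single (one-way) pass.
#' @export
sosGain <- function(sos, freq, rate) {
  vapply(freq, function(f) {
    z <- exp(1i * 2 * pi * f / rate)
    Mod(prod(apply(sos, 1, function(s)
      (s[1] + s[2] / z + s[3] / z^2) / (s[4] + s[5] / z + s[6] / z^2))))
  }, numeric(1))
}
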