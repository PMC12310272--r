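#' Continuous evaluator for a waveform template
#'
#' Returns a vectorized function of time (ms since template onset) that is
#' exactly zero for negative times and whose global extremum equals the
#' template amplitude. The normalization constant is computed once on a fine
#' grid (0.002 ms) spanning eight decay constants.
#' @noRd
makeTemplateFun <- function(template) {
  r <- template$riseTau; d <- template$decayTau
  if (template$amplitude == 0) return(function(tMs) numeric(length(tMs)) * 0 + 0 * tMs)
  peak <- log(d / r) * r * d / (d - r)
  m <- exp(-peak / d) - exp(-peak / r)
  shape <- function(t) ifelse(t > 0, (exp(-t / d) - exp(-t / r)) / m, 0)
  raw <- switch(template$kind,
    EPSP = shape,
    PS = {
      w <- template$psWidthMs / 4
      tc <- 0.6 * peak
      g <- template$psGain
      function(t) {
        u <- (t - tc) / w
        ifelse(t > 0, shape(t) + g * u * exp(-u^2 / 2) / exp(-0.5), 0)
      }
    },
    multiphasic = {
      delay <- 0.8 * d
      function(t) shape(t) - 0.6 * shape(t - delay)
    })
  tt <- seq(0, 8 * d, by = 0.002)
  v <- raw(tt)
  i <- which.max(abs(v))
  scale <- template$amplitude / v[i]
  attr1 <- tt[i]
  f <- function(tMs) scale * raw(tMs)
  attr(f, "peakMs") <- attr1
  f
}

#' Peak time of a waveform template
#'
#' Time (ms from template onset) of the global absolute extremum, located
#' numerically on a fine grid. For a pure EPSP this matches the closed form
#' `log(decayTau/riseTau) * riseTau * decayTau / (decayTau - riseTau)`.
#'
#' @param template a [waveformTemplate()].
#' @export
templatePeakTime <- function(template) {
  attr(makeTemplateFun(template), "peakMs")
}

#' Sample a waveform template
#'
#' @param template a [waveformTemplate()].
#' @param rate sampling rate, Hz.
#' @param windowMs window length, ms; must cover at least five decay
#'   constants so the rendered extremum is within 0.1% of `amplitude`.
#' @return numeric vector of voltages (uV) at times `0, 1/rate, ...` up to
#'   `windowMs`; zero at t = 0, extremum equal to `amplitude`.
#' @examples
#' w <- renderTemplate(waveformTemplate("EPSP", -120, 2, 12), 14000, 100)
#' min(w)   # -120 uV at ~4.3 ms
#' @export
renderTemplate <- function(template, rate = 14000, windowMs = 100) {
  if (windowMs < 5 * template$decayTau)
    stopf("window (%g ms) must cover >= 5 decay constants (%g ms)",
          windowMs, 5 * template$decayTau)
  f <- makeTemplateFun(template)
  tMs <- seq(0, windowMs, by = 1000 / rate)
  f(tMs)
}
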