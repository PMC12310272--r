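#' @useDynLib netLTP, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package functions that need
#' reproducible draws do not disturb the caller's RNG stream.
#' @noRd
withLocalSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Deterministic Gaussian deviates from a scalar seed
#'
#' Uses the package's compiled generator (xoshiro256++ with a polar
#' Box-Muller transform), so synthetic voltages are bit-reproducible
#' independently of R's RNG state.
#' @noRd
gaussNoise <- function(n, seed) {
  stopifnot(n >= 0, is.finite(seed))
  if (n == 0) return(numeric(0))
  .cpp_rnorm(as.double(n), as.double(seed))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assertScalarNum <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a finite numeric scalar", name)
  if (x < lower || x > upper)
    stopf("'%s' = %g outside admissible range [%g, %g]", name, x, lower, upper)
  invisible(as.numeric(x))
}
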