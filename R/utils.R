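# Internal helpers shared across modules.

#' Derive a child RNG seed from a base seed and a counter
#'
#' All generators in the package draw their randomness from a single integer
#' seed per object (scene, track, model). Sub-components receive independent
#' streams through this counter-based split, so adding or removing one event
#' never perturbs the noise of another.
#'
#' @param seed base integer seed.
#' @param counter non-negative integer stream index.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, counter) {
  # affine map modulo a Mersenne prime; keeps results within 32-bit range
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(counter) * 1000003
  as.integer(s %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Root-mean-square amplitude
#'
#' @param x numeric vector of samples.
#' @return RMS of `x` (0 for an empty vector).
#' @export
rms <- function(x) {
  if (length(x) == 0) return(0)
  sqrt(mean(x^2))
}

# dBFS conventions: levels are RMS relative to full scale 1.0
dbfs_to_amp <- function(db) 10^(db / 20)

amp_to_dbfs <- function(a) 20 * log10(a)

#' Round half away from zero
#'
#' R's `round()` rounds half to even; printed percentages in reports use the
#' conventional half-up rule instead.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x)

# FFT convolution, full ("open") length, padded to a fast composite size
fft_conv <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nf <- stats::nextn(n, c(2L, 3L, 5L))
  xf <- stats::fft(c(x, numeric(nf - length(x))))
  hf <- stats::fft(c(h, numeric(nf - length(h))))
  Re(stats::fft(xf * hf, inverse = TRUE))[seq_len(n)] / nf
}
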