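# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All exported stochastic functions
# take an explicit seed and go through this, so package calls never perturb
# the user's RNG stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic small-integer sub-seed derivation, kept inside 32-bit range.
derive_seed <- function(seed, ...) {
  offs <- c(...)
  s <- (as.double(seed) + sum(as.double(offs) * seq_along(offs) * 9973)) %% 2147483629
  as.integer(s) + 1L
}

#' Gaussian noise band-limited by FFT masking
#'
#' Generates zero-mean Gaussian noise whose power is confined to a frequency
#' band, by masking the discrete Fourier transform of white noise with a
#' raised-cosine-edged band mask. Used for spontaneous blood-pressure
#' variability in the synthetic generator and for coherence null surrogates.
#'
#' @param n number of samples.
#' @param rate sampling rate, samples/s.
#' @param band numeric length-2, pass band in Hz.
#' @param sd target standard deviation of the output.
#' @param shape `"flat"` for white-within-band, `"one_over_f"` for power
#'   density proportional to 1/f inside the band.
#' @param edge_hz width of the raised-cosine transition at each band edge.
#' @return numeric vector of length `n`.
#' @export
band_limited_noise <- function(n, rate, band = c(0.02, 0.45), sd = 1,
                               shape = c("flat", "one_over_f"),
                               edge_hz = 0.01) {
  shape <- match.arg(shape)
  x <- stats::rnorm(n)
  f <- seq(0, rate, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, rate - f) # two-sided frequency magnitude
  mask <- rep(0, n)
  lo <- band[1]; hi <- band[2]
  inb <- f >= lo & f <= hi
  mask[inb] <- 1
  rise <- f > (lo - edge_hz) & f < lo
  mask[rise] <- 0.5 * (1 - cos(pi * (f[rise] - lo + edge_hz) / edge_hz))
  fall <- f > hi & f < (hi + edge_hz)
  mask[fall] <- 0.5 * (1 + cos(pi * (f[fall] - hi) / edge_hz))
  if (shape == "one_over_f") {
    w <- mask > 0
    mask[w] <- mask[w] / sqrt(pmax(f[w], lo / 2))
  }
  X <- stats::fft(x) * mask
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y <- y * (sd / s)
  y - mean(y)
}

# Index range of a half-open time window [from, to) on a time axis.
window_index <- function(time_s, from, to) {
  which(time_s >= from - 1e-9 & time_s < to - 1e-9)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
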