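# Welch cross-spectral transfer function analysis between mean arterial
# pressure (input) and cerebral blood velocity (output), coherence
# confidence limits, and impulse/step response derivation.

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

#' Welch transfer function analysis
#'
#' Estimates gain, phase and magnitude-squared coherence between an input
#' and an output series by Welch's method: the series are split into
#' `segment_samples`-long segments with fractional overlap, each segment is
#' mean-detrended and multiplied by a raised-cosine (Hann) taper, and the
#' auto- and cross-spectra are averaged across segments. Power spectra are
#' window-power normalized (unbiased for white noise).
#'
#' @param x input series (pressure).
#' @param y output series (velocity), same length as `x`.
#' @param rate sampling rate, samples/s.
#' @param segment_samples segment length in samples (256 for 3-min task
#'   recordings, 512 for baseline recordings).
#' @param overlap_fraction fractional segment overlap (0.5 standard).
#' @param window taper; only `"hann"` (the full raised cosine) is provided.
#' @param detrend remove each segment's mean before tapering.
#' @return object of class `spectral_estimate`: list with `freqs_hz`,
#'   `gain`, `phase_rad`, `coherence`, `n_windows`, `input_psd`,
#'   `output_psd`, `cross_spectrum` (complex), and `settings`.
#' @export
welch_tfa <- function(x, y, rate = 5, segment_samples = 256,
                      overlap_fraction = 0.5, window = "hann",
                      detrend = TRUE) {
  n <- length(x)
  stopifnot(length(y) == n, segment_samples >= 8,
            overlap_fraction >= 0, overlap_fraction < 1)
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values in input series")
  if (n < segment_samples) stop("series shorter than one segment")
  window <- match.arg(window, "hann")
  L <- as.integer(segment_samples)
  hop <- max(1L, as.integer(round(L * (1 - overlap_fraction))))
  starts <- seq(1L, n - L + 1L, by = hop)
  w <- hann_window(L)
  U <- mean(w^2) # window power for PSD normalization
  sxx <- syy <- numeric(L)
  sxy <- complex(L)
  for (s in starts) {
    xi <- x[s:(s + L - 1L)]
    yi <- y[s:(s + L - 1L)]
    if (detrend) {
      xi <- xi - mean(xi)
      yi <- yi - mean(yi)
    }
    X <- stats::fft(xi * w)
    Y <- stats::fft(yi * w)
    sxx <- sxx + Mod(X)^2
    syy <- syy + Mod(Y)^2
    sxy <- sxy + Conj(X) * Y
  }
  nw <- length(starts)
  scale <- 1 / (nw * rate * L * U)
  sxx <- sxx * scale; syy <- syy * scale; sxy <- sxy * scale
  nf <- L %/% 2L + 1L
  keep <- seq_len(nf)
  sxx <- sxx[keep]; syy <- syy[keep]; sxy <- sxy[keep]
  # one-sided spectra: double the interior bins
  dbl <- 2:(nf - 1L)
  sxx[dbl] <- 2 * sxx[dbl]; syy[dbl] <- 2 * syy[dbl]; sxy[dbl] <- 2 * sxy[dbl]
  gain <- Mod(sxy) / sxx
  phase <- Arg(sxy)
  coh <- pmin(1, Mod(sxy)^2 / (sxx * syy))
  structure(list(
    freqs_hz = (keep - 1L) * rate / L,
    gain = gain,
    phase_rad = phase,
    coherence = coh,
    n_windows = nw,
    input_psd = sxx,
    output_psd = syy,
    cross_spectrum = sxy,
    settings = list(rate = rate, segment_samples = L,
                    overlap_fraction = overlap_fraction, window = window,
                    n_samples = n)
  ), class = "spectral_estimate")
}

#' Band-averaged coherence
#'
#' Mean magnitude-squared coherence over a frequency band (0.15-0.25 Hz for
#' the ARI acceptance gate).
#'
#' @param spec a `spectral_estimate`.
#' @param band numeric length-2 band in Hz (inclusive).
#' @return scalar in \[0, 1\].
#' @export
band_mean_coherence <- function(spec, band = c(0.15, 0.25)) {
  i <- which(spec$freqs_hz >= band[1] - 1e-9 & spec$freqs_hz <= band[2] + 1e-9)
  if (!length(i)) stop("no frequency bins inside the band")
  mean(spec$coherence[i])
}

#' Closed-form coherence confidence limit for independent windows
#'
#' The (1 - alpha) quantile of estimated magnitude-squared coherence between
#' independent Gaussian signals averaged over `n_windows` *non-overlapping*
#' windows: `1 - alpha^(1/(n_windows - 1))`.
#'
#' @param n_windows number of averaged windows (>= 2).
#' @param alpha significance level.
#' @return limit in \[0, 1\].
#' @export
coherence_limit_analytic <- function(n_windows, alpha = 0.05) {
  stopifnot(n_windows >= 2)
  1 - alpha^(1 / (n_windows - 1))
}

# cache for Monte-Carlo limits (keyed on all calibration parameters)
.limit_cache <- new.env(parent = emptyenv())

#' Coherence 95% confidence limit
#'
#' Threshold above which band-averaged coherence is distinguishable from
#' zero. Two estimators: the closed form for `L` non-overlapping windows
#' (`method = "analytic"`), and a seeded Monte-Carlo surrogate calibration
#' (`method = "mc"`, default) that honours overlapping segments — it
#' generates independent band-limited Gaussian noise pairs of the actual
#' record length, runs [welch_tfa()] with the same settings, and returns the
#' (1 - alpha) quantile of the band-mean coherence. Monte-Carlo results are
#' cached per parameter set.
#'
#' @param n_samples record length in samples (required for `"mc"`).
#' @param rate sampling rate, samples/s.
#' @param segment_samples,overlap_fraction Welch settings being calibrated.
#' @param alpha significance level (0.05 standard).
#' @param band frequency band (Hz) over which coherence is averaged.
#' @param method `"mc"` or `"analytic"`.
#' @param n_windows number of windows (required for `"analytic"`; ignored
#'   otherwise).
#' @param n_surrogate number of Monte-Carlo surrogate pairs.
#' @param seed RNG seed for the surrogate draw.
#' @param noise_band band (Hz) of the surrogate noise.
#' @return limit in \[0, 1\].
#' @export
coherence_limit <- function(n_samples = NULL, rate = 5, segment_samples = 256,
                            overlap_fraction = 0.5, alpha = 0.05,
                            band = c(0.15, 0.25), method = c("mc", "analytic"),
                            n_windows = NULL, n_surrogate = 1000, seed = 1L,
                            noise_band = c(0.02, 0.45)) {
  method <- match.arg(method)
  if (method == "analytic") {
    if (is.null(n_windows)) stop("n_windows required for the analytic limit")
    return(coherence_limit_analytic(n_windows, alpha))
  }
  if (is.null(n_samples)) stop("n_samples required for Monte-Carlo calibration")
  key <- paste(n_samples, rate, segment_samples, overlap_fraction, alpha,
               paste(band, collapse = "-"), n_surrogate, seed,
               paste(noise_band, collapse = "-"), sep = "|")
  hit <- .limit_cache[[key]]
  if (!is.null(hit)) return(hit)
  vals <- with_seed(seed, {
    vapply(seq_len(n_surrogate), function(i) {
      a <- band_limited_noise(n_samples, rate, noise_band)
      b <- band_limited_noise(n_samples, rate, noise_band)
      sp <- welch_tfa(a, b, rate = rate, segment_samples = segment_samples,
                      overlap_fraction = overlap_fraction)
      band_mean_coherence(sp, band)
    }, numeric(1))
  })
  lim <- unname(stats::quantile(vals, probs = 1 - alpha, type = 7))
  .limit_cache[[key]] <- lim
  lim
}

#' Impulse response from a spectral estimate
#'
#' Real-valued inverse FFT of the complex frequency response
#' `H(f) = gain * exp(i * phase)`. The unestimable DC bin is set to the
#' nearest estimated low-frequency gain (zero phase) and Hermitian symmetry
#' is enforced before the inverse transform, so the impulse response is
#' real by construction.
#'
#' @param spec a `spectral_estimate` covering DC to Nyquist.
#' @return list with `lag_s` and `h` (impulse response), class
#'   `impulse_response`.
#' @export
impulse_response <- function(spec) {
  nf <- length(spec$freqs_hz)
  L <- spec$settings$segment_samples
  stopifnot(nf == L %/% 2 + 1)
  H <- spec$gain * exp(1i * spec$phase_rad)
  H[1] <- spec$gain[2] # DC: carry the lowest estimated gain, zero phase
  H[nf] <- Re(H[nf])   # Nyquist bin must be real
  full <- c(H, Conj(rev(H[2:(nf - 1L)])))
  h <- Re(stats::fft(full, inverse = TRUE)) / L
  sym_err <- max(Mod(Im(stats::fft(full, inverse = TRUE)) / L))
  if (sym_err > 1e-8) stop("internal error: non-Hermitian frequency response")
  structure(list(lag_s = (seq_len(L) - 1) / spec$settings$rate, h = h),
            class = "impulse_response")
}

#' Step response by running integration of the impulse response
#'
#' Cumulative sum of the impulse response: the normalized velocity response
#' to a sustained unit pressure step, on the same 0.2 s lag grid (at the
#' standard 5 samples/s).
#'
#' @param impulse an `impulse_response`.
#' @return object of class `step_response`: list with `time_s`, `response`.
#' @export
step_response <- function(impulse) {
  stopifnot(all(is.finite(impulse$h)))
  structure(list(time_s = impulse$lag_s, response = cumsum(impulse$h)),
            class = "step_response")
}
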