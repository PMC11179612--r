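# Second-order autoregulation model (Tiecks), template generation and
# ARI assignment by best fit of the measured step response.

#' Tiecks model parameter table
#'
#' Returns the canonical (T, D, K) parameter triplets of the second-order
#' dynamic cerebral autoregulation model, one row per Autoregulation Index
#' grade 0-9 (T: time constant in seconds, D: damping factor, K:
#' autoregulatory gain). The table is shipped as a plain-text data file and
#' validated on load: 10 complete grades, K non-decreasing from 0 (absent
#' autoregulation) towards 1.
#'
#' @return data.frame with columns `ari`, `T`, `D`, `K`.
#' @export
tiecks_param_table <- function() {
  path <- system.file("extdata", "tiecks_parameters.csv", package = "cadenza")
  tab <- utils::read.csv(path, comment.char = "#")
  stopifnot(
    identical(tab$ari, 0:9),
    all(tab$T > 0), all(tab$D >= 0),
    all(tab$K >= 0), all(tab$K <= 1),
    tab$K[1] == 0, !is.unsorted(tab$K)
  )
  tab
}

# Core state recursion: response of the normalized velocity deviation
# (dP - K*x2) to a normalized pressure deviation series dP, at sampling
# frequency f. Explicit Euler as in the original model; an internal
# oversampling factor keeps f*T well away from the stability margin for the
# fastest time constants.
tiecks_filter <- function(dp, f, T, D, K, oversample = NULL) {
  if (is.null(oversample)) {
    oversample <- if (f * T < 5) ceiling(5 / (f * T)) else 1L
  }
  if (f * T * oversample <= 1) {
    stop("unstable discretization: f*T <= 1; raise the internal oversampling factor")
  }
  if (oversample > 1L) {
    n <- length(dp)
    # sample-and-hold upsampling preserves step inputs exactly
    dpo <- rep(dp, each = oversample)
    fo <- f * oversample
  } else {
    dpo <- dp
    fo <- f
  }
  ft <- fo * T
  x1 <- 0; x2 <- 0
  out <- numeric(length(dpo))
  for (i in seq_along(dpo)) {
    x2new <- x2 + (x1 - 2 * D * x2) / ft
    x1 <- x1 + (dpo[i] - x2) / ft
    x2 <- x2new
    out[i] <- dpo[i] - K * x2
  }
  if (oversample > 1L) out <- out[seq(oversample, length(dpo), by = oversample)]
  out
}

#' Forward-simulate the Tiecks autoregulation model
#'
#' Computes the cerebral blood velocity response to a mean arterial pressure
#' series under the second-order autoregulation model. Pressure is
#' normalized as `dP = (MAP - MAP_base) / (MAP_base - crcp)` and the
#' velocity is `V = v0 * (1 + dP - K * x2)` where `x2` follows the model's
#' damped second-order state recursion (states start at rest).
#'
#' @param map_mmHg mean arterial pressure series, mmHg.
#' @param rate sampling rate of `map_mmHg`, samples/s.
#' @param params single-row data.frame with `T`, `D`, `K` (a row of
#'   [tiecks_param_table()]), or an integer ARI grade 0-9.
#' @param v0 baseline velocity, cm/s.
#' @param crcp critical closing pressure offset used in the normalization,
#'   mmHg (model convention default 12).
#' @param map_base baseline pressure; default mean of the first 30 s.
#' @param oversample internal Euler oversampling factor; `NULL` selects
#'   automatically so that `rate * T * oversample >= 5`.
#' @return numeric velocity series, cm/s, same length as `map_mmHg`.
#' @export
tiecks_forward <- function(map_mmHg, rate, params, v0 = 60, crcp = 12,
                           map_base = NULL, oversample = NULL) {
  stopifnot(all(is.finite(map_mmHg)), rate > 0)
  if (is.numeric(params) && length(params) == 1L) {
    tab <- tiecks_param_table()
    params <- tab[tab$ari == as.integer(params), ]
    if (nrow(params) != 1L) stop("ARI grade must be an integer in 0..9")
  }
  if (is.null(map_base)) {
    i <- seq_len(min(length(map_mmHg), max(2L, round(30 * rate))))
    map_base <- mean(map_mmHg[i])
  }
  if (map_base <= crcp) stop("baseline MAP must exceed the critical closing pressure")
  dp <- (map_mmHg - map_base) / (map_base - crcp)
  dev <- tiecks_filter(dp, rate, params$T, params$D, params$K, oversample)
  v0 * (1 + dev)
}

#' Generate the ten ARI step-response templates
#'
#' Simulates the normalized velocity response of each ARI grade to a unit
#' positive pressure step (dP: 0 to 1 at t = 0). Templates are deviation
#' curves (`dP - K*x2`, i.e. `V/v0 - 1`): they jump to 1 at the step and
#' recover towards `1 - K`, faster for higher grades.
#'
#' @param rate sampling rate, samples/s (5 for the standard pipeline).
#' @param duration_s template duration, s; must cover the fit window.
#' @param param_table parameter table; default [tiecks_param_table()].
#' @return object of class `ari_templates`: numeric matrix
#'   (time x 10 grades) with attribute `time_s`.
#' @export
make_templates <- function(rate = 5, duration_s = 12,
                           param_table = tiecks_param_table()) {
  stopifnot(nrow(param_table) == 10L, identical(param_table$ari, 0:9))
  n <- round(duration_s * rate)
  dp <- rep(1, n)
  tm <- vapply(seq_len(10), function(i) {
    p <- param_table[i, ]
    tiecks_filter(dp, rate, p$T, p$D, p$K)
  }, numeric(n))
  colnames(tm) <- paste0("ari", 0:9)
  structure(tm, time_s = (seq_len(n) - 1) / rate, class = "ari_templates")
}

#' Fit a measured step response to the ARI templates
#'
#' Assigns the Autoregulation Index as the template grade minimising the
#' normalised mean square error (NMSE) against the measured blood-velocity
#' step response over the fit window. NMSE is the mean squared
#' template-minus-measurement error divided by the mean squared value of the
#' measured step over the window: scale-free, well defined even for flat
#' (absent-autoregulation) responses whose variance is near zero, and with
#' no effect on which template wins (the denominator is
#' template-independent). Ties take the lower grade. The fit is accepted when the NMSE is below 0.3 *and* the
#' caller-supplied coherence gate passed.
#'
#' @param step a `step_response` (see [step_response()]) or a list with
#'   `time_s` and `response`.
#' @param templates an `ari_templates` matrix from [make_templates()], on
#'   the same time grid.
#' @param fit_window_s length-2 window (s) over which the fit is evaluated.
#' @param mean_coherence band-averaged coherence supplied by the caller
#'   (`NA` if not available).
#' @param coherence_limit the 95% confidence limit against which
#'   `mean_coherence` is gated (`NA` if not available).
#' @return object of class `ari_estimate`: list with `ari`, `nmse`,
#'   `nmse_by_template`, `mean_coherence`, `coherence_limit`,
#'   `coherence_pass`, `nmse_pass`, `accepted`.
#' @export
fit_ari <- function(step, templates, fit_window_s = c(0, 10),
                    mean_coherence = NA_real_, coherence_limit = NA_real_) {
  tt <- attr(templates, "time_s")
  idx_t <- which(tt >= fit_window_s[1] - 1e-9 & tt <= fit_window_s[2] + 1e-9)
  idx_s <- which(step$time_s >= fit_window_s[1] - 1e-9 &
                   step$time_s <= fit_window_s[2] + 1e-9)
  if (length(idx_t) != length(idx_s)) {
    stop("step response and templates must share the time grid over the fit window")
  }
  meas <- step$response[idx_s]
  if (!all(is.finite(meas))) stop("non-finite step response")
  if (stats::var(meas) <= 0) stop("zero-variance measured step response")
  denom <- mean(meas^2)
  nmse_all <- apply(templates[idx_t, , drop = FALSE], 2,
                    function(tpl) mean((meas - tpl)^2) / denom)
  best <- which.min(nmse_all) # ties resolve to the lower ARI
  nmse <- unname(nmse_all[best])
  nmse_pass <- nmse < 0.3
  coherence_pass <- if (is.na(mean_coherence) || is.na(coherence_limit)) {
    NA
  } else {
    mean_coherence > coherence_limit
  }
  structure(list(
    ari = as.integer(best - 1L),
    nmse = nmse,
    nmse_by_template = nmse_all,
    mean_coherence = mean_coherence,
    coherence_limit = coherence_limit,
    coherence_pass = coherence_pass,
    nmse_pass = nmse_pass,
    accepted = if (is.na(coherence_pass)) NA else coherence_pass && nmse_pass
  ), class = "ari_estimate")
}

#' @export
print.ari_estimate <- function(x, ...) {
  cat(sprintf(
    "ARI estimate: %d  (NMSE %.3f%s; band coherence %s vs limit %s; %s)\n",
    x$ari, x$nmse, if (x$nmse_pass) "" else " [>= 0.3]",
    ifelse(is.na(x$mean_coherence), "NA", sprintf("%.2f", x$mean_coherence)),
    ifelse(is.na(x$coherence_limit), "NA", sprintf("%.2f", x$coherence_limit)),
    if (isTRUE(x$accepted)) "accepted" else if (isFALSE(x$accepted)) "rejected" else "gate incomplete"
  ))
  invisible(x)
}

#' Estimate the Autoregulation Index from 5 Hz MAP and MCAv series
#'
#' End-to-end ARI estimation for one hemisphere and one recording segment
#' type: normalizes pressure and velocity, runs short-segment Welch transfer
#' function analysis ([welch_tfa()]), derives the impulse and step responses,
#' and fits the Tiecks templates with the coherence and NMSE acceptance
#' gates. Task recordings use 256-sample (51.2 s) segments, baseline
#' recordings 512-sample (102.4 s) segments, both Hann ("cosine") windowed
#' with 50% overlap.
#'
#' @param map_mmHg,mcav uniformly sampled MAP (mmHg) and MCAv series; `mcav`
#'   in cm/s, or %-change if `mcav_is_percent = TRUE`.
#' @param rate sampling rate (5 samples/s standard).
#' @param segment_type `"task"` (256-sample segments) or `"baseline"`
#'   (512-sample segments).
#' @param crcp critical closing pressure used for pressure normalization.
#' @param coherence_band band (Hz) over which coherence is averaged for the
#'   acceptance gate.
#' @param alpha significance level of the coherence confidence limit.
#' @param limit_method `"mc"` (surrogate-calibrated, honours the overlap) or
#'   `"analytic"`.
#' @param limit_seed seed for the surrogate calibration.
#' @param fit_window_s template fit window, s.
#' @param templates optional precomputed [make_templates()] result.
#' @return an `ari_estimate` with the `spectral_estimate` attached as
#'   `$spectrum` and the measured step response as `$step`.
#' @export
estimate_ari <- function(map_mmHg, mcav, rate = 5,
                         segment_type = c("task", "baseline"),
                         crcp = 12, coherence_band = c(0.15, 0.25),
                         alpha = 0.05, limit_method = c("mc", "analytic"),
                         limit_seed = 1L, fit_window_s = c(0, 10),
                         mcav_is_percent = FALSE, templates = NULL) {
  segment_type <- match.arg(segment_type)
  limit_method <- match.arg(limit_method)
  seg <- if (segment_type == "task") 256L else 512L
  n <- length(map_mmHg)
  stopifnot(length(mcav) == n)
  map_base <- mean(map_mmHg)
  if (map_base <= crcp) stop("mean MAP must exceed the critical closing pressure")
  p <- (map_mmHg - map_base) / (map_base - crcp)
  v <- if (mcav_is_percent) {
    (mcav - mean(mcav)) / (100 + mean(mcav))
  } else {
    (mcav - mean(mcav)) / mean(mcav)
  }
  spec <- welch_tfa(p, v, rate = rate, segment_samples = seg)
  mean_coh <- band_mean_coherence(spec, coherence_band)
  lim <- coherence_limit(
    n_samples = n, rate = rate, segment_samples = seg,
    overlap_fraction = 0.5, alpha = alpha, band = coherence_band,
    method = limit_method, n_windows = spec$n_windows, seed = limit_seed
  )
  imp <- impulse_response(spec)
  stp <- step_response(imp)
  if (is.null(templates)) templates <- make_templates(rate = rate)
  est <- fit_ari(stp, templates, fit_window_s = fit_window_s,
                 mean_coherence = mean_coh, coherence_limit = lim)
  est$spectrum <- spec
  est$step <- stp
  est$segment_type <- segment_type
  est
}
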