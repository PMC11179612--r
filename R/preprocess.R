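# Preprocessing of raw 500 samples/s physiological waveforms into clean,
# beat-averaged, uniformly resampled 5 Hz series.

#' Remove narrow spikes by linear interpolation
#'
#' Detects transient artefacts as runs of samples deviating from a running-
#' median baseline by more than `k` robust standard deviations (MAD), and
#' replaces runs narrower than `max_width_ms` by the linear chord between
#' the last good sample before and the first good sample after. Wider runs
#' are left untouched and reported; runs touching the record edge are held
#' at the nearest good value and reported.
#'
#' @param waveform numeric series.
#' @param sample_rate samples/s.
#' @param max_width_ms only spikes narrower than this are interpolated
#'   (100 ms standard).
#' @param k MAD multiplier of the detection threshold.
#' @return the cleaned series, with a `spike_report` attribute (see
#'   [spike_report()]).
#' @export
remove_spikes <- function(waveform, sample_rate, max_width_ms = 100, k = 8) {
  stopifnot(max_width_ms > 0, sample_rate > 0)
  n <- length(waveform)
  max_w <- max(1L, floor(max_width_ms * sample_rate / 1000))
  win <- min(4L * max_w + 1L, if (n %% 2L == 1L) n else n - 1L)
  out <- waveform
  report <- list(n_flagged = 0L, interpolated = list(),
                 too_wide = list(), edge = list())

  # Edge regions first: the running median tracks a spike that touches the
  # record boundary, so edge spikes are found from outsized first
  # differences (jumps) instead, and held at the nearest good value.
  d <- diff(out)
  sigma_d <- max(stats::mad(d),
                 stats::quantile(abs(d), 0.80, names = FALSE) / 2,
                 1e-12 * max(1, max(abs(out))))
  jumps <- which(abs(d) > k * sigma_d)
  head_j <- jumps[jumps <= max_w]
  if (length(head_j)) {
    j <- max(head_j)
    out[1:j] <- out[j + 1L]
    report$edge <- c(report$edge, list(c(start = 1L, end = j)))
  }
  tail_j <- jumps[jumps >= n - max_w]
  if (length(tail_j)) {
    j <- min(tail_j)
    out[(j + 1L):n] <- out[j]
    report$edge <- c(report$edge, list(c(start = j + 1L, end = n)))
  }

  baseline <- stats::runmed(out, k = win, endrule = "median")
  resid <- out - baseline
  # Robust scale of the artefact-free residual. For signals with a
  # continuous noise floor the MAD is the classic choice, but for smooth,
  # heavily oversampled signals the running-median residual is exactly zero
  # at most samples (the median of a monotone window is its centre) and the
  # MAD degenerates; the 80th percentile of |residual| — still robust to
  # up to ~20% artefact contamination — floors the scale at half the
  # normal residual shoulder, so pulsatile waveforms are not flagged.
  sigma <- max(stats::mad(resid),
               stats::quantile(abs(resid), 0.80, names = FALSE) / 2,
               1e-12 * max(1, max(abs(waveform))))
  flagged <- abs(resid) > k * sigma
  report$n_flagged <- sum(flagged)
  if (mean(flagged) > 0.10) stop("signal unusable: more than 10% of samples flagged as artefact")
  r <- rle(flagged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    a <- starts[j]; b <- ends[j]
    width <- b - a + 1L
    if (a == 1L || b == n) {
      # spike spans the record edge: hold the nearest good value constant
      hold <- if (a == 1L) out[b + 1L] else out[a - 1L]
      out[a:b] <- hold
      report$edge <- c(report$edge, list(c(start = a, end = b)))
    } else if (width < max_w) {
      out[a:b] <- out[a - 1L] +
        (out[b + 1L] - out[a - 1L]) * seq_len(width) / (width + 1L)
      report$interpolated <- c(report$interpolated, list(c(start = a, end = b)))
    } else {
      report$too_wide <- c(report$too_wide, list(c(start = a, end = b)))
    }
  }
  attr(out, "spike_report") <- report
  out
}

#' Spike-removal report of a cleaned series
#' @param x result of [remove_spikes()].
#' @return list with counts and sample intervals of interpolated, too-wide
#'   and edge-held artefacts.
#' @export
spike_report <- function(x) attr(x, "spike_report")

# Zero-phase filtering: odd-reflection padding, forward pass, reversed
# backward pass. The padding length is chosen from the slowest pole radius
# so start-up transients decay below 1e-9 before the data proper; the
# signal package's own filtfilt does not pad at all.
filtfilt_refl <- function(filt, x, order) {
  n <- length(x)
  r <- max(Mod(polyroot(rev(filt$a))))
  if (r >= 1) stop("unstable filter design")
  nf <- min(n - 1L, max(3L * order, ceiling(log(1e-9) / log(max(r, 0.1)))))
  pre <- 2 * x[1] - x[(nf + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - nf)]
  xp <- c(pre, x, post)
  y <- signal::filter(filt, xp)
  y <- rev(signal::filter(filt, rev(y)))
  y[(nf + 1L):(nf + n)]
}

#' Zero-phase low-pass Butterworth filter
#'
#' Designs a Butterworth low-pass filter of the given order and applies it
#' forward and backward (zero phase; the magnitude response is squared, so
#' the gain at the cutoff is the squared single-pass half-power gain).
#' Unit DC gain.
#'
#' @param waveform numeric series.
#' @param sample_rate samples/s.
#' @param cutoff_hz cutoff frequency (20 Hz standard); must be below
#'   Nyquist.
#' @param order filter order of each pass (even; 8 standard).
#' @return filtered series.
#' @export
lowpass_filter <- function(waveform, sample_rate, cutoff_hz = 20, order = 8) {
  if (cutoff_hz <= 0 || cutoff_hz >= sample_rate / 2) {
    stop("cutoff must lie strictly between 0 and the Nyquist frequency")
  }
  if (order %% 2 != 0 || order < 2) stop("filter order must be even and >= 2")
  bf <- signal::butter(order, cutoff_hz / (sample_rate / 2), type = "low")
  filtfilt_refl(bf, waveform, order)
}

#' Median filter for narrow velocity artefacts
#'
#' Running median with an odd kernel; monotone stretches longer than the
#' kernel pass through unchanged, single-sample outliers are removed
#' exactly.
#'
#' @param waveform numeric series.
#' @param kernel_samples odd kernel width >= 3 (default 5 at 500 samples/s).
#' @return filtered series.
#' @export
median_filter_mcav <- function(waveform, kernel_samples = 5) {
  if (kernel_samples %% 2 != 1 || kernel_samples < 3) stop("kernel must be odd and >= 3")
  if (kernel_samples >= length(waveform)) stop("kernel must be shorter than the signal")
  as.numeric(stats::runmed(waveform, k = kernel_samples, endrule = "keep"))
}

# Greedy local-maximum peak picking with a minimum separation (samples).
find_peaks <- function(x, min_dist, min_height = -Inf) {
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  cand <- cand[x[cand] >= min_height]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || all(abs(keep - i) >= min_dist)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Detect R waves in an ECG signal
#'
#' Pan-Tompkins-style detector: 5-25 Hz zero-phase band-pass, squared
#' derivative, 150 ms moving-window integration, adaptive threshold, and
#' refinement of each fiducial point to the local ECG maximum. R-R
#' intervals outside the physiologic gate (0.3-2.0 s), or beyond 1.66x /
#' below 0.5x the median interval (missed or spurious beats), are flagged
#' for the manual-correction hook [correct_beats()].
#'
#' @param ecg ECG series (arbitrary units, R waves positive).
#' @param sample_rate samples/s.
#' @param rr_gate_s physiologic R-R interval gate, s.
#' @return list with `beat_times` (s, strictly increasing) and `rr_flags`
#'   (data.frame of out-of-gate intervals: index, rr_s).
#' @export
detect_r_waves <- function(ecg, sample_rate, rr_gate_s = c(0.3, 2.0)) {
  n <- length(ecg)
  if (n < 2 * sample_rate) stop("need at least 2 s of ECG")
  if (stats::sd(ecg) == 0) stop("no QRS found")
  bf <- signal::butter(2, c(5, 25) / (sample_rate / 2), type = "pass")
  bp <- filtfilt_refl(bf, ecg, 4L)
  feat <- c(0, diff(bp))^2
  iw <- max(3L, round(0.150 * sample_rate))
  integ <- stats::filter(feat, rep(1 / iw, iw), sides = 2)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)
  # two-stage adaptive threshold: provisional peaks near the global
  # maximum set the QRS energy scale, the final pass keeps peaks above a
  # fraction of their median height
  p1 <- find_peaks(integ, min_dist = round(0.3 * sample_rate),
                   min_height = 0.3 * max(integ))
  if (!length(p1)) stop("no QRS found")
  thr <- 0.3 * stats::median(integ[p1])
  if (thr <= 0) stop("no QRS found")
  pk <- find_peaks(integ, min_dist = round(0.3 * sample_rate), min_height = thr)
  if (!length(pk)) stop("no QRS found")
  # refine: local raw-ECG maximum within +/- 100 ms of each integration peak
  half <- as.integer(round(0.1 * sample_rate))
  beats <- vapply(pk, function(i) {
    a <- max(1L, as.integer(i) - half); b <- min(n, as.integer(i) + half)
    a + which.max(ecg[a:b]) - 1L
  }, integer(1))
  beats <- sort(unique(beats))
  times <- (beats - 1) / sample_rate
  rr <- diff(times)
  # absolute physiologic gate plus relative outliers (missed/extra beats
  # show up as intervals far from the running rhythm)
  med_rr <- stats::median(rr)
  bad <- which(rr < rr_gate_s[1] | rr > rr_gate_s[2] |
                 rr > 1.66 * med_rr | rr < 0.5 * med_rr)
  list(beat_times = times,
       rr_flags = data.frame(index = bad, rr_s = rr[bad]))
}

#' Manual beat correction hook
#'
#' Programmatic counterpart of visual inspection with manual correction of
#' missing or misplaced beat marks: insert beats at given times and/or
#' delete beats near given times.
#'
#' @param beat_times numeric, s.
#' @param insert_s times (s) of beats to add.
#' @param delete_near_s times (s); the closest beat within `tol_s` of each
#'   is removed.
#' @param tol_s matching tolerance for deletion.
#' @return corrected, strictly increasing beat times.
#' @export
correct_beats <- function(beat_times, insert_s = numeric(0),
                          delete_near_s = numeric(0), tol_s = 0.15) {
  for (t in delete_near_s) {
    d <- abs(beat_times - t)
    if (length(d) && min(d) <= tol_s) beat_times <- beat_times[-which.min(d)]
  }
  out <- sort(unique(c(beat_times, insert_s)))
  if (any(diff(out) <= 0)) stop("beat times must be strictly increasing")
  out
}

#' Beat-to-beat mean values
#'
#' Mean of the waveform over each cardiac cycle, defined by the half-open
#' interval between consecutive beat times.
#'
#' @param waveform numeric series.
#' @param sample_rate samples/s.
#' @param beat_times strictly increasing beat instants, s (sample 1 is
#'   t = 0).
#' @return numeric vector of length `length(beat_times) - 1`.
#' @export
beat_average <- function(waveform, sample_rate, beat_times) {
  stopifnot(length(beat_times) >= 2, !is.unsorted(beat_times, strictly = TRUE))
  n <- length(waveform)
  vapply(seq_len(length(beat_times) - 1L), function(i) {
    a <- ceiling(beat_times[i] * sample_rate + 1 - 1e-9)
    b <- ceiling(beat_times[i + 1L] * sample_rate + 1 - 1e-9) - 1L
    if (b < a || a < 1L || a > n) stop("beat interval contains no samples")
    mean(waveform[a:min(b, n)])
  }, numeric(1))
}

#' Per-beat end-tidal CO2
#'
#' Detects the end-tidal value of each breath (the maximum of the capnogram
#' within each expiratory phase, segmented at the signal's mid-level),
#' interpolates the per-breath values linearly and evaluates them at the
#' beat times. Outside the span of detected breaths the first/last breath
#' value is held constant.
#'
#' @param capno capnogram series, mmHg.
#' @param sample_rate samples/s.
#' @param beat_times beat instants, s.
#' @return per-beat EtCO2, mmHg, length `length(beat_times) - 1` (matching
#'   [beat_average()] output).
#' @export
etco2_per_beat <- function(capno, sample_rate, beat_times) {
  thr <- (max(capno) + min(capno)) / 2
  above <- capno > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ex <- which(r$values)
  if (length(ex) < 2) stop("fewer than 2 breaths detected")
  bt <- vapply(ex, function(j) {
    i <- starts[j]:ends[j]
    i[which.max(capno[i])]
  }, integer(1))
  breath_t <- (bt - 1) / sample_rate
  breath_v <- capno[bt]
  mid <- beat_times[-length(beat_times)]
  stats::approx(breath_t, breath_v, xout = mid, rule = 2)$y
}

#' Spline-resample per-beat series onto a uniform grid
#'
#' Third-order (cubic) spline interpolation of a beat-indexed series,
#' sampled on a uniform grid spanning the beat span.
#'
#' @param beat_times beat instants, s (must be distinct).
#' @param values per-beat values, same length as `beat_times`.
#' @param rate target rate, samples/s (5 standard).
#' @return list with `time_s` and `values`.
#' @export
resample_uniform <- function(beat_times, values, rate = 5) {
  stopifnot(length(beat_times) == length(values), length(beat_times) >= 4)
  if (anyDuplicated(beat_times)) stop("duplicated beat times")
  grid <- seq(beat_times[1], beat_times[length(beat_times)], by = 1 / rate)
  sf <- stats::splinefun(beat_times, values, method = "fmm")
  list(time_s = grid, values = sf(grid))
}

#' Percent-change normalization against the pre-task baseline
#'
#' Expresses a velocity series as percent change from its mean over the
#' 30 s immediately preceding task onset: `100 * (v - m) / m`. The output
#' has zero mean over the normalization window.
#'
#' @param v uniformly sampled series.
#' @param time_s matching time axis, s.
#' @param task_onset_s task onset, s; at least 30 s of data must precede it.
#' @param baseline_s normalization window length, s.
#' @return percent-change series.
#' @export
normalize_percent <- function(v, time_s, task_onset_s, baseline_s = 30) {
  idx <- window_index(time_s, task_onset_s - baseline_s, task_onset_s)
  if (length(idx) < baseline_s * 0.9 / max(diff(time_s[1:2]), 1e-9)) {
    stop("need at least the full baseline window before task onset")
  }
  m <- mean(v[idx])
  if (m <= 0) stop("non-positive baseline mean")
  100 * (v - m) / m
}

#' Calibrate a Finometer pressure waveform against brachial readings
#'
#' Linear rescale `a*x + b` chosen so that the systolic (max) and diastolic
#' (min) values over a stable early reference window match the brachial
#' cuff readings; the rescale is then applied to the whole waveform.
#'
#' @param finometer pressure waveform, mmHg.
#' @param sample_rate samples/s.
#' @param brachial numeric length-2 `(systolic, diastolic)`, mmHg.
#' @param window_s reference window, s (default the first 30 s).
#' @return calibrated waveform.
#' @export
calibrate_bp <- function(finometer, sample_rate, brachial,
                         window_s = c(0, 30)) {
  stopifnot(length(brachial) == 2, brachial[1] > brachial[2])
  t <- (seq_along(finometer) - 1) / sample_rate
  idx <- window_index(t, window_s[1], window_s[2])
  hi <- max(finometer[idx]); lo <- min(finometer[idx])
  if (hi == lo) stop("reference window has zero pulse pressure")
  a <- (brachial[1] - brachial[2]) / (hi - lo)
  b <- brachial[2] - a * lo
  a * finometer + b
}

#' Preprocess a raw multichannel recording
#'
#' Full preprocessing chain for one recording: optional Finometer
#' calibration, spike removal (<100 ms artefacts), 20 Hz zero-phase
#' low-pass filtering, median filtering of the velocity channels, R-wave
#' detection, beat-to-beat averaging of pressure and velocity, heart rate
#' from R-R intervals, per-beat end-tidal CO2, cubic-spline resampling at
#' 5 samples/s, percent normalization of the velocity channels against the
#' 30 s pre-task baseline, and per-sample segment labels (rest / task /
#' recovery).
#'
#' @param rec a `raw_recording` (see [raw_recording()]).
#' @param spike_ms spike-width threshold, ms.
#' @param lp_hz low-pass cutoff, Hz.
#' @param median_kernel velocity median-filter kernel, samples.
#' @param out_rate uniform resampling rate, samples/s.
#' @param beat_insert_s,beat_delete_s manual beat corrections forwarded to
#'   [correct_beats()].
#' @return object of class `preprocessed_recording`: list with `beats`
#'   (data.frame), `uniform` (data.frame: time_s, map_mmHg, mcav_left_pct,
#'   mcav_right_pct, hr_bpm, etco2_mmHg, segment), and `report`.
#' @export
preprocess_recording <- function(rec, spike_ms = 100, lp_hz = 20,
                                 median_kernel = 5, out_rate = 5,
                                 beat_insert_s = numeric(0),
                                 beat_delete_s = numeric(0)) {
  stopifnot(inherits(rec, "raw_recording"))
  fs <- rec$sample_rate
  report <- list(spikes = list())
  bp <- rec$channels$bp
  if (!is.null(rec$brachial)) bp <- calibrate_bp(bp, fs, rec$brachial)
  clean <- list()
  for (ch in c("bp", "mcav_left", "mcav_right", "etco2")) {
    x <- if (ch == "bp") bp else rec$channels[[ch]]
    x <- remove_spikes(x, fs, max_width_ms = spike_ms)
    report$spikes[[ch]] <- spike_report(x)
    clean[[ch]] <- lowpass_filter(as.numeric(x), fs, cutoff_hz = lp_hz)
  }
  for (ch in c("mcav_left", "mcav_right")) {
    clean[[ch]] <- median_filter_mcav(clean[[ch]], median_kernel)
  }
  det <- detect_r_waves(rec$channels$ecg, fs)
  beat_times <- correct_beats(det$beat_times, beat_insert_s, beat_delete_s)
  report$rr_flags <- det$rr_flags
  report$n_beats <- length(beat_times)

  rr <- diff(beat_times)
  beats <- data.frame(
    beat_time_s = beat_times[-length(beat_times)],
    rr_interval_s = rr,
    hr_bpm = 60 / rr,
    map_mmHg = beat_average(clean$bp, fs, beat_times),
    mcav_left = beat_average(clean$mcav_left, fs, beat_times),
    mcav_right = beat_average(clean$mcav_right, fs, beat_times),
    etco2_mmHg = etco2_per_beat(clean$etco2, fs, beat_times)
  )

  rs <- lapply(c("map_mmHg", "mcav_left", "mcav_right", "hr_bpm", "etco2_mmHg"),
               function(ch) resample_uniform(beats$beat_time_s, beats[[ch]], out_rate))
  time_s <- rs[[1]]$time_s
  onset <- if (nrow(rec$annotations)) rec$annotations$onset_s[1] else NULL
  norm_onset <- onset %||% (time_s[1] + 30) # baseline-only: first 30 s
  uniform <- data.frame(
    time_s = time_s,
    map_mmHg = rs[[1]]$values,
    mcav_left_pct = normalize_percent(rs[[2]]$values, time_s, norm_onset),
    mcav_right_pct = normalize_percent(rs[[3]]$values, time_s, norm_onset),
    hr_bpm = rs[[4]]$values,
    etco2_mmHg = rs[[5]]$values,
    segment = segment_labels(time_s, rec$annotations)
  )
  attr(uniform, "rate") <- out_rate
  structure(list(beats = beats, uniform = uniform, report = report),
            class = "preprocessed_recording")
}

# Per-sample rest/task/recovery labels from task annotations.
segment_labels <- function(time_s, annotations) {
  lab <- rep("rest", length(time_s))
  if (!is.null(annotations) && nrow(annotations)) {
    for (i in seq_len(nrow(annotations))) {
      on <- annotations$onset_s[i]
      off <- on + annotations$duration_s[i]
      lab[time_s >= on & time_s < off] <- "task"
      lab[time_s >= off] <- "recovery"
    }
  }
  factor(lab, levels = c("rest", "task", "recovery"))
}

#' Construct a raw multichannel recording
#'
#' Container for one raw recording: equal-length channels sampled at a
#' common rate, task annotations, and optional brachial calibration
#' readings.
#'
#' @param sample_rate samples/s (nominally 500).
#' @param channels named list: `bp` (mmHg), `mcav_left`, `mcav_right`
#'   (cm/s), `ecg` (a.u.), `etco2` (mmHg); equal lengths.
#' @param annotations data.frame with `task_id`, `onset_s`, `duration_s`
#'   (may have zero rows for baseline recordings).
#' @param brachial optional `(systolic, diastolic)` mmHg.
#' @return object of class `raw_recording`.
#' @export
raw_recording <- function(sample_rate, channels,
                          annotations = data.frame(task_id = character(0),
                                                   onset_s = numeric(0),
                                                   duration_s = numeric(0)),
                          brachial = NULL) {
  stopifnot(sample_rate > 0, is.list(channels))
  need <- c("bp", "mcav_left", "mcav_right", "ecg", "etco2")
  stopifnot(all(need %in% names(channels)))
  lens <- vapply(channels[need], length, integer(1))
  stopifnot(length(unique(lens)) == 1L)
  dur <- lens[[1]] / sample_rate
  if (nrow(annotations)) {
    stopifnot(all(annotations$onset_s >= 0),
              all(annotations$onset_s + annotations$duration_s <= dur + 1e-9))
    if (dur < 180 - 1e-9) stop("task recordings must last at least 180 s")
  }
  structure(list(sample_rate = sample_rate, channels = channels[need],
                 annotations = annotations, brachial = brachial,
                 duration_s = dur),
            class = "raw_recording")
}
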