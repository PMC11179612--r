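# Preprocessing operations: spike removal, filtering, R-wave detection,
# beat averaging, EtCO2 resampling, spline resampling, normalization,
# pressure calibration.

fs <- 500

test_that("spike removal interpolates narrow spikes and leaves clean and wide regions alone", {
  t <- (0:(20 * fs - 1)) / fs
  x <- 80 + 10 * sin(2 * pi * 1 * t)

  # clean signal: identity
  expect_identical(as.numeric(remove_spikes(x, fs)), x)

  # one 40 ms rectangular spike of +50: removed, chord error only inside
  y <- x
  i0 <- 5 * fs + 1
  w <- round(0.040 * fs)
  y[i0:(i0 + w - 1)] <- y[i0:(i0 + w - 1)] + 50
  cleaned <- remove_spikes(y, fs)
  rep <- spike_report(cleaned)
  expect_length(rep$interpolated, 1)
  outside <- setdiff(seq_along(x), i0:(i0 + w - 1))
  expect_identical(as.numeric(cleaned)[outside], x[outside])
  # linear chord between the bracketing good samples bounds the error
  chord <- approx(c(i0 - 1, i0 + w), x[c(i0 - 1, i0 + w)],
                  xout = i0:(i0 + w - 1))$y
  expect_lt(max(abs(as.numeric(cleaned)[i0:(i0 + w - 1)] - chord)), 1e-9)
  expect_lt(max(abs(as.numeric(cleaned)[i0:(i0 + w - 1)] - x[i0:(i0 + w - 1)])),
            max(abs(chord - x[i0:(i0 + w - 1)])) + 1e-9)

  # 150 ms spike (>= 100 ms threshold): untouched, reported
  z <- x
  wz <- round(0.150 * fs)
  z[i0:(i0 + wz - 1)] <- z[i0:(i0 + wz - 1)] + 50
  cleaned2 <- remove_spikes(z, fs)
  expect_length(spike_report(cleaned2)$too_wide, 1)
  expect_identical(as.numeric(cleaned2), z)

  # spike touching the record edge: held constant, reported
  e <- x
  e[1:10] <- e[1:10] + 50
  cleanede <- remove_spikes(e, fs)
  expect_length(spike_report(cleanede)$edge, 1)
  expect_equal(as.numeric(cleanede)[1:10], rep(e[11], 10))

  # > 10% flagged: unusable (noisy signal, spikes on every 7th sample)
  set.seed(12)
  b <- x + rnorm(length(x), sd = 0.2)
  b[seq(100, length(b) - 100, by = 7)] <- b[seq(100, length(b) - 100, by = 7)] + 50
  expect_error(remove_spikes(b, fs), "unusable")
})

test_that("zero-phase Butterworth low-pass has unit DC gain, flat passband and strong stopband attenuation", {
  t <- (0:(10 * fs - 1)) / fs
  # constant in, constant out
  expect_equal(lowpass_filter(rep(7.5, length(t)), fs), rep(7.5, length(t)),
               tolerance = 1e-8)
  # 1 Hz passband tone: amplitude within 1%, zero phase
  x1 <- sin(2 * pi * 1 * t)
  y1 <- lowpass_filter(x1, fs)
  mid <- (2 * fs):(8 * fs)
  fit <- lm(y1[mid] ~ sin(2 * pi * t[mid]) + cos(2 * pi * t[mid]) - 1)
  amp <- sqrt(sum(coef(fit)^2))
  expect_equal(amp, 1, tolerance = 0.01)
  expect_lt(abs(atan2(coef(fit)[2], coef(fit)[1])), 0.01) # phase ~ 0
  # 100 Hz tone (5x cutoff): > 60 dB down
  x2 <- sin(2 * pi * 100 * t)
  y2 <- lowpass_filter(x2, fs)
  expect_lt(max(abs(y2[mid])), 1e-3)
  # cutoff at/above Nyquist rejected
  expect_error(lowpass_filter(x1, fs, cutoff_hz = 250), "Nyquist")
})

test_that("median filter removes point outliers and passes monotone ramps", {
  r <- seq(0, 10, length.out = 101)
  expect_equal(median_filter_mcav(r, 5)[3:99], r[3:99])
  x <- rep(5, 50)
  x[25] <- 105
  expect_equal(median_filter_mcav(x, 5), rep(5, 50))
  # alternating square at period 2, kernel 3: median is the per-window majority
  sq <- rep(c(1, -1), 10)
  out <- median_filter_mcav(sq, 3)
  expect_equal(out[2:19], vapply(2:19, function(i) median(sq[(i - 1):(i + 1)]),
                                 numeric(1)))
  expect_error(median_filter_mcav(x, 4), "odd")
  expect_error(median_filter_mcav(x, 51), "shorter")
})

test_that("R-wave detection recovers impulse-train beats, flags gaps, rejects flat signals", {
  beats <- seq(1, 59, by = 0.8)
  ecg <- fixture_ecg(beats, 60, fs, seed = 3)
  det <- detect_r_waves(ecg, fs)
  expect_equal(length(det$beat_times), length(beats))
  expect_lt(max(abs(det$beat_times - beats)), 2 / fs + 1e-9)
  expect_equal(nrow(det$rr_flags), 0)

  # one missing beat -> a 1.6 s interval flagged as out-of-gate
  gap <- beats[-30]
  det2 <- detect_r_waves(fixture_ecg(gap, 60, fs, seed = 4), fs)
  expect_equal(length(det2$beat_times), length(gap))
  expect_equal(nrow(det2$rr_flags), 1)
  expect_equal(det2$rr_flags$rr_s, 1.6, tolerance = 0.02)

  expect_error(detect_r_waves(rep(0, 10 * fs), fs), "no QRS")
})

test_that("manual beat correction inserts and deletes beats", {
  bt <- seq(0, 10, by = 1)
  out <- correct_beats(bt, insert_s = 5.5, delete_near_s = 3.02)
  expect_true(5.5 %in% out)
  expect_false(3 %in% out)
  expect_equal(length(out), length(bt))
})

test_that("beat averaging matches analytic means and conserves the global mean", {
  t <- (0:(10 * fs - 1)) / fs
  bt <- seq(0, 10, by = 0.5)
  # constant
  expect_equal(beat_average(rep(3.2, length(t)), fs, bt),
               rep(3.2, length(bt) - 1))
  # full sine cycles aligned to beats average to ~0
  x <- sin(2 * pi * 2 * t) # period 0.5 s = one beat
  expect_lt(max(abs(beat_average(x, fs, bt))), 1e-3)
  # linear ramp: means are interval midpoints
  r <- t
  m <- beat_average(r, fs, bt)
  mid <- bt[-length(bt)] + 0.25 - 0.5 / fs / 2 # half-open sample window
  expect_equal(m, mid, tolerance = 1e-3)
  # conservation: duration-weighted mean of beat means == mean over the span
  set.seed(9)
  y <- cumsum(rnorm(length(t)))
  bt2 <- c(0, sort(runif(20, 0.5, 9.5)), 10)
  mb <- beat_average(y, fs, bt2)
  counts <- vapply(seq_len(length(bt2) - 1), function(i) {
    a <- ceiling(bt2[i] * fs + 1 - 1e-9)
    b <- ceiling(bt2[i + 1] * fs + 1 - 1e-9) - 1
    b - a + 1
  }, numeric(1))
  span <- ceiling(bt2[1] * fs + 1 - 1e-9):(ceiling(bt2[length(bt2)] * fs + 1 - 1e-9) - 1)
  expect_equal(sum(mb * counts) / sum(counts), mean(y[span]), tolerance = 1e-9)
})

test_that("per-beat EtCO2 interpolates breath end-tidal values with held boundaries", {
  # plateau train at 38 mmHg
  t <- (0:(60 * fs - 1)) / fs
  gate <- as.numeric((t %% 4) > 1 & (t %% 4) < 2.6)
  capno <- 3 + 35 * gate
  bt <- seq(0.5, 59, by = 0.8)
  v <- etco2_per_beat(capno, fs, bt)
  expect_equal(v, rep(38, length(bt) - 1), tolerance = 1e-6)
  # alternating 36/40 peaks: beat values on the chords, inside [36, 40]
  pk <- rep(c(33, 37), 8) # plateau heights above the 3 mmHg base
  capno2 <- numeric(length(t))
  for (i in seq_along(pk)) {
    idx <- which(t >= (i - 1) * 4 + 1 & t < (i - 1) * 4 + 2.6)
    capno2[idx] <- pk[i]
  }
  capno2 <- capno2 + 3
  v2 <- etco2_per_beat(capno2, fs, bt)
  expect_true(all(v2 >= 36 - 1e-9 & v2 <= 40 + 1e-9))
  # beats before the first breath peak hold the first value
  v3 <- etco2_per_beat(capno, fs, c(0.1, 0.2, 59.5, 59.9))
  expect_equal(v3[1], 38, tolerance = 1e-6)
  expect_error(etco2_per_beat(rep(38, fs * 4), fs, bt), "breaths")
})

test_that("cubic-spline resampling reproduces cubics and matches a dense oracle for smooth signals", {
  bt <- seq(0, 20, by = 0.8)
  cubic <- function(x) 1 + 0.5 * x - 0.2 * x^2 + 0.01 * x^3
  out <- resample_uniform(bt, cubic(bt), rate = 5)
  expect_equal(out$values, cubic(out$time_s), tolerance = 1e-9)
  cst <- resample_uniform(bt, rep(4, length(bt)), rate = 5)
  expect_equal(cst$values, rep(4, length(cst$time_s)))
  # slow sinusoid sampled at beats: interior within 1% of the true curve
  s <- sin(2 * pi * 0.1 * bt)
  o <- resample_uniform(bt, s, rate = 5)
  interior <- o$time_s > 1 & o$time_s < 19
  expect_lt(max(abs(o$values[interior] - sin(2 * pi * 0.1 * o$time_s[interior]))),
            0.01)
  expect_error(resample_uniform(c(0, 1, 1, 2), 1:4), "duplicated")
})

test_that("percent normalization is zero-mean over the baseline window", {
  t <- (0:899) / 5
  v <- rep(60, 900)
  expect_equal(normalize_percent(v, t, 60), rep(0, 900))
  v2 <- c(rep(60, 300), rep(66, 600))
  out <- normalize_percent(v2, t, 60)
  expect_equal(out[301], 10)
  expect_lt(abs(mean(out[window_index <- t >= 30 & t < 60])), 1e-9)
  expect_error(normalize_percent(-v, t, 60), "non-positive")
  expect_error(normalize_percent(v, t, 10), "baseline window")
})

test_that("Finometer calibration maps the reference window onto brachial readings", {
  t <- (0:(40 * fs - 1)) / fs
  x <- 80 + 20 * sin(2 * pi * 1.2 * t) # range [60, 100]
  cal <- calibrate_bp(x, fs, brachial = c(120, 80))
  win <- 1:(30 * fs)
  expect_equal(max(cal[win]), 120, tolerance = 1e-6)
  expect_equal(min(cal[win]), 80, tolerance = 1e-6)
  # already matching: identity
  cal2 <- calibrate_bp(cal, fs, brachial = c(120, 80))
  expect_equal(cal2, cal, tolerance = 1e-9)
  expect_error(calibrate_bp(rep(90, fs * 40), fs, c(120, 80)), "pulse pressure")
})

test_that("spike removal then filtering leaves an already-clean signal within passband ripple", {
  t <- (0:(20 * fs - 1)) / fs
  x <- 80 + 5 * sin(2 * pi * 0.3 * t) + 2 * sin(2 * pi * 1.1 * t)
  y <- lowpass_filter(as.numeric(remove_spikes(x, fs)), fs)
  mid <- (2 * fs):(18 * fs)
  expect_lt(max(abs(y[mid] - x[mid])), 0.01 * 7)
})
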