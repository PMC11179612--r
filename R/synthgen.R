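# Synthetic recording generator with known ground truth: blood pressure
# with spontaneous low-frequency variability, cerebral blood velocity
# produced through the Tiecks autoregulation model at a known ARI, a
# task-evoked neurovascular coupling response, and (optionally) fully
# pulsatile raw 500 samples/s waveforms.

#' Specification of a synthetic recording or cohort
#'
#' Bundles the generator's ground-truth parameters. Defaults emulate the
#' study conditions for healthy adults performing 1-min cognitive tasks:
#' 3-min task recordings (1 min rest / 1 min task / 1 min recovery), 5-min
#' baseline recordings, a task-evoked MCAv rise of ~7%, MAP rise of
#' ~4 mmHg, HR rise of ~6 bpm, slight EtCO2 decline, baseline ARI 6
#' depressed to 4 during activation, and ~85% responders.
#'
#' @param seed master seed; all per-subject/visit/task seeds derive from it.
#' @param n_subjects cohort size.
#' @param duration_s task-recording duration, s.
#' @param baseline_duration_s baseline-recording duration, s.
#' @param rate uniform sampling rate, samples/s.
#' @param rate_raw raw waveform sampling rate, samples/s.
#' @param task_onset_s,task_duration_s task timing within a task recording.
#' @param true_ari_baseline,true_ari_task ARI grades outside/during the
#'   task minute.
#' @param v0_cms baseline MCAv, cm/s.
#' @param map_baseline_mmHg baseline mean arterial pressure, mmHg.
#' @param map_rise_mmHg task-evoked MAP rise, mmHg.
#' @param mayer_amp_mmHg amplitude of the ~0.1 Hz Mayer-wave component.
#' @param lf_noise_sd_mmHg SD of the band-limited (0.02-0.45 Hz) 1/f MAP
#'   variability.
#' @param white_noise_sd_mmHg SD of the broadband MAP noise floor.
#' @param nvc_amplitude_pct task-evoked MCAv rise for responders, percent.
#' @param nvc_shape `"ramp-plateau"` (3 s ramp, plateau, 5 s decay) or
#'   `"gamma"` (gamma-kernel rise and fall).
#' @param noise_sd_pct additive MCAv noise SD, percent.
#' @param noise_ref `"v0"`: noise SD is `noise_sd_pct`% of baseline
#'   velocity; `"signal_sd"`: percent of the noise-free signal SD.
#' @param hr_baseline_bpm,hr_rise_bpm heart-rate level and task rise.
#' @param etco2_baseline_mmHg,etco2_drift_mmHg EtCO2 level and task drift.
#' @param responder_fraction probability that a subject x task is a true
#'   responder.
#' @param tasks character vector of task ids per subject and visit.
#' @param n_visits number of visits.
#' @param crcp_mmHg critical closing pressure used in the forward model.
#' @return object of class `synth_spec` (a validated list).
#' @export
synth_spec <- function(seed = 1L, n_subjects = 16L, duration_s = 180,
                       baseline_duration_s = 300, rate = 5, rate_raw = 500,
                       task_onset_s = 60, task_duration_s = 60,
                       true_ari_baseline = 6L, true_ari_task = 4L,
                       v0_cms = 60, map_baseline_mmHg = 89,
                       map_rise_mmHg = 4, mayer_amp_mmHg = 2,
                       lf_noise_sd_mmHg = 3, white_noise_sd_mmHg = 0.3,
                       nvc_amplitude_pct = 6.9,
                       nvc_shape = c("ramp-plateau", "gamma"),
                       noise_sd_pct = 2, noise_ref = c("v0", "signal_sd"),
                       hr_baseline_bpm = 71, hr_rise_bpm = 6,
                       etco2_baseline_mmHg = 36.5, etco2_drift_mmHg = -0.6,
                       responder_fraction = 0.85,
                       tasks = c("nw", "ss"), n_visits = 2L,
                       crcp_mmHg = 12) {
  spec <- list(
    seed = as.integer(seed), n_subjects = as.integer(n_subjects),
    duration_s = duration_s, baseline_duration_s = baseline_duration_s,
    rate = rate, rate_raw = rate_raw,
    task_onset_s = task_onset_s, task_duration_s = task_duration_s,
    true_ari_baseline = as.integer(true_ari_baseline),
    true_ari_task = as.integer(true_ari_task),
    v0_cms = v0_cms, map_baseline_mmHg = map_baseline_mmHg,
    map_rise_mmHg = map_rise_mmHg, mayer_amp_mmHg = mayer_amp_mmHg,
    lf_noise_sd_mmHg = lf_noise_sd_mmHg,
    white_noise_sd_mmHg = white_noise_sd_mmHg,
    nvc_amplitude_pct = nvc_amplitude_pct,
    nvc_shape = match.arg(nvc_shape),
    noise_sd_pct = noise_sd_pct, noise_ref = match.arg(noise_ref),
    hr_baseline_bpm = hr_baseline_bpm, hr_rise_bpm = hr_rise_bpm,
    etco2_baseline_mmHg = etco2_baseline_mmHg,
    etco2_drift_mmHg = etco2_drift_mmHg,
    responder_fraction = responder_fraction,
    tasks = tasks, n_visits = as.integer(n_visits),
    crcp_mmHg = crcp_mmHg
  )
  stopifnot(
    spec$rate > 0, spec$rate_raw > 0, spec$duration_s >= 180,
    spec$true_ari_baseline %in% 0:9, spec$true_ari_task %in% 0:9,
    spec$nvc_amplitude_pct >= 0, spec$noise_sd_pct >= 0,
    spec$responder_fraction >= 0, spec$responder_fraction <= 1,
    spec$map_baseline_mmHg > spec$crcp_mmHg
  )
  structure(spec, class = "synth_spec")
}

# Smooth task-locked activation profile: raised-cosine edges of `edge_s`.
task_profile <- function(time_s, onset, duration, edge_s = 5) {
  up <- pmin(1, pmax(0, (time_s - onset) / edge_s))
  down <- pmin(1, pmax(0, (time_s - (onset + duration)) / edge_s))
  f <- function(u) 0.5 * (1 - cos(pi * u))
  f(up) - f(down)
}

#' Generate a synthetic mean arterial pressure series
#'
#' MAP = baseline + ~0.1 Hz Mayer wave + band-limited (0.02-0.45 Hz) 1/f
#' variability + broadband noise floor + smooth task-locked rise. Seeded
#' and fully reproducible.
#'
#' @param spec a [synth_spec()].
#' @param seed RNG seed for this realization.
#' @param duration_s record length, s; default the spec's task duration.
#' @param task include the task-locked MAP rise.
#' @return list with `time_s`, `map_mmHg`, `rate`.
#' @export
gen_map <- function(spec, seed = spec$seed, duration_s = spec$duration_s,
                    task = TRUE) {
  n <- round(duration_s * spec$rate)
  t <- (seq_len(n) - 1) / spec$rate
  map <- with_seed(seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    f_mayer <- stats::runif(1, 0.09, 0.11)
    m <- spec$map_baseline_mmHg +
      spec$mayer_amp_mmHg * sin(2 * pi * f_mayer * t + phase)
    if (spec$lf_noise_sd_mmHg > 0) {
      m <- m + band_limited_noise(n, spec$rate, c(0.02, 0.45),
                                  sd = spec$lf_noise_sd_mmHg,
                                  shape = "one_over_f")
    }
    if (spec$white_noise_sd_mmHg > 0) {
      m <- m + stats::rnorm(n, sd = spec$white_noise_sd_mmHg)
    }
    m
  })
  if (task && spec$map_rise_mmHg != 0) {
    map <- map + spec$map_rise_mmHg *
      task_profile(t, spec$task_onset_s, spec$task_duration_s)
  }
  list(time_s = t, map_mmHg = map, rate = spec$rate)
}

# Neurovascular coupling response shape on [0, 1].
nvc_shape_curve <- function(time_s, onset, duration,
                            shape = c("ramp-plateau", "gamma"),
                            ramp_s = 3, decay_s = 5) {
  shape <- match.arg(shape)
  s <- numeric(length(time_s))
  if (shape == "ramp-plateau") {
    dt <- time_s - onset
    s[dt >= 0 & dt < ramp_s] <- dt[dt >= 0 & dt < ramp_s] / ramp_s
    s[dt >= ramp_s & dt < duration] <- 1
    post <- dt >= duration & dt < duration + decay_s
    s[post] <- 1 - (dt[post] - duration) / decay_s
  } else {
    dt <- pmax(0, time_s - onset)
    g <- (dt / 4)^2 * exp(-dt / 4) # gamma-kernel rise
    gate <- task_profile(time_s, onset, duration, edge_s = decay_s)
    s <- g / max(g) * gate
  }
  s
}

#' Generate bilateral MCAv series from a MAP series
#'
#' Passes the pressure series through the Tiecks forward model at the true
#' ARI (the baseline grade outside the task minute, the task grade during
#' it, crossfaded over 2 s), adds the task-evoked neurovascular coupling
#' response for responders, and additive Gaussian noise (independent per
#' hemisphere).
#'
#' @param map a result of [gen_map()].
#' @param spec a [synth_spec()].
#' @param seed RNG seed for the noise.
#' @param responder is this subject a responder for this task?
#' @param task does the recording contain a task (ARI switch + NVC)?
#' @return list with `time_s`, `mcav_left`, `mcav_right` (cm/s), `truth`.
#' @export
gen_mcav <- function(map, spec, seed = spec$seed, responder = TRUE,
                     task = TRUE) {
  t <- map$time_s
  n <- length(t)
  v_base <- tiecks_forward(map$map_mmHg, map$rate, spec$true_ari_baseline,
                           v0 = spec$v0_cms, crcp = spec$crcp_mmHg,
                           map_base = spec$map_baseline_mmHg)
  if (task && spec$true_ari_task != spec$true_ari_baseline) {
    v_task <- tiecks_forward(map$map_mmHg, map$rate, spec$true_ari_task,
                             v0 = spec$v0_cms, crcp = spec$crcp_mmHg,
                             map_base = spec$map_baseline_mmHg)
    w <- task_profile(t, spec$task_onset_s, spec$task_duration_s, edge_s = 2)
    v_nf <- (1 - w) * v_base + w * v_task
  } else {
    v_nf <- v_base
  }
  amp <- if (task && responder) spec$nvc_amplitude_pct else 0
  if (amp > 0) {
    v_nf <- v_nf + spec$v0_cms * amp / 100 *
      nvc_shape_curve(t, spec$task_onset_s, spec$task_duration_s,
                      spec$nvc_shape)
  }
  noise_sd <- if (spec$noise_ref == "v0") {
    spec$noise_sd_pct / 100 * spec$v0_cms
  } else {
    spec$noise_sd_pct / 100 * stats::sd(v_nf)
  }
  out <- with_seed(seed, {
    list(left = v_nf + stats::rnorm(n, sd = noise_sd),
         right = v_nf + stats::rnorm(n, sd = noise_sd))
  })
  list(time_s = t, mcav_left = out$left, mcav_right = out$right,
       truth = list(ari_baseline = spec$true_ari_baseline,
                    ari_task = if (task) spec$true_ari_task else spec$true_ari_baseline,
                    responder = responder, nvc_amplitude_pct = amp,
                    noise_sd = noise_sd, seed = seed))
}

#' Generate one uniformly sampled synthetic recording
#'
#' Produces a 5 Hz recording in the same layout the preprocessing stage
#' emits: MAP, bilateral MCAv (absolute and percent-normalized), HR and
#' EtCO2 trajectories, segment labels, plus the ground truth.
#'
#' @param spec a [synth_spec()].
#' @param seed RNG seed.
#' @param type `"task"` (3-min rest/task/recovery) or `"baseline"`.
#' @param responder true responder status for this recording.
#' @return object of class `synthetic_recording`: list with `uniform`
#'   (data.frame), `onset_s`, `type`, `truth`.
#' @export
gen_recording <- function(spec, seed = spec$seed,
                          type = c("task", "baseline"), responder = TRUE) {
  type <- match.arg(type)
  task <- type == "task"
  dur <- if (task) spec$duration_s else spec$baseline_duration_s
  map <- gen_map(spec, seed = derive_seed(seed, 1), duration_s = dur,
                 task = task)
  mc <- gen_mcav(map, spec, seed = derive_seed(seed, 2),
                 responder = responder, task = task)
  t <- map$time_s
  prof <- if (task) task_profile(t, spec$task_onset_s, spec$task_duration_s) else 0
  hr <- spec$hr_baseline_bpm + spec$hr_rise_bpm * prof
  etco2 <- spec$etco2_baseline_mmHg + spec$etco2_drift_mmHg * prof
  onset <- if (task) spec$task_onset_s else NA_real_
  norm_onset <- if (task) onset else t[1] + 30
  ann <- if (task) {
    data.frame(task_id = "task", onset_s = onset,
               duration_s = spec$task_duration_s)
  } else {
    data.frame(task_id = character(0), onset_s = numeric(0),
               duration_s = numeric(0))
  }
  uniform <- data.frame(
    time_s = t,
    map_mmHg = map$map_mmHg,
    mcav_left = mc$mcav_left,
    mcav_right = mc$mcav_right,
    mcav_left_pct = normalize_percent(mc$mcav_left, t, norm_onset),
    mcav_right_pct = normalize_percent(mc$mcav_right, t, norm_onset),
    hr_bpm = hr,
    etco2_mmHg = etco2,
    segment = segment_labels(t, ann)
  )
  attr(uniform, "rate") <- spec$rate
  structure(list(uniform = uniform, onset_s = onset, type = type,
                 truth = mc$truth, seed = seed),
            class = "synthetic_recording")
}

#' Generate a raw 500 samples/s synthetic recording
#'
#' Synthesizes pulsatile waveforms around the 5 Hz trajectories: blood
#' pressure with a zero-mean intra-beat pulse shape gated on the beat
#' times, an impulse-train ECG at the prescribed R-R series, a pulsatile
#' MCAv waveform, and a plateau-train capnogram. Optionally injects narrow
#' rectangular spikes for artefact-handling tests.
#'
#' @param spec a [synth_spec()].
#' @param seed RNG seed.
#' @param type `"task"` or `"baseline"`.
#' @param responder true responder status.
#' @param pulse_mmHg half-amplitude of the arterial pulse wave.
#' @param n_spikes number of injected 40 ms artefact spikes (0 = clean).
#' @return list with `recording` (a [raw_recording()]), `beat_times_s`
#'   (ground-truth R-wave instants), `uniform_truth` (the underlying
#'   [gen_recording()] object), and `spike_times_s`.
#' @export
gen_raw <- function(spec, seed = spec$seed, type = c("task", "baseline"),
                    responder = TRUE, pulse_mmHg = 15, n_spikes = 0) {
  type <- match.arg(type)
  base <- gen_recording(spec, seed = seed, type = type, responder = responder)
  u <- base$uniform
  fs <- spec$rate_raw
  dur <- u$time_s[length(u$time_s)] + 1 / spec$rate
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  up <- function(v) stats::splinefun(u$time_s, v, method = "fmm")(t)
  map500 <- up(u$map_mmHg)
  mcl500 <- up(u$mcav_left)
  mcr500 <- up(u$mcav_right)
  hr500 <- up(u$hr_bpm)
  etc500 <- up(u$etco2_mmHg)

  # beat times by integrating the instantaneous heart rate; the train
  # starts clear of the record edge so the first QRS is not truncated
  beats <- numeric(0)
  tk <- 0.5
  while (tk < dur - 0.3) {
    beats <- c(beats, tk)
    hr_k <- hr500[min(n, floor(tk * fs) + 1L)]
    tk <- tk + 60 / hr_k
  }
  # Gaussian QRS complexes (~30 ms wide) on a small noise floor
  ecg <- with_seed(derive_seed(seed, 11), stats::rnorm(n, sd = 0.03))
  qrs_hw <- round(0.03 * fs)
  kernel <- exp(-0.5 * ((-qrs_hw):qrs_hw / (0.01 * fs))^2)
  for (b in round(beats * fs) + 1L) {
    i <- (b - qrs_hw):(b + qrs_hw)
    ok <- i >= 1L & i <= n
    ecg[i[ok]] <- ecg[i[ok]] + kernel[ok]
  }

  # intra-beat phase and a zero-mean pulse shape
  phase <- numeric(n)
  idx <- findInterval(t, beats)
  idx[idx < 1L] <- 1L
  b0 <- beats[idx]
  b1 <- c(beats[-1], dur)[idx]
  phase <- (t - b0) / (b1 - b0)
  pulse <- sin(2 * pi * phase) + 0.3 * sin(4 * pi * phase)
  bp <- map500 + pulse_mmHg * pulse
  mcav_l <- mcl500 + 0.4 * pulse_mmHg * pulse
  mcav_r <- mcr500 + 0.4 * pulse_mmHg * pulse

  # capnogram: expiration plateaus at the end-tidal trajectory, smoothed
  breath_period <- 4
  bphase <- (t %% breath_period) / breath_period
  gate <- task_profile(bphase, 0.25, 0.45, edge_s = 0.08)
  capno <- 3 + (etc500 - 3) * gate

  spike_times <- numeric(0)
  if (n_spikes > 0) {
    spike_times <- with_seed(derive_seed(seed, 13),
                             sort(stats::runif(n_spikes, 5, dur - 5)))
    w <- round(0.040 * fs)
    for (st in spike_times) {
      i0 <- round(st * fs) + 1L
      bp[i0:(i0 + w - 1L)] <- bp[i0:(i0 + w - 1L)] + 50
      mcav_l[i0:(i0 + w - 1L)] <- mcav_l[i0:(i0 + w - 1L)] + 50
    }
  }
  ann <- if (type == "task") {
    data.frame(task_id = "task", onset_s = spec$task_onset_s,
               duration_s = spec$task_duration_s)
  } else {
    data.frame(task_id = character(0), onset_s = numeric(0),
               duration_s = numeric(0))
  }
  rec <- raw_recording(fs, list(bp = bp, mcav_left = mcav_l,
                                mcav_right = mcav_r, ecg = ecg,
                                etco2 = capno),
                       annotations = ann)
  list(recording = rec, beat_times_s = beats, uniform_truth = base,
       spike_times_s = spike_times)
}

#' Generate a synthetic cohort with ground truth
#'
#' One baseline recording plus one recording per task, per subject and
#' visit. Responder status is a subject x task trait drawn once with
#' probability `responder_fraction` and shared across visits; every
#' recording draws fresh noise through a visit-and-task-specific seed
#' derived from the master seed, so generation is a pure function of the
#' spec.
#'
#' @param spec a [synth_spec()].
#' @param identical_visits if `TRUE`, visit 2 reuses visit 1's seeds
#'   (useful for reproducibility-statistic checks: downstream ICC must be 1).
#' @return object of class `synthetic_cohort`: list with `recordings`
#'   (`recordings[[subject]][[visit]]` = list of `baseline` + one entry per
#'   task), `truth` (data.frame), `spec`.
#' @export
gen_cohort <- function(spec, identical_visits = FALSE) {
  resp <- with_seed(derive_seed(spec$seed, 99), {
    matrix(stats::runif(spec$n_subjects * length(spec$tasks)) <
             spec$responder_fraction,
           nrow = spec$n_subjects,
           dimnames = list(NULL, spec$tasks))
  })
  recordings <- vector("list", spec$n_subjects)
  truth <- list()
  for (s in seq_len(spec$n_subjects)) {
    recordings[[s]] <- vector("list", spec$n_visits)
    for (v in seq_len(spec$n_visits)) {
      v_eff <- if (identical_visits) 1L else v
      entry <- list()
      entry$baseline <- gen_recording(
        spec, seed = derive_seed(spec$seed, s, v_eff, 0),
        type = "baseline"
      )
      for (k in seq_along(spec$tasks)) {
        task <- spec$tasks[k]
        entry[[task]] <- gen_recording(
          spec, seed = derive_seed(spec$seed, s, v_eff, k),
          type = "task", responder = resp[s, task]
        )
        truth[[length(truth) + 1L]] <- data.frame(
          subject = s, visit = v, task = task,
          responder = resp[s, task],
          ari_baseline = spec$true_ari_baseline,
          ari_task = spec$true_ari_task,
          nvc_amplitude_pct = if (resp[s, task]) spec$nvc_amplitude_pct else 0
        )
      }
      recordings[[s]][[v]] <- entry
    }
  }
  structure(list(recordings = recordings, truth = do.call(rbind, truth),
                 spec = spec),
            class = "synthetic_cohort")
}
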