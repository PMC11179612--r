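# Shared fixtures: small synthetic signals built in code.

# Noise-free single-ARI recording at 5 Hz; returns the uniform data.frame.
fixture_recording <- function(ari, seed = 100 + ari, noise_sd_pct = 0,
                              noise_ref = "v0", duration_s = 180) {
  sp <- synth_spec(seed = seed, noise_sd_pct = noise_sd_pct,
                   noise_ref = noise_ref, nvc_amplitude_pct = 0,
                   map_rise_mmHg = 0, true_ari_baseline = ari,
                   true_ari_task = ari, duration_s = duration_s)
  gen_recording(sp, type = "task")
}

# Unstimulated percent-change MCAv curves (no NVC, no MAP task rise) on the
# -60..+120 s grid, as a matrix with one column per curve.
fixture_null_curves <- function(n_curves, seed, noise_sd_pct = 2) {
  sp <- synth_spec(seed = seed, noise_sd_pct = noise_sd_pct,
                   nvc_amplitude_pct = 0, map_rise_mmHg = 0)
  out <- vapply(seq_len(n_curves), function(i) {
    rec <- gen_recording(sp, seed = seed + 7 * i, type = "task",
                         responder = FALSE)
    rec$uniform$mcav_left_pct
  }, numeric(900))
  list(time_s = (0:899) / 5 - 60, curves = out)
}

# Synthetic ECG: unit impulses on a noise floor.
fixture_ecg <- function(beat_times, duration_s, fs = 500, noise_sd = 0.02,
                        seed = 1) {
  set.seed(seed)
  n <- round(duration_s * fs)
  ecg <- rnorm(n, sd = noise_sd)
  ecg[round(beat_times * fs) + 1] <- 1
  ecg
}
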