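# Tiecks autoregulation model: forward simulation, template generation,
# and ARI assignment with the coherence/NMSE acceptance gates.

test_that("parameter table is complete, ordered, with absent autoregulation at grade 0", {
  tab <- tiecks_param_table()
  expect_identical(tab$ari, 0:9)
  expect_equal(tab$K[1], 0)
  expect_true(!is.unsorted(tab$K))
  expect_true(all(tab$T > 0))
})

test_that("forward model tracks pressure exactly at K = 0 and reaches the closed-form fixed point", {
  rate <- 5
  n <- 60 * rate
  map <- c(rep(100, 10 * rate), rep(110, n - 10 * rate))
  # K = 0: V/v0 - 1 = dP, no recovery
  v <- tiecks_forward(map, rate, params = 0, v0 = 60, crcp = 12,
                      map_base = 100)
  dp <- (map - 100) / (100 - 12)
  expect_equal(v / 60 - 1, dp, tolerance = 1e-12)
  # sustained step: steady state V/v0 = 1 + d*(1 - K) for every grade
  tab <- tiecks_param_table()
  d <- (110 - 100) / (100 - 12)
  for (a in 1:9) {
    va <- tiecks_forward(map, rate, params = a, v0 = 60, crcp = 12,
                         map_base = 100)
    expect_equal(va[n] / 60, 1 + d * (1 - tab$K[a + 1]),
                 tolerance = 0.01 * d)
  }
  # constant pressure: V identically v0
  vc <- tiecks_forward(rep(95, n), rate, params = 7, v0 = 55, crcp = 12,
                       map_base = 95)
  expect_equal(vc, rep(55, n), tolerance = 1e-12)
})

test_that("model response is linear in the pressure deviation", {
  rate <- 5
  set.seed(77)
  base <- 100
  dev <- cadenza:::band_limited_noise(600, rate, c(0.02, 0.45), sd = 3)
  v1 <- tiecks_forward(base + dev, rate, 5, v0 = 60, map_base = base)
  v2 <- tiecks_forward(base + 2 * dev, rate, 5, v0 = 60, map_base = base)
  expect_equal(v2 - 60, 2 * (v1 - 60), tolerance = 1e-9)
})

test_that("oversampled recursion agrees with a plain-loop reference", {
  # direct transcription of the state recursion, no oversampling
  loop_ref <- function(dp, f, T, D, K) {
    x1 <- x2 <- 0
    out <- numeric(length(dp))
    for (i in seq_along(dp)) {
      x2n <- x2 + (x1 - 2 * D * x2) / (f * T)
      x1 <- x1 + (dp[i] - x2) / (f * T)
      x2 <- x2n
      out[i] <- dp[i] - K * x2
    }
    out
  }
  dp <- c(rep(0, 10), rep(1, 140))
  # grade with large T: no internal oversampling triggered, exact match
  expect_equal(cadenza:::tiecks_filter(dp, 5, 2.0, 0.9, 0.8),
               loop_ref(dp, 5, 2.0, 0.9, 0.8), tolerance = 1e-12)
  # grade with small T: oversampling approximates the same dynamics
  expect_equal(cadenza:::tiecks_filter(dp, 5, 0.65, 0.5, 0.98, oversample = 10),
               loop_ref(rep(dp, each = 10), 50, 0.65, 0.5, 0.98)[seq(10, 1500, 10)],
               tolerance = 1e-12)
  expect_error(cadenza:::tiecks_filter(dp, 5, 0.05, 0.5, 0.98, oversample = 1),
               "unstable")
})

test_that("templates recover faster with higher ARI and match fixed-point terminal values", {
  tpl <- make_templates(rate = 5, duration_s = 12)
  tt <- attr(tpl, "time_s")
  # ARI 0: no recovery, stays at the full step deviation
  expect_equal(unname(tpl[tt >= 1, "ari0"]),
               rep(1, sum(tt >= 1)), tolerance = 1e-9)
  # recovery at t = 10 s is monotone non-increasing in deviation with ARI
  at10 <- tpl[which.min(abs(tt - 10)), ]
  expect_true(all(diff(at10) < 1e-9))
  # strict ordering during the early recovery (before the underdamped
  # high-grade templates overshoot and oscillate across each other)
  win <- tt >= 0.4 & tt <= 2.4
  for (j in 1:9) expect_true(all(tpl[win, j + 1] < tpl[win, j] + 1e-9))
  # ARI 9 terminal value matches 1 - K9 for a unit step
  tab <- tiecks_param_table()
  long <- make_templates(rate = 5, duration_s = 60)
  expect_equal(unname(long[nrow(long), "ari9"]), 1 - tab$K[10],
               tolerance = 1e-3)
})

test_that("template self-fit is exact and the acceptance gate follows its truth table", {
  tpl <- make_templates(rate = 5, duration_s = 12)
  tt <- attr(tpl, "time_s")
  step7 <- list(time_s = tt, response = unname(tpl[, "ari7"]))
  est <- fit_ari(step7, tpl, mean_coherence = 0.8, coherence_limit = 0.5)
  expect_equal(est$ari, 7L)
  expect_equal(est$nmse, 0, tolerance = 1e-12)
  expect_true(est$accepted)
  # 2x2 truth table: accepted <=> coherence_pass AND nmse_pass
  noisy <- list(time_s = tt,
                response = unname(tpl[, "ari7"]) + 10 * sin(131 * tt))
  cases <- list(
    list(step = step7, coh = 0.8, lim = 0.5, acc = TRUE),
    list(step = step7, coh = 0.3, lim = 0.5, acc = FALSE),
    list(step = noisy, coh = 0.8, lim = 0.5, acc = FALSE),
    list(step = noisy, coh = 0.3, lim = 0.5, acc = FALSE)
  )
  for (cs in cases) {
    e <- fit_ari(cs$step, tpl, mean_coherence = cs$coh,
                 coherence_limit = cs$lim)
    expect_identical(e$accepted, e$coherence_pass && e$nmse_pass)
    expect_identical(e$accepted, cs$acc)
  }
  expect_error(fit_ari(list(time_s = tt, response = rep(1, length(tt))), tpl),
               "zero-variance")
})

test_that("white-noise step responses are rejected by the NMSE gate", {
  tpl <- make_templates(rate = 5, duration_s = 12)
  tt <- attr(tpl, "time_s")
  set.seed(61)
  rejected <- vapply(1:100, function(i) {
    stp <- list(time_s = tt, response = rnorm(length(tt)))
    fit_ari(stp, tpl, mean_coherence = 1, coherence_limit = 0.5)$nmse >= 0.3
  }, logical(1))
  expect_gte(mean(rejected), 0.95)
})

test_that("full pipeline recovers the true ARI exactly on noise-free recordings", {
  for (a in c(0, 3, 6, 9)) {
    rec <- fixture_recording(a, seed = 300 + a)
    u <- rec$uniform
    for (ch in c("mcav_left", "mcav_right")) {
      est <- estimate_ari(u$map_mmHg, u[[ch]], rate = 5,
                          segment_type = "task", limit_method = "analytic")
      expect_identical(est$ari, as.integer(a))
      expect_lt(est$nmse, 0.05)
      expect_true(est$accepted)
    }
  }
})

test_that("ARI estimation degrades gracefully under velocity noise", {
  errs <- unlist(lapply(c(3, 5, 7), function(a) {
    vapply(1:8, function(s) {
      rec <- fixture_recording(a, seed = 40 + 13 * s + a, noise_sd_pct = 10,
                               noise_ref = "signal_sd")
      u <- rec$uniform
      est <- estimate_ari(u$map_mmHg, u$mcav_left, rate = 5,
                          segment_type = "task", limit_method = "analytic")
      abs(est$ari - a)
    }, numeric(1))
  }))
  expect_lte(median(errs), 1)
})
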