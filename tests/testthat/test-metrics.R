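# Fatigue index, relative FI, vascular metrics and hyperaemic scope.

test_that("constant-amplitude twitch trains give FI = 1 and scaling leaves
           FI unchanged", {
  rec <- make_twitch_recording(function(t) 0.4 + 0 * t)
  expect_equal(fatigue_index(rec), 1, tolerance = 1e-9)
  rec2 <- rec
  rec2$tension <- rec2$tension * 3.7
  expect_equal(fatigue_index(rec2), fatigue_index(rec), tolerance = 1e-12)
})

test_that("FI of a noise-free exponential decay matches the closed-form
           5-twitch oracle", {
  amp <- function(t) 0.3 + 0.7 * exp(-t / 60)
  rec <- make_twitch_recording(amp)
  t_i <- seq(0, 179.9, by = 0.1)
  a_i <- amp(t_i)
  run5 <- vapply(5:length(a_i), function(k) mean(a_i[(k - 4):k]), 0)
  oracle <- mean(tail(a_i, 5)) / max(run5[seq_len(300)])
  expect_equal(fatigue_index(rec), oracle, tolerance = 1e-6)
  expect_gt(fatigue_index(rec), 0)
  expect_lte(fatigue_index(rec), 1)
})

test_that("undetectable twitches raise a quality error", {
  rec <- make_twitch_recording(function(t) 0 * t)
  set.seed(1)
  rec$tension <- abs(rnorm(length(rec$tension), 0, 1e-4))
  expect_error(fatigue_index(rec), "not detectable")
})

test_that("relative FI follows the configured direction convention", {
  expect_equal(relative_fi(0.5, 0.5), 1)
  expect_equal(relative_fi(0.5, 0.25), 0.5)
  expect_equal(relative_fi(0.5, 0.25, direction = "pre_over_post"), 2)
  expect_error(relative_fi(0, 0.5), "must lie in")
})

test_that("constant flow and pressure give the textbook FVC and zero
           amplitude", {
  rec <- make_twitch_recording(function(t) 0.4 + 0 * t,
                               flow = 1, pressure = 100, mass = 0.15)
  vm <- vascular_metrics(rec, "rest")
  expect_equal(vm$fvc, 1 / 100 / 0.15, tolerance = 1e-12)
  expect_equal(vm$flow_amplitude, 0, tolerance = 1e-12)
  expect_equal(vm$map, 100)
  # FVC scale covariance: doubling flow doubles FVC; doubling MAP halves it
  rec2 <- rec; rec2$flow <- rec$flow * 2
  expect_equal(vascular_metrics(rec2, "rest")$fvc, 2 * vm$fvc)
  rec3 <- rec; rec3$pressure <- rec$pressure * 2
  expect_equal(vascular_metrics(rec3, "rest")$fvc, vm$fvc / 2)
})

test_that("generated pulsatile traces round-trip their configured amplitude
           and window metrics are position invariant on stationary traces", {
  cfg <- generator_config(tension_noise_sd = 0, flow_noise_sd = 0,
                          fi_sd = 0, heart_rate = 5)
  rec <- generate_recording(cfg, 1, seed = 6)
  vm <- vascular_metrics(rec, "rest")
  expect_equal(vm$flow_amplitude, unname(rec$meta$flow_rest["amp"]),
               tolerance = 1e-9)
  expect_equal(vm$peak_flow, unname(rec$meta$flow_rest["peak"]),
               tolerance = 1e-9)
  expect_equal(vm$mean_flow, unname(rec$meta$flow_rest["mean"]),
               tolerance = 1e-6)
  # a second rest window 10 s earlier sees the same stationary statistics
  rec_shift <- rec
  rec_shift$stim$duration[1L] <- 20
  rec_shift$stim$onset[2L:3L] <- rec_shift$stim$onset[2L:3L] - 10
  vm2 <- vascular_metrics(rec_shift, "rest")
  expect_equal(vm2$mean_flow, vm$mean_flow, tolerance = 1e-6)
  expect_equal(vm2$flow_amplitude, vm$flow_amplitude, tolerance = 1e-9)
})

test_that("Table-style group means produce the printed conductance and
           scope arithmetic", {
  # 8.13 ml/min/g at 123 mmHg -> FVC 0.0661; printed rounding gives 0.067
  expect_equal(8.13 / 123, 0.0661, tolerance = 1e-3)
  expect_equal(hyperaemic_scope(0.067, 0.100), 1.4925, tolerance = 1e-4)
  expect_equal(hyperaemic_scope(0.05, 0.05), 1)
  expect_error(hyperaemic_scope(0, 0.1), "positive")
})

test_that("analyze_recording assembles a consistent summary", {
  cfg <- generator_config(tension_noise_sd = 0, flow_noise_sd = 0, fi_sd = 0)
  rec <- generate_recording(cfg, 1, seed = 2)
  ms <- analyze_recording(rec, pre_fi = 0.5)
  expect_equal(ms$hyperaemic_scope, ms$end_stim$fvc / ms$rest$fvc,
               tolerance = 1e-12)
  expect_equal(ms$rel_fi, ms$fi / 0.5, tolerance = 1e-12)
  expect_equal(ms$rest$fvc * ms$rest$map, ms$rest$mean_flow,
               tolerance = 1e-9)
})
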