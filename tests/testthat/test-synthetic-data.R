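# Generator: determinism, feasibility, anatomical invariants, linkage,
# recording construction.

test_that("identical config and seed reproduce sections and recordings
           byte-identically", {
  cfg <- generator_config(section_width = 700, section_height = 700)
  s1 <- generate_section(cfg, 42)
  s2 <- generate_section(cfg, 42)
  expect_identical(s1, s2)
  s3 <- generate_section(cfg, 43)
  expect_false(identical(s1$capillaries, s3$capillaries))

  r1 <- generate_recording(cfg, 0.8, seed = 7)
  r2 <- generate_recording(cfg, 0.8, seed = 7)
  expect_identical(r1, r2)
})

test_that("config validation rejects malformed inputs", {
  expect_error(generator_config("martian"), "unknown group preset")
  expect_error(generator_config(fibre_type_fractions = c(0.5, 0.4, 0.2)),
               "summing to 1")
  expect_error(generator_config(tension_noise_sd = -1), "non-negative")
  expect_error(generator_config(target_cf_ratio = -2), "positive")
})

test_that("infeasible morphometric targets raise an explicit error", {
  # C:F so high that implied fibres cannot hold their CSA targets
  cfg <- generator_config(target_capillary_density = 2500,
                          target_cf_ratio = 1.0)
  expect_error(generate_section(cfg, 1), "infeasible")
})

test_that("zero capillary density yields a fibre mosaic with no capillaries", {
  cfg <- generator_config(target_capillary_density = 0,
                          section_width = 600, section_height = 600)
  sec <- generate_section(cfg, 1)
  expect_equal(nrow(sec$capillaries), 0L)
  expect_gt(nrow(sec$fibre_meta), 50L)
})

test_that("capillaries sit on fibre boundaries, inside bounds, and supply
           units partition them with the minimum size", {
  cfg <- generator_config(section_width = 700, section_height = 700)
  sec <- generate_section(cfg, 5)
  caps <- sec$capillaries
  expect_true(all(caps$x >= 0 & caps$x <= 700 &
                  caps$y >= 0 & caps$y <= 700))
  expect_false(anyNA(caps$unit_id))
  expect_true(all(table(caps$unit_id) >= cfg$supply_unit_min_size))
  idx <- seq(1L, nrow(caps), length.out = 60L)
  d <- vapply(idx, function(i) {
    min_dist_to_fibre_edge(caps$x[i], caps$y[i], sec$fibres)
  }, 0)
  expect_lt(max(d), 2)
})

test_that("realized type-specific fibre CSAs track the configured means", {
  for (g in c("control", "OV")) {
    cfg <- generator_config(g, section_width = 900, section_height = 900)
    sec <- generate_section(cfg, 11)
    got <- vapply(c("I", "IIa", "IIb/IIx"), function(tp) {
      mean(sec$fibre_meta$csa[sec$fibre_meta$type == tp])
    }, 0)
    expect_lt(max(abs(got - cfg$fibre_csa_means) / cfg$fibre_csa_means), 0.1)
  }
})

test_that("the perfusion-FI linkage passes through its anchors and is
           non-decreasing", {
  expect_equal(rel_fi_linkage(0.755), 0.77)
  expect_equal(rel_fi_linkage(1), 1)
  expect_equal(rel_fi_linkage(0.95), 1)
  expect_equal(rel_fi_linkage(0.1), 0.3)
  p <- seq(0, 1, by = 0.005)
  expect_true(all(diff(rel_fi_linkage(p)) >= -1e-12))
  expect_error(rel_fi_linkage(1.2), "must lie in")
})

test_that("noise-free recordings reproduce the target fatigue index through
           the metrics stage", {
  cfg <- generator_config(tension_noise_sd = 0, flow_noise_sd = 0, fi_sd = 0)
  rec <- generate_recording(cfg, perfusion_index = 1, seed = 3)
  expect_equal(fatigue_index(rec), 0.47, tolerance = 1e-6)
  # no-fatigue limit: baseline FI 1 gives constant twitch amplitudes
  rec1 <- generate_recording(cfg, perfusion_index = 1, seed = 3,
                             fi_baseline = 1)
  expect_equal(fatigue_index(rec1), 1, tolerance = 1e-9)
})

test_that("recordings respect physiological trace invariants", {
  cfg <- generator_config("chronic_MS")
  rec <- generate_recording(cfg, seed = 9)
  expect_true(all(rec$tension >= 0))
  expect_true(all(rec$flow > 0))
  expect_true(all(rec$pressure > 0))
  expect_length(rec$tension, length(rec$time))
  expect_length(rec$flow, length(rec$time))
  expect_length(rec$pressure, length(rec$time))
  expect_error(generate_recording(cfg, perfusion_index = 1.4, seed = 1),
               "must lie in")
})

test_that("control pressure preset is reproduced in the trace", {
  cfg <- generator_config(tension_noise_sd = 0, flow_noise_sd = 0, fi_sd = 0,
                          heart_rate = 5)
  # average MAP / pulse pressure over animals approaches 123 / 12.2 mmHg
  maps <- pps <- numeric(15)
  for (s in seq_len(15)) {
    rec <- generate_recording(cfg, 1, seed = s)
    vm <- vascular_metrics(rec, "rest")
    maps[s] <- vm$map
    pps[s] <- vm$pulse_pressure
  }
  expect_lt(abs(mean(maps) - 123), 8)
  expect_lt(abs(mean(pps) - 12.2), 6)
})

test_that("cohorts carry preset structure: ids, doses, hypertrophy", {
  co <- generate_cohort(1, seed = 2)
  expect_equal(nrow(co$animals), 5L)
  expect_false(anyDuplicated(co$animals$animal) > 0)
  expect_error(generate_cohort(2, groups = "krypton"), "unknown group")

  ov <- generate_cohort(40, seed = 3, groups = "OV")
  ratio <- ov$animals$edl_mass_g / ov$animals$edl_mass_contra_g
  expect_lt(abs(mean(ratio) - 1.19) / 1.19, 0.05)

  ac <- generate_cohort(25, seed = 4, groups = "acute_MS")
  expect_true(all(ac$animals$dose_spheres >= 1e5 &
                  ac$animals$dose_spheres <= 1.4e6))
  # heavier acute doses lower the perfusion index on average
  fit <- fit_ols(ac$animals$dose_spheres, ac$animals$perfusion_index, 1)
  expect_lt(fit$coefficients["b1"], 0)
})

test_that("derived seeds are stable and distinct across index paths", {
  expect_identical(derive_seed(1, 2, 3), derive_seed(1, 2, 3))
  s <- vapply(1:200, function(i) derive_seed(7, i), 1L)
  expect_false(anyDuplicated(s) > 0)
  expect_true(all(s > 0))
})
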