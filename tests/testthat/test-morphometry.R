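# Counting frames, Voronoi domains, capillarity summaries and the domain
# histogram.

test_that("systematic random frames are equidistant, non-overlapping and
           deterministic", {
  cfg <- generator_config(section_width = 2000, section_height = 600,
                          target_capillary_density = 300)
  sec <- generate_section(cfg, 1)
  frs <- place_counting_frames(sec, n = 3, side = 475, seed = 5)
  x0 <- vapply(frs, function(f) f$origin[1L], 0)
  expect_equal(diff(x0), rep(2000 / 3, 2), tolerance = 1e-9)
  expect_true(all(diff(x0) >= 475))              # non-overlapping
  frs2 <- place_counting_frames(sec, n = 3, side = 475, seed = 5)
  expect_identical(frs, frs2)
  # width exactly n * side forces offset 0, tiling edge to edge
  cfg2 <- generator_config(section_width = 3 * 475, section_height = 600,
                           target_capillary_density = 300)
  sec2 <- generate_section(cfg2, 1)
  fr3 <- place_counting_frames(sec2, n = 3, side = 475, seed = 99)
  expect_equal(fr3[[1L]]$origin[1L], 0)
  expect_equal(fr3[[3L]]$origin[1L] + 475, 3 * 475)
  expect_error(place_counting_frames(sec2, n = 4, side = 475),
               "too small")
})

test_that("single and symmetric capillary layouts give exact domain areas", {
  fr <- counting_frame(c(0, 0), 475)
  one <- compute_domains(data.frame(x = 237.5, y = 237.5), fr)
  expect_equal(one$domains$area, 225625)
  quad <- compute_domains(
    data.frame(x = c(118.75, 356.25, 118.75, 356.25),
               y = c(118.75, 118.75, 356.25, 356.25)), fr)
  expect_equal(quad$domains$area, rep(56406.25, 4))
  expect_error(compute_domains(data.frame(x = 900, y = 900), fr),
               "no capillaries")
})

test_that("clipped Voronoi domains conserve frame area and match the pixel
           oracle", {
  set.seed(10)
  fr <- counting_frame(c(0, 0), 200)
  caps <- data.frame(x = runif(30, 0, 200), y = runif(30, 0, 200))
  dom <- compute_domains(caps, fr)
  expect_equal(sum(dom$domains$area), 200^2, tolerance = 1e-9)
  pa <- pixel_domain_areas(dom$domains$x, dom$domains$y,
                           c(0, 200), c(0, 200), px = 0.25)
  expect_lt(max(abs(pa - dom$domains$area) / dom$domains$area), 0.01)
})

test_that("the unbiased edge rule excludes exclusion-edge capillaries and is
           translation invariant", {
  fr <- counting_frame(c(0, 0), 100)
  caps <- data.frame(x = c(0, 50, 100, 30), y = c(50, 0, 60, 100))
  dom <- compute_domains(caps, fr)
  # (0,50) on left and (50,0) on bottom excluded; (100,60) right and
  # (30,100) top included
  expect_equal(nrow(dom$domains), 2L)
  set.seed(11)
  caps2 <- data.frame(x = runif(40, 0, 100), y = runif(40, 0, 100))
  d0 <- compute_domains(caps2, fr)
  shift <- c(123.4, -56.7)
  caps3 <- data.frame(x = caps2$x + shift[1L], y = caps2$y + shift[2L])
  d1 <- compute_domains(caps3, counting_frame(shift, 100))
  expect_equal(d1$domains$area, d0$domains$area, tolerance = 1e-9)
})

test_that("summaries satisfy the capillarity identities", {
  cfg <- generator_config(section_width = 700, section_height = 700)
  sec <- generate_section(cfg, 21)
  fr <- place_counting_frames(sec, n = 1, side = 475, seed = 1)[[1L]]
  ms <- summarize_morphometry(sec, fr)
  expect_equal(ms$cd_anatomical * ms$cda_anatomical, 1e6,
               tolerance = 0.005)
  expect_lte(ms$cd_perfused, ms$cd_anatomical)
  expect_gte(ms$perfusion_index, 0)
  expect_lte(ms$perfusion_index, 1)
  expect_equal(sum(ms$fibre_type_pct), 100, tolerance = 1e-9)
  # re-tessellated perfused domains are at least as large on average
  expect_gte(ms$cda_perfused, ms$cda_anatomical - 1e-9)
  # all-perfused section gives index exactly 1
  sec$capillaries$perfused <- TRUE
  expect_equal(summarize_morphometry(sec, fr)$perfusion_index, 1)
})

test_that("perfectly regular lattices have zero spacing heterogeneity", {
  fr <- counting_frame(c(0, 0), 400)
  g <- expand.grid(x = seq(25, 375, by = 50), y = seq(25, 375, by = 50))
  dom <- compute_domains(g, fr)
  ms_logsd <- sd(log10(dom$domains$eq_radius))
  expect_equal(ms_logsd, 0, tolerance = 1e-12)
})

test_that("domain histograms use half-open 200-unit bins and normalise to
           100 percent", {
  h <- bin_domain_distribution(rep(300, 7))
  expect_equal(h$bin, "201-400")
  expect_equal(h$percent, 100)
  # boundary value 200 falls in the first bin under (0, 200]
  h2 <- bin_domain_distribution(c(200, 200.0001))
  expect_equal(h2$bin, c("1-200", "201-400"))
  set.seed(3)
  h3 <- bin_domain_distribution(rexp(500, 1 / 1500))
  expect_equal(sum(h3$percent), 100, tolerance = 1e-9)
})

test_that("removing capillaries from the perfused set never shrinks mean
           perfused domain area", {
  cfg <- generator_config(section_width = 700, section_height = 700)
  sec <- generate_section(cfg, 31)
  fr <- place_counting_frames(sec, n = 1, side = 475, seed = 1)[[1L]]
  sec$capillaries$perfused <- TRUE
  set.seed(12)
  drop_order <- sample.int(nrow(sec$capillaries))
  cdas <- vapply(c(0, 0.2, 0.4, 0.6), function(fr_drop) {
    s <- sec
    s$capillaries$perfused[
      drop_order[seq_len(floor(fr_drop * length(drop_order)))]] <- FALSE
    summarize_morphometry(s, fr)$cda_perfused
  }, 0)
  expect_true(all(diff(cdas) > -1e-9))
})

test_that("degenerate summaries raise informative errors", {
  fr <- counting_frame(c(0, 0), 100)
  dom <- compute_domains(data.frame(x = 50, y = 50), fr)
  expect_error(
    summarize_morphometry(dom, fr,
                          fibres = data.frame(type = character(0),
                                              csa = numeric(0),
                                              cx = numeric(0),
                                              cy = numeric(0))),
    "undefined")
})
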