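# PO2 solver: exact degenerate cases, the Krogh-Erlang closed form,
# conservation, maximum principle, facilitation and sink-removal
# monotonicity.

small_frame <- counting_frame(c(0, 0), 60)
five_caps <- data.frame(x = c(15, 45, 30, 12, 48), y = c(15, 18, 42, 48, 45))

test_that("zero demand returns a uniform field at capillary PO2", {
  f <- solve_po2(five_caps, small_frame, demand = 0, h = 2)
  expect_lt(max(abs(f$po2 - 40)), 1e-8)
})

test_that("the radial solver reproduces the Krogh-Erlang closed form", {
  pars <- transport_params(D_Mb = 0)
  r_t <- 10e-4
  sol <- solve_po2_radial(pars, r_t = r_t, h = 0.5, demand = "max",
                          consumption = "constant")
  exact <- krogh_erlang(sol$r, pars, r_t = r_t)
  drop <- pars$P_cap - min(exact)
  expect_gt(drop, 5)                      # a non-trivial profile
  expect_lt(max(abs(sol$po2 - exact)) / drop, 0.01)
})

test_that("radial grid refinement converges at second order", {
  pars <- transport_params(D_Mb = 0)
  r_t <- 10e-4
  errs <- vapply(c(2, 1, 0.5), function(h) {
    sol <- solve_po2_radial(pars, r_t = r_t, h = h, consumption = "constant")
    max(abs(sol$po2 - krogh_erlang(sol$r, pars, r_t = r_t)))
  }, 0)
  expect_true(all(diff(errs) < 0))
  order1 <- log2(errs[1L] / errs[2L])
  order2 <- log2(errs[2L] / errs[3L])
  expect_gt(min(order1, order2), 1.5)
  expect_lt(max(order1, order2), 2.6)
})

test_that("2-D grid refinement is monotone with observed order near 2", {
  # a grid-resolved capillary disc; sub-grid discs limit the observable order
  pars <- transport_params(r_c = 8e-4)
  caps <- data.frame(x = 30, y = 30)
  means <- vapply(c(2, 1, 0.5), function(h) {
    f <- solve_po2(caps, small_frame, pars, demand = "max", h = h)
    mean(f$po2)
  }, 0)
  d1 <- abs(means[2L] - means[1L])
  d2 <- abs(means[3L] - means[2L])
  expect_lt(d2, d1)
  expect_gt(log2(d1 / d2), 1.2)
  expect_lt(log2(d1 / d2), 2.8)
})

test_that("interior PO2 respects the maximum principle and stays
           non-negative", {
  f <- solve_po2(five_caps, small_frame, demand = "max", h = 1)
  expect_lte(max(f$po2), 40 + 1e-9)
  expect_gte(min(f$po2), 0)
})

test_that("capillary efflux balances total consumption at convergence", {
  f <- solve_po2(five_caps, small_frame, demand = "max", h = 1)
  fb <- po2_flux_balance(f)
  expect_lt(fb$rel_imbalance, 0.01)
  fc <- solve_po2(five_caps, small_frame, demand = 2e-5, h = 1,
                  consumption = "constant")
  expect_lt(po2_flux_balance(fc)$rel_imbalance, 0.01)
})

test_that("myoglobin facilitation never increases the hypoxic fraction", {
  lone <- data.frame(x = 30, y = 30)
  f_mb <- solve_po2(lone, small_frame, transport_params(), demand = "max",
                    h = 1)
  f_no <- solve_po2(lone, small_frame, transport_params(D_Mb = 0),
                    demand = "max", h = 1)
  hf_mb <- hypoxic_fraction(f_mb)$hypoxic_fraction
  hf_no <- hypoxic_fraction(f_no)$hypoxic_fraction
  expect_lte(hf_mb, hf_no)
  expect_gte(mean(f_mb$po2), mean(f_no$po2))
})

test_that("removing a perfused capillary never decreases the hypoxic
           fraction", {
  f_all <- solve_po2(five_caps, small_frame, demand = "max", h = 2)
  f_less <- solve_po2(five_caps[-3L, ], small_frame, demand = "max", h = 2)
  expect_gte(hypoxic_fraction(f_less)$hypoxic_fraction,
             hypoxic_fraction(f_all)$hypoxic_fraction)
})

test_that("hypoxic fraction handles the trivial and degenerate fields", {
  f <- solve_po2(five_caps, small_frame, demand = 0, h = 2)
  expect_equal(hypoxic_fraction(f)$hypoxic_fraction, 0)
  expect_warning(
    f0 <- solve_po2(five_caps[0L, ], small_frame, demand = "max", h = 2),
    "degenerate")
  expect_true(f0$degenerate)
  expect_equal(hypoxic_fraction(f0)$hypoxic_fraction, 1)
})

test_that("demand sweeps order rest below maximal and scale linearly in the
           zero-demand limit", {
  sw <- demand_sweep(five_caps, small_frame, demands = c("rest", "max"),
                     h = 2)
  expect_lte(sw$hypoxic_fraction[1L], sw$hypoxic_fraction[2L])
  expect_gte(sw$mean_po2[1L], sw$mean_po2[2L])
  p40 <- transport_params(P_cap = 40)
  p80 <- transport_params(P_cap = 80)
  f40 <- solve_po2(five_caps, small_frame, p40, demand = 0, h = 2)
  f80 <- solve_po2(five_caps, small_frame, p80, demand = 0, h = 2)
  expect_equal(f80$po2, 2 * f40$po2, tolerance = 1e-9)
})

test_that("solver rejects too-coarse grids and reports non-convergence with
           diagnostics", {
  expect_error(solve_po2(five_caps, small_frame, h = 5), "h must be <= 2")
  expect_error(
    solve_po2(five_caps, small_frame, demand = "max", h = 2,
              max_iter = 2L, relax = 0.3),
    "converge")
})
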