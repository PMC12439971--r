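test_that("the reference grid matches the stated spacing", {
  g <- reference_grid()
  expect_equal(length(g$x), 1000L)
  expect_equal(range(g$x), c(1e-20, 1e20))
  expect_equal(diff(log10(g$x))[1], 40 / 999, tolerance = 1e-12)
  expect_true(all(diff(g$x) > 0))
  expect_error(concentration_grid(1, 0.1), "xmax")
})

test_that("unregulated ladders give flat curves and zero dynamic range", {
  sp <- ladder_spec(3L, c(0.7, 2), c(1.1, 3), kon = 2, koff = 0.5, r = 4)
  cv <- compute_response_curves(sp, concentration_grid(n = 200L))
  expect_lt(diff(range(cv$ss_bar)), 1e-9)
  expect_lt(diff(range(cv$raw_mfpt)) / max(cv$raw_mfpt), 1e-9)
  dr <- dynamic_ranges(cv)
  expect_lt(dr[["delta_ss"]], 1e-9)
  expect_lt(dr[["delta_mfpt"]], 1e-9)
})

test_that("curve normalizations and bounds hold across regimes", {
  specs <- list(sym_d3_spec(10^-0.5, 10, 10, g23 = 10),
                named_model_families()$equal_rates(0.5, 2),
                sym_d3_spec(0.3, 2, 7, g21 = 0.2, g23 = 30, kon = 3, koff = 0.1))
  for (sp in specs) {
    cv <- compute_response_curves(sp, concentration_grid(n = 300L))
    expect_true(all(cv$ss_bar >= 0 & cv$ss_bar <= 1))
    expect_true(all(cv$mfpt_bar > 0 & cv$mfpt_bar <= 1))
    expect_equal(max(cv$mfpt_bar), 1)
    expect_equal(cv$raw_ss, cv$ss_bar * sp$r / sp$delta)
    dr <- dynamic_ranges(cv)
    expect_true(all(dr >= 0 & dr <= 1))
  }
})

test_that("the symmetric case starts at a steady-state level of one third", {
  sp <- sym_d3_spec(1, 1, 10, g23 = 10)
  cv <- compute_response_curves(sp, concentration_grid(include_zero = TRUE,
                                                       n = 200L))
  expect_equal(attr(cv, "zero")[["ss_bar"]], 1 / 3, tolerance = 1e-12)
  expect_equal(cv$ss_bar[1], 1 / 3, tolerance = 1e-9)
})

test_that("the coupling score follows its defining identities", {
  expect_equal(coupling_score(1, 0), 0)   # perfect decoupling
  expect_equal(coupling_score(0.3, 0.3), 1)
  expect_gt(coupling_score(0.2, 0.5), 1)  # mFPT varies more than SS
  expect_equal(coupling_score(0, 1), 2)
  expect_error(coupling_score(1.2, 0), "0, 1")
  expect_error(coupling_score(0.5, -0.1), "0, 1")
})

test_that("activator ladders respond monotonically in the expected directions", {
  for (sp in list(ladder_spec(2L, 1, 1, fwd_gamma = 5, kon = 1, koff = 1, r = 2),
                  ladder_spec(2L, 1, 1, bwd_gamma = 0.2, kon = 1, koff = 1, r = 2),
                  sym_d3_spec(1, 2, 3, g23 = 20))) {
    cv <- compute_response_curves(sp, concentration_grid(n = 300L))
    expect_true(monotonicity_check(cv$ss_bar, "increasing"))
    expect_true(monotonicity_check(cv$mfpt_bar, "decreasing"))
  }
  expect_true(monotonicity_check(c(1, 2, 3)))
  expect_false(monotonicity_check(c(1, 3, 2)))
  # incoherent regulation can break monotonicity of the activation time
  spi <- named_model_families()$equal_rates(0.2, 5)
  cvi <- compute_response_curves(spi, concentration_grid(n = 300L))
  expect_false(monotonicity_check(cvi$mfpt_bar, "decreasing") &&
                 monotonicity_check(cvi$mfpt_bar, "increasing"))
})

test_that("equilibrium-start weights are the unbound-chain steady state", {
  # symmetric unbound chain: uniform weights
  sp <- sym_d3_spec(2, 2, 1, g23 = 5)
  w <- steady_state_gth(unbound_chain(sp))
  expect_equal(unname(w), rep(1 / 3, 3))
  t_each <- mfpt_linear_solve(augment_with_terminal(
    instantiate_ladder(sp, 0.7), productive_vertices(sp), sp$r))
  expect_equal(equilibrium_start_mfpt(sp, 0.7),
               mean(t_each[c("U1", "U2", "U3")]))
  # curves in equilibrium mode average over the unbound states
  cv <- compute_response_curves(sp, concentration_grid(n = 50L),
                                start_mode = "equilibrium_unbound")
  i <- 25L
  expect_equal(cv$raw_mfpt[i], equilibrium_start_mfpt(sp, cv$x[i]),
               tolerance = 1e-12)
})

test_that("half-activation interpolates and argmin breaks ties leftward", {
  sp <- sym_d3_spec(1, 1, 10, g23 = 10, kon = 2, koff = 1)
  cv <- compute_response_curves(sp)
  hx <- half_activation_and_fastest(cv)
  ss_norm <- (cv$ss_bar - min(cv$ss_bar)) / diff(range(cv$ss_bar))
  below <- max(cv$x[ss_norm < 0.5])
  above <- min(cv$x[ss_norm >= 0.5])
  expect_gt(hx[["x_half"]], below)
  expect_lte(hx[["x_half"]], above)

  # flat activation time: the tie rule picks the smallest grid point
  spf <- ladder_spec(3L, c(1, 1), c(1, 1), kon = 1, koff = 1, r = 1)
  cvf <- compute_response_curves(spf, concentration_grid(n = 100L))
  hxf <- half_activation_and_fastest(cvf)
  expect_equal(hxf[["x_fast"]], cvf$x[1])
  expect_true(is.na(hxf[["x_half"]]))
})

test_that("interval overlap follows the stated formula", {
  expect_equal(interval_overlap(c(0, 2), c(1, 3)), 0.25)
  expect_equal(interval_overlap(c(0, 1), c(2, 3)), 0)
  expect_equal(interval_overlap(c(1, 4), c(1, 4)), 0.5)
  # flat curves are flagged rather than scored
  x <- 10^seq(-3, 3, length.out = 50)
  ov <- response_overlap(x, rep(0.5, 50), seq(0, 1, length.out = 50))
  expect_true(is.na(ov))
  # identical curves overlap by half
  y <- stats::plogis(log10(x))
  expect_equal(response_overlap(x, y, y), 0.5, tolerance = 1e-12)
})

test_that("chain models have concentration-independent responses", {
  cs <- chain_spec(3L, c(1, 2), c(0.5, 0.3), r = 2)
  cv <- compute_response_curves(cs, concentration_grid(n = 50L))
  expect_equal(diff(range(cv$raw_mfpt)), 0)
  expect_equal(dynamic_ranges(cv)[["delta_ss"]], 0)
  # function-valued rates reproduce ligand regulation of the 2 -> 1 edge:
  # with fast production the activation time stays flat while the
  # steady-state level responds
  cs2 <- chain_spec(2L, fwd_rates = 1,
                    bwd_rates = list(function(x) 1 + 10 * x / (1 + x)),
                    r = 1e5)
  cv2 <- compute_response_curves(cs2, concentration_grid(1e-3, 1e3, 100L))
  dr2 <- dynamic_ranges(cv2)
  # SS falls from 1/2 to 1/12 as the deactivation rate rises from 1 to 11
  expect_equal(dr2[["delta_ss"]], 1 / 2 - 1 / 12, tolerance = 1e-2)
  expect_lt(dr2[["delta_mfpt"]], 1e-3)
})

test_that("the decoupling summary ties the diagnostics together", {
  sp <- named_model_families()$rate_scale_sweep(10^-0.5)
  sm <- decoupling_summary(compute_response_curves(sp))
  expect_equal(sm$f, 1 - sm$delta_ss + sm$delta_mfpt)
  expect_true(sm$ss_monotonic)
  expect_true(sm$mfpt_monotonic)
  expect_equal(sm$x_half, 1, tolerance = 0.5)  # koff/kon = 1, order of magnitude
})
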