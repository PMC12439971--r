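# The closed forms are checked two ways: against the numeric grid pipeline
# (here and in the acceptance suite) and against exact symbolic derivation
# via the limiting chains (acceptance suite).

grid_ranges <- function(spec) dynamic_ranges(compute_response_curves(spec))

test_that("two-state activation time and its large-r limit", {
  expect_equal(c2_mfpt(1, 1, 1), 3)
  expect_equal(c2_mfpt(2, 1, 1e12), 1 / 2, tolerance = 1e-9)
  g <- c2_plus(0.3, 4, 7)
  expect_equal(mfpt_recurrence(g)[["1"]], c2_mfpt(0.3, 4, 7))
})

test_that("two-rung closed forms match grid numerics for both regulated edges", {
  # forward regulation
  cf <- d2_dynamic_ranges("forward", gamma = 4, l12 = 1.5, l21 = 0.7, r = 2)
  sp <- ladder_spec(2L, 1.5, 0.7, fwd_gamma = 4, kon = 1, koff = 1, r = 2)
  expect_equal(unname(grid_ranges(sp)), unname(cf), tolerance = 1e-4)
  # r -> infinity keeps a finite activation-time range (gamma - 1)/gamma
  cf_inf <- d2_dynamic_ranges("forward", 4, 1.5, 0.7, r = 1e9)
  expect_equal(cf_inf[["delta_mfpt"]], 3 / 4, tolerance = 1e-6)

  # backward regulation
  cf <- d2_dynamic_ranges("backward", gamma = 0.3, l12 = 2, l21 = 5, r = 3)
  sp <- ladder_spec(2L, 2, 5, bwd_gamma = 0.3, kon = 1, koff = 1, r = 3)
  expect_equal(unname(grid_ranges(sp)), unname(cf), tolerance = 1e-4)
  # r -> infinity kills the activation-time range but not the steady state
  cf_inf <- d2_dynamic_ranges("backward", 0.3, 2, 5, r = 1e9)
  expect_lt(cf_inf[["delta_mfpt"]], 1e-8)
  expect_equal(cf_inf[["delta_ss"]], cf[["delta_ss"]])

  expect_error(d2_dynamic_ranges("forward", 0.5, 1, 1, 1), "gamma > 1")
  expect_error(d2_dynamic_ranges("backward", 2, 1, 1, 1), "gamma < 1")
})

test_that("single-regulation ladder closed forms match grid numerics", {
  cases <- list(
    list(case = "1.I", g = 6, args = list(g12 = 6)),
    list(case = "1.II", g = 0.2, args = list(g21 = 0.2)),
    list(case = "1.III", g = 10, args = list(g23 = 10)),
    list(case = "1.IV", g = 0.15, args = list(g32 = 0.15)))
  for (cs in cases) {
    l12 <- 0.4; l23 <- 3; r <- 5
    cf <- d3_single_case_ranges(cs$case, cs$g, alpha = l23 / l12, beta = r / l12)
    sp <- do.call(sym_d3_spec, c(list(l12 = l12, l23 = l23, r = r), cs$args))
    expect_equal(unname(grid_ranges(sp)), unname(cf), tolerance = 1e-4,
                 label = cs$case)
  }
  # saturation of the steady-state range in case 1.III
  expect_equal(d3_single_case_ranges("1.III", 1e12, 1, 1)[["delta_ss"]],
               2 / 3, tolerance = 1e-10)
  expect_error(d3_single_case_ranges("1.III", 0.5, 1, 1), "gamma > 1")
})

test_that("double-regulation ladder closed forms match grid numerics", {
  cases <- list(
    list(case = "2.I", g1 = 3, g2 = 7, args = list(g12 = 3, g23 = 7)),
    list(case = "2.II", g1 = 3, g2 = 0.4, args = list(g12 = 3, g32 = 0.4)),
    list(case = "2.III", g1 = 0.4, g2 = 7, args = list(g21 = 0.4, g23 = 7)),
    list(case = "2.IV", g1 = 0.4, g2 = 0.3, args = list(g21 = 0.4, g32 = 0.3)))
  for (cs in cases) {
    l12 <- 0.5; l23 <- 2; r <- 4
    cf <- d3_double_case_ranges(cs$case, cs$g1, cs$g2,
                                alpha = l23 / l12, beta = r / l12)
    sp <- do.call(sym_d3_spec, c(list(l12 = l12, l23 = l23, r = r), cs$args))
    expect_equal(unname(grid_ranges(sp)), unname(cf), tolerance = 1e-4,
                 label = cs$case)
  }
})

test_that("each double-regulation form reduces to its single-edge case", {
  a <- 4.2; b <- 0.9
  expect_equal(d3_double_case_ranges("2.I", 5, 1 + 1e-14, a, b),
               d3_single_case_ranges("1.I", 5, a, b), tolerance = 1e-10)
  expect_equal(d3_double_case_ranges("2.I", 1 + 1e-14, 5, a, b),
               d3_single_case_ranges("1.III", 5, a, b), tolerance = 1e-10)
  expect_equal(d3_double_case_ranges("2.II", 1 + 1e-14, 0.3, a, b),
               d3_single_case_ranges("1.IV", 0.3, a, b), tolerance = 1e-10)
  expect_equal(d3_double_case_ranges("2.III", 0.3, 1 + 1e-14, a, b),
               d3_single_case_ranges("1.II", 0.3, a, b), tolerance = 1e-10)
  expect_equal(d3_double_case_ranges("2.IV", 0.3, 1 - 1e-14, a, b),
               d3_single_case_ranges("1.II", 0.3, a, b), tolerance = 1e-10)
})

test_that("rate scale separation kills the activation-time range in 2.III/2.IV", {
  big <- 1e6
  for (cs in c("2.III", "2.IV")) {
    cf <- d3_double_case_ranges(cs, 0.4, if (cs == "2.III") 7 else 0.3,
                                alpha = big, beta = big)
    expect_lt(cf[["delta_mfpt"]], 1e-4)
    expect_gt(cf[["delta_ss"]], 0.1)
  }
})

test_that("the zero-ligand activation time matches the unbound-chain solve", {
  expect_equal(d3_mfpt_at_zero(1, 1, 1), 6)
  for (i in 1:20) {
    set.seed(i)
    l12 <- 10^stats::runif(1, -2, 2)
    al <- 10^stats::runif(1, -2, 2)
    be <- 10^stats::runif(1, -2, 2)
    sp <- sym_d3_spec(l12, al * l12, be * l12)
    uc <- unbound_chain(sp)
    gp <- augment_with_terminal(uc, "U3", sp$r)
    expect_equal(mfpt_linear_solve(gp)[["U1"]], d3_mfpt_at_zero(l12, al, be),
                 tolerance = 1e-10)
  }
  # alpha, beta >> 1: the slow unregulated transition sets the time
  expect_equal(d3_mfpt_at_zero(0.5, 1e8, 1e8), 2, tolerance = 1e-7)
})

test_that("the incoherent balance factor equalizes the activation-time endpoints", {
  expect_equal(incoherent_balance_gamma(2), 0.5)
  expect_equal(incoherent_balance_gamma(1), 1)
  expect_error(incoherent_balance_gamma(0.4), "pole|2/5")
  for (g23 in c(0.6, 0.9, 1.5, 4, 50)) {
    g12 <- incoherent_balance_gamma(g23)
    expect_equal(g12 > 1, g23 < 1)
    u <- 1.3
    sp <- named_model_families()$equal_rates(g12, g23, rate = u)
    t0 <- mfpt_u1_endpoints(sp)
    expect_equal(t0[["at_zero"]], t0[["at_infinity"]], tolerance = 1e-6)
  }
})
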