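test_that("steady states of small graphs match spanning-tree enumeration", {
  # two-state cycle: rho = (l21, l12)
  expect_equal(unname(steady_state_decomposition(two_cycle(2, 1))),
               c(1 / 3, 2 / 3))
  expect_equal(unname(steady_state_recurrence(two_cycle(2, 1))),
               c(1 / 3, 2 / 3))
  expect_equal(unname(steady_state_decomposition(labelled_digraph("v"))), 1)
  expect_error(steady_state_decomposition(
    labelled_digraph(c("1", "2"), "1", "2", 1)), "strongly connected")
})

test_that("the forest recurrence reproduces hand-enumerated forest weights", {
  g <- two_cycle(5, 3)  # labels a = 5 (1->2), b = 3 (2->1)
  rec <- chebotarev_recurrence(g)
  expect_equal(unname(rec$Q[[1]]), diag(1, 2))
  expect_equal(unname(rec$Q[[2]]), matrix(c(3, 3, 5, 5), 2, 2))
  expect_equal(unname(rec$Q[[3]]), matrix(0, 2, 2))

  # C2+ forest weights against the enumeration oracle
  gp <- c2_plus(2, 1, 3)
  expect_equal(enumerate_forest_weight(gp, "1"), 0)      # 1 cannot be sole root
  expect_equal(enumerate_forest_weight(gp, "M"), 6)      # {1->2, 2->M}
  expect_equal(enumerate_forest_weight(gp, c("1", "M"),
                                       path_from = "1", path_to = "1"), 4)
  rec <- chebotarev_recurrence(gp)
  expect_equal(rec$Q[[3]][["M", "M"]], 6)
})

test_that("first-passage solvers agree with first-step analysis on C2+", {
  gp <- c2_plus(1, 1, 1)
  expect_equal(unname(mfpt_linear_solve(gp)), c(3, 2))
  expect_equal(unname(mfpt_recurrence(gp)), c(3, 2))

  # general C2+ closed form
  for (i in 1:25) {
    set.seed(i)
    l <- 10^stats::runif(3, -2, 2)
    gp <- c2_plus(l[1], l[2], l[3])
    expect_equal(mfpt_linear_solve(gp)[["1"]], c2_mfpt(l[1], l[2], l[3]),
                 tolerance = 1e-12)
    expect_equal(mfpt_recurrence(gp)[["1"]], c2_mfpt(l[1], l[2], l[3]),
                 tolerance = 1e-12)
  }

  # single state, one production edge at rate 2: exponential mean 1/2
  g1 <- labelled_digraph(c("1", "M"), "1", "M", 2)
  expect_equal(mfpt_linear_solve(g1, "M")[["1"]], 0.5)

  # unreachable terminal is rejected
  bad2 <- labelled_digraph(c("1", "2", "3", "M"),
                           from = c("1", "2", "3"), to = c("2", "1", "M"),
                           label = c(1, 1, 1))
  expect_error(mfpt_linear_solve(bad2, "M"), "unreachable")
})

test_that("all solver routes agree on random strongly connected graphs", {
  # 40 graphs here; the full 200-graph protocol runs in the acceptance suite
  for (i in 1:40) {
    g <- random_strongly_connected_graph(3L + (i %% 4L), seed = 1000 + i)
    p_svd <- steady_state_decomposition(g)
    p_rec <- steady_state_recurrence(g)
    p_gth <- steady_state_gth(g)
    # componentwise-accurate routes agree per entry; the SVD kernel vector
    # is accurate in norm (tiny components carry absolute, not relative,
    # accuracy in a dense decomposition)
    expect_lt(max(abs(p_gth - p_rec) / p_rec), 1e-9)
    expect_lt(max(abs(p_svd - p_rec)) / max(p_rec), 1e-9)
    gp <- augment_with_terminal(g, g$vertices[1:2], r = 2)
    t_lin <- mfpt_linear_solve(gp)
    t_rec <- mfpt_recurrence(gp)
    expect_lt(max(abs(t_lin - t_rec) / t_rec), 1e-9)
  }
})

test_that("recurrence diagonals equal enumerated tree weights on small graphs", {
  for (i in 1:12) {
    g <- random_strongly_connected_graph(3L + (i %% 3L), seed = 2000 + i)
    m <- length(g$vertices)
    rho <- diag(chebotarev_recurrence(g, m - 1L, precision = "exact")$Q[[m]])
    for (v in g$vertices) {
      w <- enumerate_forest_weight(g, v)
      expect_equal(rho[[v]], w, tolerance = 1e-9 * w)
    }
  }
})

test_that("probability conservation and forest-matrix structure hold", {
  for (i in 1:10) {
    g <- random_strongly_connected_graph(4L, seed = 3000 + i)
    p <- steady_state_recurrence(g)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
    m <- length(g$vertices)
    rec <- chebotarev_recurrence(g, precision = "exact")
    scale <- max(abs(rec$Q[[m]]))
    for (k in seq_len(m))  # Q_0 .. Q_{m-1} have nonnegative entries
      expect_true(all(rec$Q[[k]] >= 0))
    expect_lt(max(abs(rec$Q[[m + 1L]])) / scale, 1e-12)  # Q_m = 0
  }
})

test_that("the stiff-regime steady state keeps componentwise accuracy", {
  # labels spanning 20 orders of magnitude: GTH keeps the detailed-balance
  # ratios componentwise, and the SVD route still agrees in norm
  sp <- sym_d3_spec(1, 1, 1, g23 = 1e9)
  g <- instantiate_ladder(sp, 1e20)
  p <- steady_state_gth(g)
  expect_equal(p[["B3"]] / p[["B1"]], 1e9, tolerance = 1e-9)
  expect_equal(p[["B2"]] / p[["B1"]], 1, tolerance = 1e-9)
  expect_lt(max(abs(steady_state_decomposition(g) - p)), 1e-9)

  # a numerically two-dimensional kernel is refused rather than guessed:
  # two cycles joined by vanishingly weak edges
  g2 <- labelled_digraph(c("1", "2", "3", "4"),
                         from = c("1", "2", "3", "4", "2", "4"),
                         to = c("2", "1", "4", "3", "3", "1"),
                         label = c(1, 1, 1, 1, 1e-15, 1e-15))
  expect_error(steady_state_decomposition(g2), "stiff")
  expect_equal(sum(steady_state_gth(g2)), 1)
})
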