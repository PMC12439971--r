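test_that("the column Laplacian matches direct substitution and sums to zero", {
  g <- two_cycle(2, 1)
  L <- laplacian(g, "column")
  expect_equal(unname(L), matrix(c(-2, 2, 1, -1), 2, 2), tolerance = 0,
               ignore_attr = TRUE)
  expect_equal(unname(laplacian(g, "row")), -t(unname(L)),
               ignore_attr = TRUE)

  g1 <- labelled_digraph("a")
  expect_equal(unname(laplacian(g1)), matrix(0, 1, 1), ignore_attr = TRUE)

  set.seed(4)
  for (i in 1:20) {
    gr <- random_strongly_connected_graph(sample(2:7, 1), seed = i)
    Lc <- laplacian(gr, "column")
    expect_lt(max(abs(colSums(Lc))) / max(abs(Lc)), 1e-12)
  }
})

test_that("graph validation rejects malformed inputs", {
  expect_error(labelled_digraph(character()), "at least one vertex")
  expect_error(labelled_digraph(c("1", "1")), "distinct")
  expect_error(labelled_digraph("1", "1", "1", 1), "self-edges")
  expect_error(labelled_digraph(c("1", "2"), c("1", "1"), c("2", "2"), c(1, 2)),
               "one edge per ordered")
  expect_error(labelled_digraph(c("1", "2"), "1", "2", 0), "strictly positive")
  expect_error(labelled_digraph(c("1", "2"), "1", "2", Inf), "strictly positive")
})

test_that("strong connectivity distinguishes cycles, chains and ladders", {
  expect_true(is_strongly_connected(two_cycle()))
  oneway <- labelled_digraph(c("1", "2"), "1", "2", 1)
  expect_false(is_strongly_connected(oneway))
  sp <- sym_d3_spec(1, 1, 1, g23 = 10)
  expect_true(is_strongly_connected(instantiate_ladder(sp, 1e-6)))
  expect_true(is_strongly_connected(instantiate_ladder(sp, 1e6)))
  expect_false(is_strongly_connected(instantiate_ladder(sp, 0)))
})

test_that("ladder instantiation has the promised structure", {
  sp2 <- ladder_spec(2L, 1.5, 0.5, 2, 0.5, kon = 3, koff = 2, r = 1)
  g <- instantiate_ladder(sp2, 1)
  expect_equal(length(g$vertices), 4L)
  expect_equal(length(g$from), 8L)

  # x = 0: binding edges absent, steady state concentrates on unbound chain
  g0 <- instantiate_ladder(sp2, 0)
  expect_equal(length(g0$from), 6L)
  p0 <- steady_state_gth(g0)
  expect_equal(unname(p0[c("B1", "B2")]), c(0, 0))
  expect_equal(unname(p0[c("U1", "U2")]), c(0.25, 0.75))

  # fully symmetric D3 at x = 1 has the uniform steady state
  gsym <- instantiate_ladder(sym_d3_spec(1, 1, 1), 1)
  expect_equal(unname(steady_state_decomposition(gsym)), rep(1 / 6, 6),
               tolerance = 1e-12)

  expect_error(instantiate_ladder(sp2, -1), "non-negative")
})

test_that("two concentrations differ only in the binding-edge labels, proportionally", {
  sp <- sym_d3_spec(0.3, 7, 2, g23 = 50, kon = 0.2)
  g1 <- instantiate_ladder(sp, 0.01)
  g2 <- instantiate_ladder(sp, 130)
  key <- function(g) paste(g$from, g$to)
  expect_setequal(key(g1), key(g2))
  m <- match(key(g1), key(g2))
  ratio <- g2$label[m] / g1$label
  binding <- grepl("^U", g1$from) & grepl("^B", g1$to[m])
  expect_equal(unique(ratio[!binding]), 1)
  expect_equal(unique(ratio[binding]), 130 / 0.01)
})

test_that("gamma = 1 makes the bound chain a copy of the unbound chain", {
  sp <- ladder_spec(4L, c(1, 2, 3), c(4, 5, 6), kon = 1, koff = 1, r = 1)
  g <- instantiate_ladder(sp, 2)
  lab <- function(f, t) g$label[g$from == f & g$to == t]
  for (i in 1:3) {
    expect_equal(lab(paste0("B", i), paste0("B", i + 1)),
                 lab(paste0("U", i), paste0("U", i + 1)))
    expect_equal(lab(paste0("B", i + 1), paste0("B", i)),
                 lab(paste0("U", i + 1), paste0("U", i)))
  }
})

test_that("terminal augmentation adds an absorbing production vertex", {
  g <- two_cycle(1, 1)
  gp <- augment_with_terminal(g, "2", 4)
  expect_equal(length(gp$vertices), 3L)
  expect_equal(terminal_vertex(gp), "M")
  expect_false(is_strongly_connected(gp))

  sp <- sym_d3_spec(1, 1, 1)
  gp3 <- augment_with_terminal(instantiate_ladder(sp, 1),
                               productive_vertices(sp), 2)
  expect_equal(sum(gp3$to == "M"), 2L)
  expect_setequal(gp3$from[gp3$to == "M"], c("U3", "B3"))
  expect_error(augment_with_terminal(g, character(), 1), "non-empty")
})

test_that("model specs survive a JSON round trip", {
  sp <- sym_d3_spec(0.5, 10, 10, g23 = 10)
  path <- tempfile(fileext = ".json")
  spec_to_json(sp, path)
  sp2 <- spec_from_json(path)
  expect_equal(sp2, sp)
  cs <- chain_spec(3L, c(1, 2), c(3, 4), r = 5)
  expect_equal(spec_from_json(spec_to_json(cs)), cs)
})
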