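# Shared model builders for the test-suite.

two_cycle <- function(a = 2, b = 1) {
  labelled_digraph(c("1", "2"), from = c("1", "2"), to = c("2", "1"),
                   label = c(a, b))
}

c2_plus <- function(l12, l21, r) {
  augment_with_terminal(two_cycle(l12, l21), "2", r)
}

# symmetric-rate D3 (l12 = l21, l23 = l32), single/double regulation
sym_d3_spec <- function(l12, l23, r, g12 = 1, g21 = 1, g23 = 1, g32 = 1,
                        kon = 1, koff = 1) {
  ladder_spec(3L, fwd_rates = c(l12, l23), bwd_rates = c(l12, l23),
              fwd_gamma = c(g12, g23), bwd_gamma = c(g21, g32),
              kon = kon, koff = koff, r = r)
}

# symbolic reversible 3-state chain with production from state 3:
# forward rates f1, f2; backward rates b1, b2 (ratepoly inputs)
sym_chain3_plus <- function(f1, b1, f2, b2, r) {
  sym_digraph(c("1", "2", "3", "M"),
              from = c("1", "2", "2", "3", "3"),
              to = c("2", "1", "3", "2", "M"),
              labels = list(f1, b1, f2, b2, r))
}

sym_chain3 <- function(f1, b1, f2, b2) {
  sym_digraph(c("1", "2", "3"),
              from = c("1", "2", "2", "3"),
              to = c("2", "1", "3", "2"),
              labels = list(f1, b1, f2, b2))
}

# activation time from U1 at the two concentration extremes: exactly x = 0
# (unbound chain) and x = 1e20 standing in for the saturating limit
mfpt_u1_endpoints <- function(spec) {
  uc <- unbound_chain(spec)
  t0 <- mfpt_linear_solve(augment_with_terminal(uc, paste0("U", spec$N),
                                                spec$r))[["U1"]]
  g <- instantiate_ladder(spec, 1e20)
  tinf <- mfpt_linear_solve(augment_with_terminal(
    g, productive_vertices(spec), spec$r))[["U1"]]
  c(at_zero = t0, at_infinity = tinf)
}

# --- symbolic derivation helpers --------------------------------------
# rational-arithmetic shorthand
rc <- function(x) rfrac(p_const(x), p_const(1))
rv <- function(s) rfrac(p_var(s), p_const(1))
r_sum <- function(...) Reduce(rfrac_add, list(...))
r_prod <- function(...) Reduce(rfrac_mul, list(...))

# Derive the D3 dynamic ranges symbolically from the limiting chains:
# at x = 0 only the unbound chain (symmetric rates u, u, v, v) is
# accessible; at saturating ligand the process reduces to the bound chain
# (gamma-scaled rates).  The activation-time range is normalised by its
# maximum, attained at x = 0 for activating regulation.
# Unregulated gammas are passed as NULL (factor 1).
sym_d3_dranges <- function(g12 = NULL, g21 = NULL, g23 = NULL, g32 = NULL) {
  lab <- function(g, base) if (is.null(g)) as_poly(base)
                           else p_mul(p_var(g), p_var(base))
  rho0 <- sym_steady_state(sym_chain3("u", "u", "v", "v"))
  ss0 <- rfrac(rho0[["3"]], p_add(p_add(rho0[["1"]], rho0[["2"]]), rho0[["3"]]))
  rhoB <- sym_steady_state(sym_chain3(lab(g12, "u"), lab(g21, "u"),
                                      lab(g23, "v"), lab(g32, "v")))
  ssI <- rfrac(rhoB[["3"]], p_add(p_add(rhoB[["1"]], rhoB[["2"]]), rhoB[["3"]]))
  m0 <- sym_mfpt(sym_chain3_plus("u", "u", "v", "v", "r"), "M")
  t0 <- rfrac(m0$num[["1"]], m0$den)
  mI <- sym_mfpt(sym_chain3_plus(lab(g12, "u"), lab(g21, "u"),
                                 lab(g23, "v"), lab(g32, "v"), "r"), "M")
  tI <- rfrac(mI$num[["1"]], mI$den)
  list(dss = rfrac_sub(ssI, ss0),
       dm = rfrac_sub(rc(1), rfrac_div(tI, t0)))
}

# same construction for D2 (two-state chains, rates p = l12, q = l21)
sym_d2_dranges <- function(g12 = NULL, g21 = NULL) {
  lab <- function(g, base) if (is.null(g)) as_poly(base)
                           else p_mul(p_var(g), p_var(base))
  ss0 <- rfrac("p", p_add("p", "q"))
  fI <- lab(g12, "p"); bI <- lab(g21, "q")
  ssI <- rfrac(fI, p_add(fI, bI))
  c2p <- function(f, b) sym_digraph(c("1", "2", "M"),
                                    from = c("1", "2", "2"),
                                    to = c("2", "1", "M"),
                                    labels = list(f, b, "r"))
  m0 <- sym_mfpt(c2p(as_poly("p"), as_poly("q")), "M")
  mI <- sym_mfpt(c2p(fI, bI), "M")
  list(dss = rfrac_sub(ssI, ss0),
       dm = rfrac_sub(rc(1), rfrac_div(rfrac(mI$num[["1"]], mI$den),
                                       rfrac(m0$num[["1"]], m0$den))))
}

# first-step mFPT from state 1 of a reversible 3-chain with production r
# from state 3 (independent scalar oracle used against the solvers)
chain3_mfpt_oracle <- function(f1, b1, f2, b2, r) {
  # t3 = (1 + b2 t2) / (b2 + r); t2 = (1 + b1 t1 + f2 t3) / (b1 + f2);
  # t1 = 1/f1 + t2  -- solved by direct elimination
  A <- matrix(c(f1, -f1, 0,
                -b1, b1 + f2, -f2,
                0, -b2, b2 + r), 3, 3, byrow = TRUE)
  solve(A, rep(1, 3))[1]
}
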