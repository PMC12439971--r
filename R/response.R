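#' Logarithmic concentration grid
#'
#' Strictly increasing ligand concentrations, log-spaced. The reference
#' configuration spans `[1e-20, 1e20]` with 1000 points (log10 step of
#' about 0.04004), wide enough that the grid endpoints stand in for the
#' `x -> 0` and `x -> infinity` limits of the response curves. An explicit
#' `x = 0` evaluation on the unbound subgraph can be requested in addition.
#'
#' @param xmin,xmax Grid endpoints (concentration units, `0 < xmin < xmax`).
#' @param n Number of grid points (>= 2).
#' @param include_zero Also evaluate the `x = 0` point explicitly via the
#'   unbound subgraph.
#' @return An object of class `concentration_grid`.
#' @export
concentration_grid <- function(xmin = 1e-20, xmax = 1e20, n = 1000L,
                               include_zero = FALSE) {
  stopifnot(xmin > 0, xmax > xmin, n >= 2L)
  structure(list(x = 10^seq(log10(xmin), log10(xmax), length.out = n),
                 include_zero = isTRUE(include_zero)),
            class = "concentration_grid")
}

#' The reference analysis grid
#' @return The reference `concentration_grid` (1000 points over
#'   `[1e-20, 1e20]`).
#' @export
reference_grid <- function() concentration_grid()

ladder_curves_kernel <- function(spec, x, start_w) {
  ladder_response_cpp(spec$N, spec$fwd_rates, spec$bwd_rates,
                      spec$fwd_gamma, spec$bwd_gamma,
                      spec$kon, spec$koff, spec$r, x, start_w)
}

ladder_curves_reference <- function(spec, x, start_w) {
  prod <- productive_vertices(spec)
  U <- paste0("U", seq_len(spec$N))
  out <- matrix(NA_real_, length(x), 2L)
  for (i in seq_along(x)) {
    g <- instantiate_ladder(spec, x[i])
    p <- steady_state_gth(g)
    gp <- augment_with_terminal(g, prod, spec$r)
    t <- mfpt_linear_solve(gp, "M")
    out[i, 1L] <- sum(p[prod])
    out[i, 2L] <- sum(start_w * t[U])
  }
  out
}

start_weights <- function(spec, start_mode) {
  if (start_mode == "fixed_U1") {
    w <- c(1, rep(0, spec$N - 1L))
  } else {
    w <- as.numeric(steady_state_gth(unbound_chain(spec)))
  }
  w
}

#' Normalised concentration-response curves
#'
#' For every grid concentration, computes the normalised steady-state level
#' (the summed stationary probability of the productive vertices, which is
#' `SS(x) / (r / delta)` and lies in `[0, 1]`) and the activation time (the
#' mean first-passage time to the production event on the augmented graph),
#' normalised by its maximum over the evaluated grid so it lies in
#' `(0, 1]`. The activation time starts from `U1` (`fixed_U1`) or from the
#' zero-ligand equilibrium over the unbound states (`equilibrium_unbound`).
#'
#' @param spec A `ladder_spec` or `chain_spec`.
#' @param grid A [concentration_grid()].
#' @param start_mode `"fixed_U1"` or `"equilibrium_unbound"`.
#' @param engine `"kernel"` (compiled, default) or `"reference"` (pure-R
#'   path through the graph objects and solvers; used for cross-checks).
#' @return A `response_curves` object: a data frame with columns `x`,
#'   `ss_bar`, `mfpt_bar`, `raw_ss`, `raw_mfpt`, plus attributes carrying
#'   the spec, start mode and any explicit `x = 0` evaluation.
#' @export
compute_response_curves <- function(spec, grid = reference_grid(),
                                    start_mode = c("fixed_U1",
                                                   "equilibrium_unbound"),
                                    engine = c("kernel", "reference")) {
  start_mode <- match.arg(start_mode)
  engine <- match.arg(engine)
  stopifnot(inherits(grid, "concentration_grid"))
  if (inherits(spec, "chain_spec")) {
    out <- chain_curves(spec, grid$x)
  } else if (inherits(spec, "ladder_spec")) {
    w <- start_weights(spec, start_mode)
    out <- if (engine == "kernel") ladder_curves_kernel(spec, grid$x, w)
           else ladder_curves_reference(spec, grid$x, w)
  } else stop("unknown spec type")
  if (any(!is.finite(out)))
    stop("solver failure at x = ",
         paste(signif(grid$x[!stats::complete.cases(out)], 3), collapse = ", "))
  mmax <- max(out[, 2L])
  df <- data.frame(x = grid$x,
                   ss_bar = out[, 1L],
                   mfpt_bar = out[, 2L] / mmax,
                   raw_ss = out[, 1L] * spec$r / spec$delta,
                   raw_mfpt = out[, 2L])
  zero <- NULL
  if (grid$include_zero && inherits(spec, "ladder_spec")) {
    w <- start_weights(spec, start_mode)
    uc <- unbound_chain(spec)
    p0 <- steady_state_gth(uc)
    gp0 <- augment_with_terminal(uc, paste0("U", spec$N), spec$r)
    t0 <- mfpt_linear_solve(gp0, "M")
    zero <- c(ss_bar = unname(p0[paste0("U", spec$N)]),
              raw_mfpt = sum(w * t0))
  }
  structure(df, class = c("response_curves", "data.frame"),
            spec = spec, start_mode = start_mode, zero = zero,
            mfpt_norm = mmax)
}

chain_curves <- function(spec, x) {
  fixed <- !any(vapply(c(spec$fwd_rates, spec$bwd_rates), is.function,
                       logical(1)))
  one <- function(xi) {
    g <- instantiate_chain(spec, xi)
    p <- steady_state_gth(g)
    gp <- augment_with_terminal(g, productive_vertices(spec), spec$r)
    t <- mfpt_linear_solve(gp, "M")
    c(p[[as.character(spec$N)]], t[["1"]])
  }
  if (fixed) {
    v <- one(x[1])
    matrix(v, length(x), 2L, byrow = TRUE)
  } else t(vapply(x, one, numeric(2)))
}

#' Dynamic ranges of a pair of response curves
#'
#' Maximum minus minimum of each normalised curve over the evaluated grid
#' (the explicit `x = 0` steady-state point is included when present).
#'
#' @param curves A `response_curves` object.
#' @return Named vector `c(delta_ss, delta_mfpt)`, each in `[0, 1]`.
#' @export
dynamic_ranges <- function(curves) {
  stopifnot(inherits(curves, "response_curves"))
  ss <- curves$ss_bar
  zero <- attr(curves, "zero")
  if (!is.null(zero)) ss <- c(zero[["ss_bar"]], ss)
  c(delta_ss = max(ss) - min(ss),
    delta_mfpt = max(curves$mfpt_bar) - min(curves$mfpt_bar))
}

#' Coupling score
#'
#' `f = 1 - delta_ss + delta_mfpt`. Perfect decoupling - the full
#' steady-state dynamic range with a flat activation time - gives `f = 0`;
#' a flat steady state with a fully varying activation time gives `f = 2`;
#' whenever the activation time varies more than the steady-state level the
#' score exceeds 1.
#'
#' @param delta_ss,delta_mfpt Normalised dynamic ranges, each in `[0, 1]`.
#' @return The coupling score `f` in `[0, 2]`.
#' @export
coupling_score <- function(delta_ss, delta_mfpt) {
  if (any(!is.finite(c(delta_ss, delta_mfpt))) ||
      delta_ss < 0 || delta_ss > 1 || delta_mfpt < 0 || delta_mfpt > 1)
    stop("dynamic ranges must lie in [0, 1]")
  1 - delta_ss + delta_mfpt
}

#' Activation time from an equilibrium of unbound initial states
#'
#' The mean first-passage time to production at concentration `x`, averaged
#' over the unbound states with weights given by their zero-ligand
#' stationary probabilities: appropriate when the system equilibrates over
#' the unbound chain before the ligand is introduced.
#'
#' @param spec A `ladder_spec`.
#' @param x Ligand concentration (> 0; at `x = 0` the unbound chain itself
#'   is used).
#' @return The weighted mean first-passage time (time units).
#' @export
equilibrium_start_mfpt <- function(spec, x) {
  stopifnot(inherits(spec, "ladder_spec"))
  w <- steady_state_gth(unbound_chain(spec))
  if (x == 0) {
    uc <- unbound_chain(spec)
    gp <- augment_with_terminal(uc, paste0("U", spec$N), spec$r)
    t <- mfpt_linear_solve(gp, "M")
    return(sum(w * t[names(w)]))
  }
  g <- instantiate_ladder(spec, x)
  gp <- augment_with_terminal(g, productive_vertices(spec), spec$r)
  t <- mfpt_linear_solve(gp, "M")
  sum(w * t[names(w)])
}

interp_crossing <- function(lx, y, level) {
  # first left-to-right crossing of `level`, log-linear in x
  above <- y >= level
  i <- which(above[-1] != above[-length(above)])[1]
  if (is.na(i)) return(NA_real_)
  lx[i] + (level - y[i]) * (lx[i + 1] - lx[i]) / (y[i + 1] - y[i])
}

#' Half-activation and fastest-response concentrations
#'
#' `x_half` is the concentration at which the steady-state level crosses
#' the midpoint of its range (log-linear interpolation of the first
#' crossing); it is `NA` (flagged) when the steady-state curve is flat.
#' `x_fast` is the grid concentration minimising the normalised activation
#' time, taking the smallest concentration on ties.
#'
#' @param curves A `response_curves` object.
#' @param flat_tol Steady-state range below which `x_half` is undefined.
#' @return Named vector `c(x_half, x_fast)`.
#' @export
half_activation_and_fastest <- function(curves, flat_tol = 1e-12) {
  stopifnot(inherits(curves, "response_curves"))
  ss <- curves$ss_bar
  rng <- max(ss) - min(ss)
  lx <- log10(curves$x)
  x_half <- if (rng <= flat_tol) NA_real_ else {
    10^interp_crossing(lx, (ss - min(ss)) / rng, 0.5)
  }
  # values within 1e-12 of the minimum (normalised scale) count as ties,
  # so a numerically flat curve resolves to the smallest concentration
  mins <- which(curves$mfpt_bar <= min(curves$mfpt_bar) + 1e-12)
  c(x_half = x_half, x_fast = curves$x[mins[1]])
}

traversal_interval <- function(x, y, change_fraction = 0.9) {
  rng <- max(y) - min(y)
  if (rng <= 0) return(c(NA_real_, NA_real_))
  pad <- (1 - change_fraction) / 2
  lo <- min(y) + pad * rng
  hi <- max(y) - pad * rng
  lx <- log10(x)
  inside <- y > lo & y < hi
  if (!any(inside)) {
    # curve jumps across the band between two grid points
    i <- which(abs(diff(y >= (min(y) + rng / 2))) > 0)[1]
    return(sort(lx[c(i, i + 1)]))
  }
  range(lx[inside])
}

#' Overlap of the concentration ranges where two curves change
#'
#' For each curve, finds the log10-concentration interval over which it
#' traverses the central `change_fraction` of its dynamic range (from the
#' 5% to the 95% level for the default 0.9). The overlap of intervals
#' `[a, b]` and `[c, d]` is
#' `max(0, min(b, d) - max(a, c)) / ((b - a) + (d - c))`: 0 for disjoint
#' ranges, 0.5 for identical ones. Quantifies concentration-dependent
#' decoupling, where the steady state and the activation time both vary
#' with ligand but over largely non-overlapping concentration ranges.
#'
#' @param x Concentration grid shared by the two curves.
#' @param yA,yB The two (normalised) response curves.
#' @param change_fraction Central fraction of the range that defines each
#'   traversal interval.
#' @return The overlap fraction in `[0, 0.5]`, or `NA` (flagged via
#'   attribute `flat`) when either curve is flat.
#' @export
response_overlap <- function(x, yA, yB, change_fraction = 0.9) {
  ia <- traversal_interval(x, yA, change_fraction)
  ib <- traversal_interval(x, yB, change_fraction)
  if (any(is.na(c(ia, ib))))
    return(structure(NA_real_, flat = TRUE))
  interval_overlap(ia, ib)
}

interval_overlap <- function(ab, cd) {
  max(0, min(ab[2], cd[2]) - max(ab[1], cd[1])) /
    ((ab[2] - ab[1]) + (cd[2] - cd[1]))
}

#' Monotonicity check with numerical slack
#'
#' Whether a curve is monotone in the stated direction, allowing successive
#' differences to dip below zero by at most `tol` times the curve's range
#' (monotonicity holds exactly in the relevant regimes; the slack absorbs
#' numerical noise on flat stretches).
#'
#' @param y Curve values along the grid.
#' @param direction `"increasing"` or `"decreasing"`.
#' @param tol Relative tolerance.
#' @return `TRUE` or `FALSE`.
#' @export
monotonicity_check <- function(y, direction = c("increasing", "decreasing"),
                               tol = 1e-6) {
  direction <- match.arg(direction)
  if (direction == "decreasing") y <- -y
  rng <- max(y) - min(y)
  all(diff(y) >= -tol * max(rng, .Machine$double.xmin))
}

#' Decoupling summary of a response-curve pair
#'
#' Collects the decoupling diagnostics of a model's response: the two
#' normalised dynamic ranges, the coupling score, the half-activation and
#' fastest-response concentrations, monotonicity flags for the two curves,
#' and the traversal-interval overlap.
#'
#' @param curves A `response_curves` object.
#' @return An object of class `decoupling_summary` (a named list).
#' @export
decoupling_summary <- function(curves) {
  dr <- dynamic_ranges(curves)
  hx <- half_activation_and_fastest(curves)
  ov <- response_overlap(curves$x, curves$ss_bar, curves$mfpt_bar)
  structure(list(delta_ss = unname(dr[["delta_ss"]]),
                 delta_mfpt = unname(dr[["delta_mfpt"]]),
                 f = coupling_score(min(dr[["delta_ss"]], 1),
                                    min(dr[["delta_mfpt"]], 1)),
                 x_half = unname(hx[["x_half"]]),
                 x_fast = unname(hx[["x_fast"]]),
                 ss_monotonic = monotonicity_check(curves$ss_bar, "increasing"),
                 mfpt_monotonic = monotonicity_check(curves$mfpt_bar,
                                                     "decreasing"),
                 overlap = as.numeric(ov)),
            class = "decoupling_summary")
}

#' @export
print.decoupling_summary <- function(x, ...) {
  cat(sprintf("decoupling summary: f = %.4g (delta_ss = %.4g, delta_mfpt = %.4g)\n",
              x$f, x$delta_ss, x$delta_mfpt))
  cat(sprintf("  x_half = %.4g, x_fast = %.4g, overlap = %.3g\n",
              x$x_half, x$x_fast, x$overlap))
  cat(sprintf("  steady state monotone increasing: %s; activation time monotone decreasing: %s\n",
              x$ss_monotonic, x$mfpt_monotonic))
  invisible(x)
}
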