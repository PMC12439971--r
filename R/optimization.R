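# Coupling-score minimization by particle swarm optimization over the
# three-rung ladder, in log10-parameter space, with optional rate-scale
# constraints handled as additive penalties.

#' Define a decoupling-search problem
#'
#' Fixes the search space for coupling-score minimization on `D3`: bounds
#' for the seven rate parameters (`l12`, `l21`, `l23`, `l32`, `kon`,
#' `koff`, `r`), the set of regulated bound-chain edges with their
#' regulatory-factor bounds, an optional rate-scale constraint (RSC), and
#' optional equality ties among rates. All bounds are expressed on the
#' natural scale; the optimizer works in log10 space.
#'
#' @param regulated Character subset of `c("g12", "g21", "g23", "g32")`
#'   naming the regulated bound-chain transitions (`g12` regulates
#'   `B1 -> B2`, etc.).
#' @param gamma_bounds List of `c(low, high)` bounds per regulated factor
#'   (recycled if a single pair is given). Default `[1e-3, 1e3]`.
#' @param rate_bounds `c(low, high)` bounds shared by all rates and `kon`.
#'   Default `[1e-4, 1e4]` (rates in units of the degradation rate, `kon`
#'   per concentration unit).
#' @param rsc Optional positive rate-scale constant: constrains
#'   `|log10(l12 / l23)|`, `|log10(l12 / l21)|` and `|log10(l23 / l32)|`
#'   to be at most `rsc`.
#' @param equality_ties `"none"` or `"fwd_prod"` (`l12 = l23 = r` and
#'   `l21 = l32`: the production step proceeds on the timescale of the
#'   forward transitions).
#' @param grid Objective concentration grid; defaults to 161 log-spaced
#'   points over `[1e-12, 1e12]` (coarser than the reference analysis grid,
#'   sufficient because the half-activation point is bounded by the
#'   parameter box well inside the span).
#' @param start_mode Activation-time start mode (see
#'   [compute_response_curves()]).
#' @param penalty_lambda Weight of the additive constraint penalty.
#' @return An object of class `decoupling_problem`.
#' @export
decoupling_problem <- function(regulated = "g23",
                               gamma_bounds = list(c(1e-3, 1e3)),
                               rate_bounds = c(1e-4, 1e4),
                               rsc = NULL,
                               equality_ties = c("none", "fwd_prod"),
                               grid = concentration_grid(1e-12, 1e12, 161L),
                               start_mode = c("fixed_U1",
                                              "equilibrium_unbound"),
                               penalty_lambda = 10) {
  equality_ties <- match.arg(equality_ties)
  start_mode <- match.arg(start_mode)
  regulated <- match.arg(regulated, c("g12", "g21", "g23", "g32"),
                         several.ok = TRUE)
  if (!is.null(rsc) && rsc <= 0) stop("'rsc' must be positive when given")
  stopifnot(rate_bounds[1] > 0, rate_bounds[1] < rate_bounds[2])
  if (length(gamma_bounds) == 1L)
    gamma_bounds <- rep(gamma_bounds, length(regulated))
  if (length(gamma_bounds) != length(regulated))
    stop("one gamma bound pair per regulated edge required")
  names(gamma_bounds) <- regulated
  rate_names <- if (equality_ties == "fwd_prod") c("l12", "l21", "kon", "koff")
                else c("l12", "l21", "l23", "l32", "kon", "koff", "r")
  bounds <- c(stats::setNames(rep(list(rate_bounds), length(rate_names)),
                              rate_names),
              gamma_bounds)
  structure(list(regulated = regulated, bounds = bounds,
                 rate_bounds = rate_bounds, rsc = rsc,
                 equality_ties = equality_ties, grid = grid,
                 start_mode = start_mode, penalty_lambda = penalty_lambda),
            class = "decoupling_problem")
}

params_to_spec <- function(problem, params) {
  p <- as.list(params)
  if (problem$equality_ties == "fwd_prod") {
    p$l23 <- p$r <- p$l12
    p$l32 <- p$l21
  }
  g <- list(g12 = 1, g21 = 1, g23 = 1, g32 = 1)
  for (nm in problem$regulated) g[[nm]] <- p[[nm]]
  ladder_spec(3L,
              fwd_rates = c(p$l12, p$l23), bwd_rates = c(p$l21, p$l32),
              fwd_gamma = c(g$g12, g$g23), bwd_gamma = c(g$g21, g$g32),
              kon = p$kon, koff = p$koff, r = p$r)
}

rsc_violations <- function(problem, spec) {
  if (is.null(problem$rsc)) return(numeric(0))
  c(g1 = abs(log10(spec$fwd_rates[1] / spec$fwd_rates[2])) - problem$rsc,
    g2 = abs(log10(spec$fwd_rates[1] / spec$bwd_rates[1])) - problem$rsc,
    g3 = abs(log10(spec$fwd_rates[2] / spec$bwd_rates[2])) - problem$rsc)
}

#' Coupling-score objective with constraint terms
#'
#' Builds the ladder from a parameter vector, computes the response curves
#' on the problem grid, and returns the coupling score together with the
#' rate-scale constraint values `g_k = |log10(rate ratio)| - RSC`
#' (feasible when `<= 0`). The penalized score adds
#' `lambda * sum(max(0, g_k))`. Solver failures map to the worst score
#' with a diagnostic flag.
#'
#' @param problem A [decoupling_problem()].
#' @param params Named parameter vector on the natural scale (names as in
#'   the problem's bounds).
#' @return List with `f`, `delta_ss`, `delta_mfpt`, `violations`,
#'   `penalized`, `failed`.
#' @export
objective <- function(problem, params) {
  res <- tryCatch({
    spec <- params_to_spec(problem, params)
    cv <- compute_response_curves(spec, problem$grid, problem$start_mode)
    dr <- dynamic_ranges(cv)
    g <- rsc_violations(problem, spec)
    f <- coupling_score(min(dr[["delta_ss"]], 1), min(dr[["delta_mfpt"]], 1))
    list(f = f, delta_ss = unname(dr[["delta_ss"]]),
         delta_mfpt = unname(dr[["delta_mfpt"]]), violations = g,
         penalized = f + problem$penalty_lambda * sum(pmax(0, g)),
         failed = FALSE)
  }, error = function(e) {
    list(f = 2, delta_ss = NA_real_, delta_mfpt = NA_real_,
         violations = numeric(0), penalized = 2 + problem$penalty_lambda,
         failed = TRUE)
  })
  res
}

#' Minimize the coupling score with a particle swarm
#'
#' Standard global-best PSO in log10-parameter space: Latin-hypercube
#' initialization, velocity update
#' `V <- omega V + c1 r1 (P - X) + c2 r2 (G - X)` with fresh uniform noise
#' `r1, r2` per particle and dimension, position update `X <- X + V` with
#' out-of-bounds coordinates set to the nearest bound. The inertia factor
#' decays linearly from 0.9 to 0.4 over the generation budget;
#' `c1 = c2 = 2`. A run terminates when the penalized global best stays
#' below `f_threshold` for more than `patience` consecutive generations,
#' or at the generation cap.
#'
#' @param problem A [decoupling_problem()].
#' @param seed Integer seed (controls initialization and noise).
#' @param swarm_size Number of particles.
#' @param max_generations Generation cap.
#' @param f_threshold Convergence threshold on the best score.
#' @param patience Consecutive below-threshold generations required.
#' @return List with the best parameters (natural scale), best scores,
#'   per-generation best-score trajectory, termination reason, and
#'   settings metadata.
#' @export
pso_minimize <- function(problem, seed, swarm_size = 25L,
                         max_generations = 200L, f_threshold = 0.1,
                         patience = 5L) {
  bl <- log10(vapply(problem$bounds, function(b) b, numeric(2)))
  d <- ncol(bl)
  nm <- colnames(bl) <- names(problem$bounds)
  X <- latin_hypercube(bl, swarm_size, seed)
  colnames(X) <- nm
  V <- matrix(0, swarm_size, d)
  score_at <- function(xrow) objective(problem, stats::setNames(10^xrow, nm))
  evals <- apply(X, 1L, score_at)
  s <- vapply(evals, `[[`, numeric(1), "penalized")
  P <- X; ps <- s
  gi <- which.min(s)
  G <- X[gi, ]; gs <- s[gi]; gbest_eval <- evals[[gi]]
  traj <- numeric(0)
  below <- 0L
  termination <- "max_generations"
  gen <- 0L
  for (gen in seq_len(max_generations)) {
    omega <- 0.9 - (0.9 - 0.4) * (gen - 1L) / max(max_generations - 1L, 1L)
    r1 <- matrix(stats::runif(swarm_size * d), swarm_size, d)
    r2 <- matrix(stats::runif(swarm_size * d), swarm_size, d)
    V <- omega * V + 2 * r1 * (P - X) + 2 * r2 * sweep(-X, 2L, G, "+")
    X <- X + V
    X <- pmin(pmax(X, matrix(bl[1, ], swarm_size, d, byrow = TRUE)),
              matrix(bl[2, ], swarm_size, d, byrow = TRUE))
    evals <- apply(X, 1L, score_at)
    s <- vapply(evals, `[[`, numeric(1), "penalized")
    imp <- s < ps
    P[imp, ] <- X[imp, ]; ps[imp] <- s[imp]
    gi <- which.min(ps)
    if (ps[gi] < gs) {
      gs <- ps[gi]; G <- P[gi, ]
      gbest_eval <- evals[[which.min(s)]]
      if (s[which.min(s)] > gs) {
        # personal best improved from an earlier generation; re-evaluate
        gbest_eval <- objective(problem, stats::setNames(10^G, nm))
      }
    }
    traj <- c(traj, gs)
    below <- if (gs < f_threshold) below + 1L else 0L
    if (below > patience) { termination <- "threshold"; break }
  }
  list(seed = seed,
       best_par = stats::setNames(10^G, nm),
       best_f = gbest_eval$f,
       best_score = gs,
       delta_ss = gbest_eval$delta_ss,
       delta_mfpt = gbest_eval$delta_mfpt,
       violations = gbest_eval$violations,
       trajectory = traj,
       generations = gen,
       termination = termination,
       settings = list(swarm_size = swarm_size,
                       max_generations = max_generations,
                       f_threshold = f_threshold, patience = patience,
                       omega = c(0.9, 0.4), c1 = 2, c2 = 2))
}

#' Run a replicate optimization campaign
#'
#' Independent [pso_minimize()] runs with replicate seeds
#' `base_seed + 1, ..., base_seed + n_replicates`, aggregated into the
#' fraction of replicates whose final score falls below standard
#' thresholds.
#'
#' @param problem A [decoupling_problem()].
#' @param n_replicates Number of replicates (>= 1).
#' @param base_seed Base integer seed.
#' @param thresholds Score thresholds for the summary fractions.
#' @param ... Passed to [pso_minimize()].
#' @return An object of class `campaign_result`: list with `replicates`,
#'   `final_f`, `fraction_below`, and the problem.
#' @export
run_campaign <- function(problem, n_replicates, base_seed,
                         thresholds = c(0.05, 0.1, 1), ...) {
  stopifnot(n_replicates >= 1L)
  reps <- lapply(seq_len(n_replicates), function(i)
    pso_minimize(problem, seed = base_seed + i, ...))
  final_f <- vapply(reps, `[[`, numeric(1), "best_score")
  frac <- vapply(thresholds, function(th) mean(final_f < th), numeric(1))
  structure(list(replicates = reps, final_f = final_f,
                 fraction_below = stats::setNames(frac, paste0("f<", thresholds)),
                 problem = problem, base_seed = base_seed),
            class = "campaign_result")
}

#' @export
print.campaign_result <- function(x, ...) {
  cat(sprintf("campaign: %d replicates, best f = %.4g\n",
              length(x$replicates), min(x$final_f)))
  print(round(x$fraction_below, 3))
  invisible(x)
}

#' Filter campaign solutions
#'
#' Re-scores each replicate's best parameter set on a full analysis grid
#' and keeps those with a coupling score below `f_max`, a non-constant
#' steady-state response, and (optionally) a monotonically increasing
#' steady-state level - the selection used for visualising activating
#' decoupled responses.
#'
#' @param result A `campaign_result`.
#' @param f_max Coupling-score threshold.
#' @param require_monotonic_ss Keep only monotonically increasing
#'   steady-state responses.
#' @param require_nonconstant_ss Drop solutions whose steady-state range is
#'   below `1e-4`.
#' @param grid Re-scoring grid (defaults to the reference grid).
#' @return List of kept solutions, each with `params`, `spec`, `summary`.
#' @export
filter_solutions <- function(result, f_max,
                             require_monotonic_ss = TRUE,
                             require_nonconstant_ss = TRUE,
                             grid = reference_grid()) {
  stopifnot(inherits(result, "campaign_result"))
  kept <- list()
  for (rep in result$replicates) {
    spec <- params_to_spec(result$problem, rep$best_par)
    cv <- compute_response_curves(spec, grid, result$problem$start_mode)
    sm <- decoupling_summary(cv)
    if (sm$f >= f_max) next
    if (require_nonconstant_ss && sm$delta_ss <= 1e-4) next
    if (require_monotonic_ss && !sm$ss_monotonic) next
    kept[[length(kept) + 1L]] <- list(params = rep$best_par, spec = spec,
                                      summary = sm, seed = rep$seed)
  }
  kept
}

#' Classify the regulatory mode of a solution
#'
#' A regulated factor promotes progression toward the productive state when
#' it exceeds 1 on a forward edge or falls below 1 on a backward edge, and
#' hinders it in the opposite cases; factors within `tol_log10` of 1 (in
#' log10) count as unregulated. A solution is `"incoherent"` when it both
#' promotes and hinders, `"coherent"` when two or more factors act in the
#' same direction, and `"single_edge"` when at most one factor is active.
#'
#' @param gammas Named vector of regulatory factors (names among
#'   `g12`, `g21`, `g23`, `g32`), e.g. the regulated entries of a campaign
#'   best.
#' @param tol_log10 Neutrality tolerance on `log10(gamma)`.
#' @return `"coherent"`, `"incoherent"`, or `"single_edge"`.
#' @export
classify_regulatory_mode <- function(gammas, tol_log10 = 0.05) {
  if (length(gammas) == 0L) stop("need at least one regulated factor")
  forward <- c(g12 = TRUE, g21 = FALSE, g23 = TRUE, g32 = FALSE)
  if (!all(names(gammas) %in% names(forward)))
    stop("gamma names must be among g12, g21, g23, g32")
  lg <- log10(gammas)
  active <- abs(lg) > tol_log10
  if (sum(active) <= 1L) return("single_edge")
  promotes <- ifelse(forward[names(gammas)], lg > 0, lg < 0)[active]
  if (any(promotes) && any(!promotes)) "incoherent" else "coherent"
}
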