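# File-based entry points: every result file embeds the configuration and
# seed that produced it, so any number in an output is regenerable from the
# file alone.

run_metadata <- function(extra = list()) {
  c(list(package = "fptdecouple",
         version = as.character(utils::packageVersion("fptdecouple"))),
    extra)
}

#' Compute and export response curves and their decoupling summary
#'
#' Runs [compute_response_curves()] and writes the curves as CSV (columns
#' `x`, `ss_bar`, `mfpt_bar`, `raw_ss`, `raw_mfpt`) and the
#' [decoupling_summary()] as JSON with embedded configuration metadata.
#'
#' @param spec A `ladder_spec`/`chain_spec`, or the name of a family in
#'   [named_model_families()] together with `spec_args`.
#' @param out_prefix Output path prefix; files `<prefix>_curves.csv` and
#'   `<prefix>_summary.json` are written.
#' @param grid A [concentration_grid()].
#' @param start_mode Activation-time start mode.
#' @param spec_args Arguments for the named family constructor.
#' @return Invisibly, the two file paths.
#' @export
response_pipeline <- function(spec, out_prefix, grid = reference_grid(),
                              start_mode = c("fixed_U1",
                                             "equilibrium_unbound"),
                              spec_args = list()) {
  start_mode <- match.arg(start_mode)
  if (is.character(spec)) {
    fam <- named_model_families()
    if (!spec %in% names(fam)) stop("unknown named spec: ", spec)
    spec <- do.call(fam[[spec]], spec_args)
  }
  cv <- compute_response_curves(spec, grid, start_mode)
  sm <- decoupling_summary(cv)
  curves_path <- paste0(out_prefix, "_curves.csv")
  summary_path <- paste0(out_prefix, "_summary.json")
  utils::write.csv(as.data.frame(cv), curves_path, row.names = FALSE)
  doc <- list(metadata = run_metadata(list(
                start_mode = start_mode,
                grid = list(xmin = min(grid$x), xmax = max(grid$x),
                            n = length(grid$x)),
                spec = jsonlite::fromJSON(spec_to_json(spec)))),
              summary = unclass(sm))
  jsonlite::write_json(doc, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(c(curves = curves_path, summary = summary_path))
}

#' Run a campaign and export its results
#'
#' Runs [run_campaign()] and writes a JSON result (summary fractions,
#' per-replicate bests, settings), a CSV of best parameters per replicate,
#' and a CSV of per-generation best-score trajectories.
#'
#' @param problem A [decoupling_problem()].
#' @param n_replicates,base_seed Campaign size and base seed.
#' @param out_prefix Output path prefix.
#' @param ... Passed to [pso_minimize()].
#' @return Invisibly, the `campaign_result` (with file paths attached as an
#'   attribute).
#' @export
campaign_pipeline <- function(problem, n_replicates, base_seed, out_prefix,
                              ...) {
  res <- run_campaign(problem, n_replicates, base_seed, ...)
  pars <- do.call(rbind, lapply(res$replicates, function(r)
    data.frame(seed = r$seed, t(r$best_par), f = r$best_f,
               score = r$best_score, generations = r$generations,
               termination = r$termination)))
  traj <- do.call(rbind, lapply(res$replicates, function(r)
    data.frame(seed = r$seed, generation = seq_along(r$trajectory),
               best_score = r$trajectory)))
  paths <- paste0(out_prefix, c("_campaign.json", "_best_params.csv",
                                "_trajectories.csv"))
  doc <- list(metadata = run_metadata(list(
                base_seed = base_seed, n_replicates = n_replicates,
                rsc = problem$rsc, regulated = problem$regulated,
                equality_ties = problem$equality_ties,
                settings = res$replicates[[1]]$settings)),
              fraction_below = as.list(res$fraction_below),
              final_f = res$final_f)
  jsonlite::write_json(doc, paths[1], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.csv(pars, paths[2], row.names = FALSE)
  utils::write.csv(traj, paths[3], row.names = FALSE)
  attr(res, "paths") <- paths
  invisible(res)
}

#' Cross-validation report for the solver stack
#'
#' Runs the package's oracle suite on freshly generated fixtures: the
#' spanning-forest recurrence against the dense decompositions and the
#' enumeration oracle, the two first-passage-time routes against each
#' other and against Gillespie estimates, and the closed forms against the
#' grid pipeline. Returns one row per check with its maximum observed
#' deviation, the tolerance, and a pass flag.
#'
#' @param n_graphs Random-graph fixtures per structural check.
#' @param n_traj Gillespie trajectories for the simulation check.
#' @param seed Integer seed for all fixtures.
#' @return A data frame with columns `check`, `max_deviation`, `tolerance`,
#'   `pass`.
#' @export
validation_report <- function(n_graphs = 25L, n_traj = 4000L, seed = 1L) {
  rows <- list()
  add <- function(check, dev, tol)
    rows[[length(rows) + 1L]] <<- data.frame(check = check,
                                             max_deviation = dev,
                                             tolerance = tol,
                                             pass = dev <= tol)
  # recurrence vs decompositions vs enumeration on random graphs
  dev_svd <- dev_gth <- dev_enum <- dev_fpt <- 0
  for (i in seq_len(n_graphs)) {
    g <- random_strongly_connected_graph(3L + (i %% 4L), seed = seed + i)
    m <- length(g$vertices)
    p2 <- steady_state_recurrence(g)
    dev_svd <- max(dev_svd,
                   max(abs(steady_state_decomposition(g) - p2)) / max(p2))
    dev_gth <- max(dev_gth, max(abs(steady_state_gth(g) - p2) / p2))
    rho <- diag(chebotarev_recurrence(g, m - 1L, precision = "exact")$Q[[m]])
    for (v in g$vertices[1:2]) {
      w <- enumerate_forest_weight(g, v)
      dev_enum <- max(dev_enum, abs(w - rho[v]) / w)
    }
    gp <- augment_with_terminal(g, g$vertices[1], r = 1)
    dev_fpt <- max(dev_fpt,
                   max(abs(mfpt_linear_solve(gp) - mfpt_recurrence(gp)) /
                         mfpt_recurrence(gp)))
  }
  add("steady state: recurrence vs SVD (norm-relative)", dev_svd, 1e-9)
  add("steady state: recurrence vs elimination (per entry)", dev_gth, 1e-9)
  add("steady state: recurrence vs enumeration", dev_enum, 1e-9)
  add("mFPT: linear solve vs recurrence", dev_fpt, 1e-9)
  # Gillespie vs exact on the four-vertex protocol graph
  rates <- matrix(sample_loguniform(9L * 3L, seed = seed + 1000L), ncol = 9L)
  worst_z <- 0
  for (i in seq_len(nrow(rates))) {
    gp <- protocol_graph_4v(rates[i, ])
    exact <- mfpt_linear_solve(gp, "4")[["1"]]
    est <- estimate_mfpt(gillespie_fpt(gp, "1", n_traj, seed = seed + i,
                                       terminal = "4", max_events = 1e9))
    worst_z <- max(worst_z, abs(est[["mean"]] - exact) / est[["se"]])
  }
  add("Gillespie mFPT within 4 SE of exact", worst_z, 4)
  # closed forms vs grid numerics (single-edge case with moderate rates)
  sp <- named_model_families()$rate_scale_sweep(10^-0.5)
  dr <- dynamic_ranges(compute_response_curves(sp))
  cf <- d3_single_case_ranges("1.III", 10, 10^1.5, 10^1.5)
  add("analytic vs numeric dynamic ranges",
      max(abs(dr - cf)), 1e-4)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
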