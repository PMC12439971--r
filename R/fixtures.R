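# Deterministic generators for everything the pipeline consumes: random
# rate sets, random strongly connected oracle graphs, Latin-hypercube
# swarms, and canonical named parameter families for the worked analyses.

#' Log-uniform rate samples
#'
#' Draws rates as `10^u` with `u` uniform on `[log10(lo), log10(hi)]` -
#' the sampling used for the simulation-validation protocol.
#'
#' @param n Number of draws.
#' @param lo,hi Range bounds (positive, `lo < hi`).
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
sample_loguniform <- function(n, lo = 1e-3, hi = 1e3, seed) {
  stopifnot(lo > 0, hi > lo, n >= 1L)
  set.seed(seed)
  10^stats::runif(n, log10(lo), log10(hi))
}

#' Latin-hypercube sample
#'
#' One point per stratum per dimension: each dimension's `n_points` values
#' occupy distinct equal-width bins of its `[low, high]` interval. Used to
#' initialize swarm positions for the optimization module.
#'
#' @param bounds A 2-row matrix (rows `low`, `high`) or a list of
#'   `c(low, high)` pairs, one per dimension.
#' @param n_points Number of points (>= 1).
#' @param seed Integer seed.
#' @return `n_points x d` matrix of samples.
#' @export
latin_hypercube <- function(bounds, n_points, seed) {
  if (is.list(bounds)) bounds <- vapply(bounds, as.numeric, numeric(2))
  stopifnot(is.matrix(bounds), nrow(bounds) == 2L, n_points >= 1L,
            all(bounds[1, ] < bounds[2, ]))
  d <- ncol(bounds)
  set.seed(seed)
  u <- lhs::randomLHS(n_points, d)
  sweep(sweep(u, 2L, bounds[2, ] - bounds[1, ], "*"), 2L, bounds[1, ], "+")
}

#' Random strongly connected labelled digraph
#'
#' Builds a strongly connected graph by construction - a random Hamiltonian
#' cycle as backbone, plus random extra edges - with log-uniform edge
#' labels. These graphs drive the cross-solver and simulation validation
#' fixtures.
#'
#' @param n_vertices Between 2 and 8 (enumeration-oracle territory).
#' @param rate_range `c(lo, hi)` for the log-uniform labels.
#' @param seed Integer seed.
#' @param extra_edges Number of additional random edges (duplicates are
#'   dropped).
#' @return A `labelled_digraph`.
#' @export
random_strongly_connected_graph <- function(n_vertices,
                                            rate_range = c(1e-3, 1e3),
                                            seed, extra_edges = n_vertices) {
  stopifnot(n_vertices >= 2L, n_vertices <= 8L)
  set.seed(seed)
  v <- as.character(seq_len(n_vertices))
  cyc <- sample(v)
  from <- cyc
  to <- c(cyc[-1], cyc[1])
  if (extra_edges > 0L) {
    cand <- expand.grid(from = v, to = v, stringsAsFactors = FALSE)
    cand <- cand[cand$from != cand$to, ]
    key <- paste(cand$from, cand$to)
    cand <- cand[!key %in% paste(from, to), ]
    take <- cand[sample(nrow(cand), min(extra_edges, nrow(cand))), ]
    from <- c(from, take$from)
    to <- c(to, take$to)
  }
  lab <- 10^stats::runif(length(from), log10(rate_range[1]), log10(rate_range[2]))
  labelled_digraph(v, from, to, lab)
}

#' The four-vertex simulation-validation graph
#'
#' The fixed topology of the simulation-validation protocol: three mutually
#' connected transient states, each with a direct edge to the absorbing
#' fourth vertex, giving nine free rates. Every state keeps an exit path,
#' so trajectory lengths stay bounded across the full log-uniform rate
#' range. Trajectories start from vertex 1 and are absorbed at vertex 4.
#'
#' @param rates Numeric vector of nine positive rates, ordered as the
#'   out-edges of vertices 1, 2, 3 toward targets in index order
#'   (`1->2, 1->3, 1->4, 2->1, 2->3, 2->4, 3->1, 3->2, 3->4`).
#' @return A `labelled_digraph` with absorbing vertex `"4"`.
#' @export
protocol_graph_4v <- function(rates) {
  stopifnot(length(rates) == 9L, all(rates > 0))
  from <- rep(c("1", "2", "3"), each = 3L)
  to <- c("2", "3", "4", "1", "3", "4", "1", "2", "4")
  labelled_digraph(c("1", "2", "3", "4"), from, to, rates)
}

#' Canonical parameter families
#'
#' The parameter families used by the worked analyses, addressable by name:
#' \describe{
#'   \item{`rate_scale_sweep`}{`l23 = l32 = 10`, `koff = 1`, `kon = 1`, `r = 10`,
#'     `gamma23 = 10`, `gamma12` either 1 (single-edge case 1.III) or 10
#'     (two-edge case 2.I), with `l12 = l21` swept logarithmically. At
#'     `l12 = 10^-0.5` the dimensionless groups are
#'     `alpha = beta = 10^1.5`.}
#'   \item{`case1III`}{the symmetric single-edge family: `l12 = l21`,
#'     `l23 = l32`, only `B2 -> B3` regulated.}
#'   \item{`equal_rates`}{the incoherent-regulation family with all
#'     horizontal rates and the production rate equal
#'     (`l12 = l21 = l23 = l32 = r`), forward edges regulated.}
#' }
#'
#' @return A named list of constructor functions returning `ladder_spec`
#'   objects.
#' @export
named_model_families <- function() {
  list(
    rate_scale_sweep = function(l12, gamma12 = 1) {
      ladder_spec(3L, fwd_rates = c(l12, 10), bwd_rates = c(l12, 10),
                  fwd_gamma = c(gamma12, 10), bwd_gamma = c(1, 1),
                  kon = 1, koff = 1, r = 10)
    },
    case1III = function(gamma23, l12 = 1, l23 = 10, r = 10,
                        kon = 1, koff = 1) {
      ladder_spec(3L, fwd_rates = c(l12, l23), bwd_rates = c(l12, l23),
                  fwd_gamma = c(1, gamma23), bwd_gamma = c(1, 1),
                  kon = kon, koff = koff, r = r)
    },
    equal_rates = function(gamma12, gamma23, rate = 1, kon = 1, koff = 1) {
      ladder_spec(3L, fwd_rates = c(rate, rate), bwd_rates = c(rate, rate),
                  fwd_gamma = c(gamma12, gamma23), bwd_gamma = c(1, 1),
                  kon = kon, koff = koff, r = rate)
    })
}
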