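#' Steady state via singular value decomposition
#'
#' Computes the stationary distribution as the normalized kernel vector of
#' the column Laplacian: the right singular vector of the smallest singular
#' value, sign-fixed so its largest-magnitude entry is positive and
#' normalized to coordinate sum 1. The matrix is rescaled by its largest
#' entry before decomposition so the separation test is meaningful for
#' badly scaled graphs.
#'
#' @param graph A strongly connected `labelled_digraph`.
#' @param sep_factor The smallest singular value must be below `sep_factor`
#'   times the second-smallest, otherwise the kernel is not numerically
#'   one-dimensional and an error is raised (use [steady_state_gth()] for
#'   stiff rate combinations).
#' @return Named probability vector over the vertices.
#' @seealso [steady_state_gth()], [steady_state_recurrence()]
#' @export
steady_state_decomposition <- function(graph, sep_factor = 1e-8) {
  n <- length(graph$vertices)
  if (n == 1L) return(stats::setNames(1, graph$vertices))
  if (!is_strongly_connected(graph))
    stop("graph must be strongly connected (kernel dimension would exceed 1)")
  L <- laplacian(graph, "column")
  L <- L / max(abs(L))
  sv <- svd(L)
  if (sv$d[n] >= sep_factor * sv$d[n - 1L])
    stop(sprintf(paste0("kernel singular value not separated ",
                        "(%.3g vs %.3g); the graph is numerically stiff - ",
                        "use steady_state_gth()"), sv$d[n], sv$d[n - 1L]))
  v <- sv$v[, n]
  if (v[which.max(abs(v))] < 0) v <- -v
  v[v < 0] <- 0
  stats::setNames(v / sum(v), graph$vertices)
}

#' Steady state by cancellation-free elimination
#'
#' Stationary distribution computed with the Grassmann-Taksar-Heyman (GTH)
#' algorithm, which uses no subtractions and therefore attains small
#' componentwise relative error even when the edge labels span tens of
#' orders of magnitude. This is the package's robust route for
#' rate-scale-separated regimes; for graphs that are not strongly connected
#' it returns the stationary distribution of the recurrent class reachable
#' from the first vertex (transient vertices receive probability 0).
#'
#' @param graph A `labelled_digraph` whose recurrent class contains the
#'   first vertex.
#' @return Named probability vector over the vertices.
#' @export
steady_state_gth <- function(graph) {
  p <- gth_stationary_cpp(rate_matrix(graph))
  stats::setNames(as.numeric(p), graph$vertices)
}

#' Mean first-passage times by linear solve
#'
#' Solves the first-step system for the expected time to reach the terminal
#' vertex from every other vertex: with `q_i` the total exit rate of vertex
#' `i` (including any production edge to the terminal), the equations are
#' `q_i t_i - sum_j l(i -> j) t_j = 1` over non-terminal `j`. The
#' coefficient matrix is the terminal-deleted sub-matrix of the row-oriented
#' Laplacian of the augmented graph. Rows are equilibrated before the
#' solve, and the solution is polished by iterative refinement with
#' compensated residuals accumulated from the raw edge rates, which keeps
#' the result in agreement with the exact spanning-forest ratio even on
#' stiff graphs where assembling the system in double precision would
#' already cost more than the target accuracy.
#'
#' @param gplus Augmented `labelled_digraph` (see [augment_with_terminal()]).
#' @param terminal The absorbing vertex; found automatically when `NULL`.
#' @return Named vector of mean first-passage times for all non-terminal
#'   vertices.
#' @export
mfpt_linear_solve <- function(gplus, terminal = NULL) {
  if (is.null(terminal)) terminal <- terminal_vertex(gplus)
  if (!terminal %in% gplus$vertices) stop("unknown terminal vertex")
  if (any(gplus$from == terminal))
    stop("terminal vertex must have no outgoing edges")
  ig <- as_igraph(gplus)
  d <- igraph::distances(ig, to = terminal, mode = "out")
  if (any(!is.finite(d[setdiff(gplus$vertices, terminal), 1])))
    stop("terminal vertex unreachable from some vertex; system is singular")
  W <- rate_matrix(gplus)
  keep <- gplus$vertices != terminal
  t <- mfpt_refine_cpp(W, match(terminal, gplus$vertices))
  stats::setNames(as.numeric(t), gplus$vertices[keep])
}

#' Spanning-forest recurrence
#'
#' Runs the Chebotarev-Agaev recurrence `Q_{k+1} = -Lr Q_k + sigma_{k+1} I`,
#' `sigma_{k+1} = tr(Lr Q_k) / (k + 1)`, initialized with `Q_0 = I`, on the
#' row-oriented Laplacian `Lr` of the graph. Entry `(i, j)` of `Q_k` is the
#' total weight of spanning forests rooted at `m - k` vertices in which `j`
#' is a root and `i` has a path to `j`; the diagonal of `Q_{m-1}` therefore
#' carries the single-rooted spanning-tree weights that determine the
#' steady state.
#'
#' @param graph A `labelled_digraph` (or a symbolic digraph built with
#'   [sym_digraph()], in which case the matrices hold polynomials).
#' @param up_to_k Highest forest order to compute (defaults to the vertex
#'   count `m`; `Q_m` is identically zero).
#' @return A list with elements `Q` (list of matrices, `Q[[k + 1]]` holding
#'   `Q_k`) and `sigma` (numeric vector, `sigma[k]` holding `sigma_k`).
#' @references Chebotarev & Agaev's recurrence for rooted-forest matrices.
#' @export
chebotarev_recurrence <- function(graph, up_to_k = NULL, ...) {
  UseMethod("chebotarev_recurrence")
}

#' @param precision `"double"` runs the recurrence in double precision;
#'   `"exact"` runs it over one symbol per edge in exact
#'   integer-coefficient polynomial arithmetic and evaluates the forest
#'   polynomials at the numeric labels afterwards. Because every forest
#'   weight is a sum of products of positive labels, the exact route is
#'   componentwise accurate for any label range, at higher cost.
#' @rdname chebotarev_recurrence
#' @export
chebotarev_recurrence.labelled_digraph <- function(graph, up_to_k = NULL,
                                                   precision = c("double",
                                                                 "exact")) {
  precision <- match.arg(precision)
  m <- length(graph$vertices)
  if (is.null(up_to_k)) up_to_k <- m
  if (up_to_k > m) stop("'up_to_k' must not exceed the vertex count")
  if (precision == "exact") {
    syms <- paste0(".e", seq_along(graph$from))
    sg <- sym_digraph(graph$vertices, graph$from, graph$to, as.list(syms))
    rec <- chebotarev_recurrence(sg, up_to_k)
    vals <- stats::setNames(graph$label, syms)
    Q <- lapply(rec$Q, function(Qk) {
      M <- matrix(vapply(Qk, p_eval, numeric(1), values = vals), m, m)
      dimnames(M) <- list(graph$vertices, graph$vertices)
      M
    })
    sigma <- vapply(rec$sigma, p_eval, numeric(1), values = vals)
    return(list(Q = Q, sigma = sigma))
  }
  Lr <- laplacian(graph, "row")
  Q <- vector("list", up_to_k + 1L)
  Q[[1L]] <- diag(1, m)
  dimnames(Q[[1L]]) <- list(graph$vertices, graph$vertices)
  sigma <- numeric(up_to_k)
  if (up_to_k >= 1L) {
    for (k in seq_len(up_to_k)) {
      LQ <- Lr %*% Q[[k]]
      sigma[k] <- sum(diag(LQ)) / k
      Q[[k + 1L]] <- -LQ + diag(sigma[k], m)
      dimnames(Q[[k + 1L]]) <- list(graph$vertices, graph$vertices)
    }
  }
  list(Q = Q, sigma = sigma)
}

#' Steady state via the spanning-forest recurrence
#'
#' The unnormalized steady-state weights are the spanning-tree weights
#' `rho_j`, read off the diagonal of `Q_{m-1}` from
#' [chebotarev_recurrence()]; normalizing by their sum gives the stationary
#' distribution. Works on numeric graphs (double precision) and on symbolic
#' digraphs (exact polynomial arithmetic).
#'
#' @param graph A strongly connected `labelled_digraph` or [sym_digraph()].
#' @return Named probability vector (numeric graphs) or a list of
#'   polynomials `rho` (symbolic graphs, unnormalized).
#' @export
steady_state_recurrence <- function(graph, ...) {
  UseMethod("steady_state_recurrence")
}

#' @param precision `"auto"` (default) runs in double precision and
#'   re-runs in exact polynomial arithmetic when the computed `Q_m`
#'   residual (identically zero in exact arithmetic) reveals cancellation;
#'   `"double"` and `"exact"` force a route.
#' @rdname steady_state_recurrence
#' @export
steady_state_recurrence.labelled_digraph <- function(graph,
                                                     precision = c("auto",
                                                                   "double",
                                                                   "exact")) {
  precision <- match.arg(precision)
  m <- length(graph$vertices)
  run <- function(prec) chebotarev_recurrence(graph, m, precision = prec)
  rec <- run(if (precision == "exact") "exact" else "double")
  rho <- diag(rec$Q[[m]])
  if (precision == "auto" &&
      (any(rho <= 0) || max(abs(rec$Q[[m + 1L]])) > 1e-10 * min(rho))) {
    rec <- run("exact")
    rho <- diag(rec$Q[[m]])
  }
  if (all(rho <= 0))
    stop("all spanning-tree weights vanish: graph is not strongly connected")
  stats::setNames(rho / sum(rho), graph$vertices)
}

#' Mean first-passage times via the spanning-forest recurrence
#'
#' Expresses each mean first-passage time as a ratio of forest weights:
#' `mFPT_i = sum_{j != M} Q_{n-1}(G+)[i, j] / Q_n(G+)[M, M]`, where `n` is
#' the vertex count of the un-augmented graph, the numerator sums weights of
#' doubly rooted forests `{j, M}` with a path `i -> j`, and the denominator
#' is the weight of the spanning trees rooted at the terminal.
#'
#' @inheritParams mfpt_linear_solve
#' @param precision As in [steady_state_recurrence()]: `"auto"` escalates
#'   from double to exact polynomial arithmetic when the `Q_m` residual
#'   reveals cancellation.
#' @return Named vector of mean first-passage times (non-terminal vertices).
#' @export
mfpt_recurrence <- function(gplus, terminal = NULL,
                            precision = c("auto", "double", "exact")) {
  precision <- match.arg(precision)
  if (is.null(terminal)) terminal <- terminal_vertex(gplus)
  m <- length(gplus$vertices)
  keep <- gplus$vertices != terminal
  run <- function(prec) chebotarev_recurrence(gplus, m, precision = prec)
  rec <- run(if (precision == "exact") "exact" else "double")
  den <- rec$Q[[m]][terminal, terminal]
  num <- rowSums(rec$Q[[m - 1L]][keep, keep, drop = FALSE])
  if (precision == "auto" &&
      (den <= 0 || any(num <= 0) ||
         max(abs(rec$Q[[m + 1L]])) > 1e-10 * min(den, num))) {
    rec <- run("exact")
    den <- rec$Q[[m]][terminal, terminal]
    num <- rowSums(rec$Q[[m - 1L]][keep, keep, drop = FALSE])
  }
  if (den <= 0)
    stop("no spanning trees rooted at the terminal: unreachable terminal")
  stats::setNames(num / den, gplus$vertices[keep])
}

#' Brute-force spanning-forest weight (enumeration oracle)
#'
#' Enumerates every spanning forest rooted at `roots` - each non-root vertex
#' contributes exactly one of its outgoing edges and the resulting subgraph
#' must be acyclic - optionally restricted to forests containing a directed
#' path from `path_from` to `path_to`, and returns the summed product of
#' edge labels. Exponential in the vertex count; intended as an independent
#' oracle for the recurrence on small graphs.
#'
#' @param graph A `labelled_digraph` with at most `max_vertices` vertices.
#' @param roots Non-empty character vector of root vertices.
#' @param path_from,path_to Optional vertices: restrict to forests in which
#'   `path_from` lies in the tree rooted at `path_to`.
#' @param max_vertices Enumeration size cap (default 8).
#' @return The total forest weight (numeric scalar, 0 for an empty
#'   ensemble).
#' @export
enumerate_forest_weight <- function(graph, roots, path_from = NULL,
                                    path_to = NULL, max_vertices = 8L) {
  m <- length(graph$vertices)
  if (m > max_vertices) stop("graph exceeds the enumeration size cap")
  roots <- as.character(roots)
  if (length(roots) == 0L) stop("'roots' must be non-empty")
  if (!all(roots %in% graph$vertices)) stop("unknown root vertex")
  if (xor(is.null(path_from), is.null(path_to)))
    stop("'path_from' and 'path_to' must be given together")
  if (!is.null(path_to) && !path_to %in% roots)
    stop("'path_to' must be one of the roots")
  nonroot <- setdiff(graph$vertices, roots)
  if (length(nonroot) == 0L) {
    ok <- is.null(path_from) || path_from == path_to
    return(if (ok) 1 else 0)
  }
  out_edges <- lapply(nonroot, function(v) which(graph$from == v))
  if (any(vapply(out_edges, length, integer(1)) == 0L)) return(0)
  idx <- lapply(out_edges, seq_along)
  combos <- as.matrix(expand.grid(idx, KEEP.OUT.ATTRS = FALSE))
  total <- 0
  vmap <- stats::setNames(seq_len(m), graph$vertices)
  root_id <- vmap[roots]
  for (row in seq_len(nrow(combos))) {
    eid <- vapply(seq_along(nonroot),
                  function(j) out_edges[[j]][combos[row, j]], integer(1))
    succ <- rep(NA_integer_, m)
    succ[vmap[nonroot]] <- vmap[graph$to[eid]]
    # follow successors from every non-root; a revisit before a root means
    # a cycle, so the assignment is not a forest
    land <- rep(NA_integer_, m)
    land[root_id] <- root_id
    acyclic <- TRUE
    for (v in vmap[nonroot]) {
      path <- integer(0)
      cur <- v
      while (is.na(land[cur])) {
        if (cur %in% path) { acyclic <- FALSE; break }
        path <- c(path, cur)
        cur <- succ[cur]
      }
      if (!acyclic) break
      land[path] <- land[cur]
    }
    if (!acyclic) next
    if (!is.null(path_from) &&
        land[vmap[path_from]] != vmap[path_to]) next
    total <- total + prod(graph$label[eid])
  }
  total
}
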