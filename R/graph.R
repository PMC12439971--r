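#' Labelled directed graph
#'
#' The basic object of the linear framework: a finite directed graph whose
#' edges carry strictly positive rate labels (units 1/time). Vertices are
#' identified by character labels; there are no self-edges and at most one
#' edge per ordered vertex pair. Every solver in the package consumes this
#' object.
#'
#' @param vertices Character vector of distinct vertex labels (length >= 1).
#' @param from,to Character vectors naming the source and target vertex of
#'   each edge. May be empty.
#' @param label Numeric vector of strictly positive, finite edge labels
#'   (transition rates), parallel to `from`/`to`.
#' @return An object of class `labelled_digraph`.
#' @examples
#' g <- labelled_digraph(c("1", "2"), from = c("1", "2"), to = c("2", "1"),
#'                       label = c(2, 1))
#' laplacian(g)
#' @export
labelled_digraph <- function(vertices, from = character(), to = character(),
                             label = numeric()) {
  vertices <- as.character(vertices)
  from <- as.character(from)
  to <- as.character(to)
  label <- as.numeric(label)
  if (length(vertices) < 1L) stop("graph must have at least one vertex")
  if (anyDuplicated(vertices)) stop("vertex labels must be distinct")
  if (length(from) != length(to) || length(from) != length(label))
    stop("'from', 'to' and 'label' must have equal length")
  if (!all(from %in% vertices) || !all(to %in% vertices))
    stop("edge endpoints must be listed in 'vertices'")
  if (any(from == to)) stop("self-edges are not allowed")
  if (anyDuplicated(paste(from, to, sep = "\r")))
    stop("at most one edge per ordered vertex pair")
  if (any(!is.finite(label)) || any(label <= 0))
    stop("all edge labels must be strictly positive and finite")
  structure(list(vertices = vertices, from = from, to = to, label = label),
            class = "labelled_digraph")
}

#' @export
print.labelled_digraph <- function(x, ...) {
  cat(sprintf("labelled_digraph: %d vertices, %d edges\n",
              length(x$vertices), length(x$from)))
  if (length(x$from)) {
    show <- utils::head(order(x$from, x$to), 12L)
    for (i in show)
      cat(sprintf("  %s -> %s : %g\n", x$from[i], x$to[i], x$label[i]))
    if (length(x$from) > 12L) cat(sprintf("  ... %d more\n", length(x$from) - 12L))
  }
  invisible(x)
}

#' Number of vertices
#' @param graph A `labelled_digraph`.
#' @return Integer vertex count.
#' @export
n_vertices <- function(graph) length(graph$vertices)

#' Transition-rate matrix of a graph
#'
#' Dense matrix of edge labels: entry `(i, j)` is the rate of the edge
#' `i -> j`, zero where no edge exists. Row and column names are the vertex
#' labels. Internal building block for the Laplacian and the solvers.
#'
#' @param graph A `labelled_digraph`.
#' @return A square numeric matrix.
#' @export
rate_matrix <- function(graph) {
  n <- length(graph$vertices)
  W <- matrix(0, n, n, dimnames = list(graph$vertices, graph$vertices))
  if (length(graph$from))
    W[cbind(match(graph$from, graph$vertices),
            match(graph$to, graph$vertices))] <- graph$label
  W
}

#' Laplacian matrix of a labelled digraph
#'
#' In the column orientation, off-diagonal entry `(i, j)` equals the label of
#' the edge `j -> i` (zero if absent) and the diagonal entry `(i, i)` is minus
#' the total outflow of vertex `i`, so that every column sums to zero and the
#' master equation reads `dp/dt = L p`. The row orientation is the negated
#' transpose, used by the first-passage-time system and the spanning-forest
#' recurrence.
#'
#' @param graph A `labelled_digraph`.
#' @param orientation `"column"` (columns sum to zero) or `"row"` (the
#'   negated transpose).
#' @return A square numeric matrix with an `orientation` attribute.
#' @export
laplacian <- function(graph, orientation = c("column", "row")) {
  orientation <- match.arg(orientation)
  W <- rate_matrix(graph)
  L <- t(W)
  diag(L) <- -rowSums(W)
  if (orientation == "row") L <- -t(L)
  attr(L, "orientation") <- orientation
  L
}

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    data.frame(from = graph$from, to = graph$to, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = graph$vertices, stringsAsFactors = FALSE))
}

#' Test strong connectivity
#'
#' A graph is strongly connected when every ordered pair of distinct vertices
#' is joined by a directed path; this is the condition under which the
#' Laplacian kernel is one-dimensional and the steady state unique.
#'
#' @param graph A `labelled_digraph`.
#' @return `TRUE` or `FALSE`.
#' @export
is_strongly_connected <- function(graph) {
  if (length(graph$vertices) == 1L) return(TRUE)
  if (length(graph$from) == 0L) return(FALSE)
  igraph::components(as_igraph(graph), mode = "strong")$no == 1L
}

#' Augment a graph with a terminal production vertex
#'
#' Adds an absorbing vertex (default `"M"`) together with one edge
#' `j -> M`, labelled with the production rate `r`, for every productive
#' vertex `j`. First-passage times to `M` on the augmented graph define the
#' activation time of the system.
#'
#' @param graph A `labelled_digraph`.
#' @param productive Character vector of productive vertices (non-empty,
#'   subset of the graph's vertices).
#' @param r Production rate (> 0).
#' @param terminal Label for the added terminal vertex.
#' @return A `labelled_digraph` with one extra vertex that has no outgoing
#'   edges.
#' @export
augment_with_terminal <- function(graph, productive, r, terminal = "M") {
  productive <- as.character(productive)
  if (length(productive) == 0L) stop("'productive' must be non-empty")
  if (!all(productive %in% graph$vertices))
    stop("productive vertices must belong to the graph")
  if (terminal %in% graph$vertices)
    stop("terminal label already present in the graph")
  if (!is.finite(r) || r <= 0) stop("'r' must be a positive rate")
  labelled_digraph(c(graph$vertices, terminal),
                   from = c(graph$from, productive),
                   to = c(graph$to, rep(terminal, length(productive))),
                   label = c(graph$label, rep(r, length(productive))))
}

#' Identify the terminal (absorbing) vertex of an augmented graph
#' @param gplus A `labelled_digraph` with exactly one vertex lacking
#'   outgoing edges.
#' @return The terminal vertex label.
#' @export
terminal_vertex <- function(gplus) {
  out <- setdiff(gplus$vertices, unique(gplus$from))
  if (length(out) != 1L)
    stop("graph must have exactly one vertex with no outgoing edges")
  out
}
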