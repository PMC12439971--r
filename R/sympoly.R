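# Exact multivariate polynomial arithmetic over edge-label symbols.
#
# Spanning-forest weights are sums of products of distinct edge labels, so
# every quantity the recurrence produces is a polynomial with (small)
# integer coefficients.  Representing those polynomials exactly - an
# exponent matrix plus a coefficient vector - gives a symbolic mode for the
# solvers: the recurrence runs in exact arithmetic and closed forms can be
# verified as polynomial identities by cross-multiplication.

new_poly <- function(vars, expo, coef) {
  structure(list(vars = vars, expo = expo, coef = coef), class = "ratepoly")
}

p_zero <- function() new_poly(character(), matrix(0L, 0L, 0L), numeric())

p_canon <- function(p) {
  keep <- p$coef != 0
  expo <- p$expo[keep, , drop = FALSE]
  coef <- p$coef[keep]
  if (length(coef) == 0L) return(p_zero())
  keepv <- colSums(expo != 0L) > 0L
  vars <- p$vars[keepv]
  expo <- expo[, keepv, drop = FALSE]
  if (length(vars)) {
    o <- order(vars)
    vars <- vars[o]
    expo <- expo[, o, drop = FALSE]
  }
  key <- if (ncol(expo)) apply(expo, 1L, paste, collapse = ",") else rep("", nrow(expo))
  agg <- rowsum(coef, key)
  first <- match(rownames(agg), key)
  expo <- expo[first, , drop = FALSE]
  coef <- as.numeric(agg)
  keep <- coef != 0
  if (!any(keep)) return(p_zero())
  new_poly(vars, expo[keep, , drop = FALSE], coef[keep])
}

#' Polynomial constant
#' @param x A numeric scalar.
#' @return A `ratepoly` constant.
#' @export
p_const <- function(x) {
  if (x == 0) return(p_zero())
  new_poly(character(), matrix(0L, 1L, 0L), as.numeric(x))
}

#' Polynomial variable (edge-label symbol)
#' @param name Symbol name, e.g. `"l12"`.
#' @return A degree-one `ratepoly`.
#' @export
p_var <- function(name) {
  new_poly(as.character(name), matrix(1L, 1L, 1L), 1)
}

#' Coerce to polynomial
#' @param x A `ratepoly`, numeric scalar, or character symbol name.
#' @return A `ratepoly`.
#' @export
as_poly <- function(x) {
  if (inherits(x, "ratepoly")) x
  else if (is.numeric(x) && length(x) == 1L) p_const(x)
  else if (is.character(x) && length(x) == 1L) p_var(x)
  else stop("cannot coerce to polynomial")
}

p_align <- function(a, b) {
  vars <- sort(union(a$vars, b$vars))
  widen <- function(p) {
    expo <- matrix(0L, nrow(p$expo), length(vars))
    if (length(p$vars)) expo[, match(p$vars, vars)] <- p$expo
    new_poly(vars, expo, p$coef)
  }
  list(widen(a), widen(b))
}

#' Polynomial arithmetic
#' @param a,b Polynomials (see [as_poly()] for accepted inputs).
#' @return A `ratepoly`.
#' @export
p_add <- function(a, b) {
  ab <- p_align(as_poly(a), as_poly(b))
  p_canon(new_poly(ab[[1]]$vars, rbind(ab[[1]]$expo, ab[[2]]$expo),
                   c(ab[[1]]$coef, ab[[2]]$coef)))
}

#' @rdname p_add
#' @export
p_sub <- function(a, b) p_add(a, p_scale(b, -1))

#' @rdname p_add
#' @export
p_mul <- function(a, b) {
  a <- as_poly(a); b <- as_poly(b)
  if (length(a$coef) == 0L || length(b$coef) == 0L) return(p_zero())
  ab <- p_align(a, b)
  a <- ab[[1]]; b <- ab[[2]]
  na <- nrow(a$expo); nb <- nrow(b$expo)
  ia <- rep(seq_len(na), each = nb)
  ib <- rep(seq_len(nb), times = na)
  p_canon(new_poly(a$vars, a$expo[ia, , drop = FALSE] + b$expo[ib, , drop = FALSE],
                   a$coef[ia] * b$coef[ib]))
}

#' Multiply a polynomial by a scalar
#' @param p A polynomial.
#' @param s A numeric scalar.
#' @return A `ratepoly`.
#' @export
p_scale <- function(p, s) {
  p <- as_poly(p)
  if (s == 0 || length(p$coef) == 0L) return(p_zero())
  new_poly(p$vars, p$expo, p$coef * s)
}

#' Test whether a polynomial is identically zero
#' @param p A polynomial.
#' @param tol Absolute tolerance on coefficients (the engine is exact for
#'   integer coefficients; the tolerance only guards scaled intermediates).
#' @return `TRUE` or `FALSE`.
#' @export
p_is_zero <- function(p, tol = 1e-9) {
  p <- p_canon(as_poly(p))
  length(p$coef) == 0L || all(abs(p$coef) <= tol)
}

#' Test polynomial equality
#' @param a,b Polynomials.
#' @param tol Coefficient tolerance passed to [p_is_zero()].
#' @return `TRUE` when `a - b` is identically zero.
#' @export
p_equal <- function(a, b, tol = 1e-9) p_is_zero(p_sub(a, b), tol)

#' Evaluate a polynomial at numeric values
#' @param p A polynomial.
#' @param values Named numeric vector covering all symbols of `p`.
#' @return Numeric scalar.
#' @export
p_eval <- function(p, values) {
  p <- as_poly(p)
  if (length(p$coef) == 0L) return(0)
  if (!all(p$vars %in% names(values)))
    stop("missing values for: ", paste(setdiff(p$vars, names(values)), collapse = ", "))
  v <- values[p$vars]
  sum(p$coef * apply(p$expo, 1L, function(e) prod(v^e)))
}

#' @export
print.ratepoly <- function(x, ...) {
  x <- p_canon(x)
  if (length(x$coef) == 0L) { cat("0\n"); return(invisible(x)) }
  terms <- vapply(seq_along(x$coef), function(i) {
    mono <- x$expo[i, ]
    sym <- x$vars[mono > 0]
    pw <- mono[mono > 0]
    ms <- paste(ifelse(pw == 1L, sym, paste0(sym, "^", pw)), collapse = "*")
    cf <- x$coef[i]
    if (ms == "") format(cf)
    else if (cf == 1) ms
    else if (cf == -1) paste0("-", ms)
    else paste0(format(cf), "*", ms)
  }, character(1))
  cat(paste(terms, collapse = " + "), "\n")
  invisible(x)
}

#' @export
Ops.ratepoly <- function(e1, e2) {
  switch(.Generic,
         "+" = p_add(e1, e2),
         "-" = if (missing(e2)) p_scale(e1, -1) else p_sub(e1, e2),
         "*" = p_mul(e1, e2),
         stop(sprintf("operation '%s' not defined for polynomials", .Generic)))
}

# --- symbolic digraphs -------------------------------------------------

#' Labelled digraph with symbolic edge labels
#'
#' Like [labelled_digraph()] but the labels are polynomials in named
#' symbols (or anything [as_poly()] accepts), enabling exact symbolic runs
#' of the spanning-forest recurrence on small graphs.
#'
#' @param vertices Character vector of vertex labels.
#' @param from,to Edge endpoint vectors.
#' @param labels List of edge labels: `ratepoly` objects, symbol names, or
#'   numeric constants.
#' @return An object of class `sym_digraph`.
#' @examples
#' g <- sym_digraph(c("1", "2"), c("1", "2"), c("2", "1"), list("a", "b"))
#' sym_steady_state(g)  # rho = (b, a)
#' @export
sym_digraph <- function(vertices, from, to, labels) {
  vertices <- as.character(vertices)
  from <- as.character(from); to <- as.character(to)
  if (length(from) != length(to) || length(from) != length(labels))
    stop("'from', 'to' and 'labels' must have equal length")
  if (!all(c(from, to) %in% vertices)) stop("edge endpoints must be vertices")
  if (any(from == to)) stop("self-edges are not allowed")
  structure(list(vertices = vertices, from = from, to = to,
                 labels = lapply(labels, as_poly)),
            class = "sym_digraph")
}

sym_row_laplacian <- function(g) {
  m <- length(g$vertices)
  Lr <- matrix(list(p_zero()), m, m, dimnames = list(g$vertices, g$vertices))
  for (e in seq_along(g$from)) {
    i <- match(g$from[e], g$vertices)
    j <- match(g$to[e], g$vertices)
    Lr[[i, j]] <- p_sub(Lr[[i, j]], g$labels[[e]])
    Lr[[i, i]] <- p_add(Lr[[i, i]], g$labels[[e]])
  }
  Lr
}

sym_matmul <- function(A, B) {
  m <- nrow(A)
  C <- matrix(list(p_zero()), m, m, dimnames = dimnames(A))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    acc <- p_zero()
    for (k in seq_len(m)) {
      a <- A[[i, k]]; b <- B[[k, j]]
      if (length(a$coef) && length(b$coef)) acc <- p_add(acc, p_mul(a, b))
    }
    C[[i, j]] <- acc
  }
  C
}

#' @export
chebotarev_recurrence.sym_digraph <- function(graph, up_to_k = NULL, ...) {
  m <- length(graph$vertices)
  if (is.null(up_to_k)) up_to_k <- m
  if (up_to_k > m) stop("'up_to_k' must not exceed the vertex count")
  Lr <- sym_row_laplacian(graph)
  I <- matrix(list(p_zero()), m, m, dimnames = dimnames(Lr))
  for (i in seq_len(m)) I[[i, i]] <- p_const(1)
  Q <- vector("list", up_to_k + 1L)
  Q[[1L]] <- I
  sigma <- vector("list", up_to_k)
  for (k in seq_len(up_to_k)) {
    LQ <- sym_matmul(Lr, Q[[k]])
    tr <- p_zero()
    for (i in seq_len(m)) tr <- p_add(tr, LQ[[i, i]])
    sigma[[k]] <- p_scale(tr, 1 / k)
    Qn <- matrix(list(p_zero()), m, m, dimnames = dimnames(Lr))
    for (i in seq_len(m)) for (j in seq_len(m)) {
      Qn[[i, j]] <- if (i == j) p_sub(sigma[[k]], LQ[[i, j]])
                    else p_scale(LQ[[i, j]], -1)
    }
    Q[[k + 1L]] <- Qn
  }
  list(Q = Q, sigma = sigma)
}

#' Symbolic steady state (unnormalized spanning-tree weights)
#'
#' Runs the recurrence in exact polynomial arithmetic and returns the
#' spanning-tree weight polynomial `rho_j` for each vertex; the steady-state
#' probability of `j` is `rho_j / sum(rho)`.
#'
#' @param graph A [sym_digraph()].
#' @return Named list of `ratepoly` objects.
#' @export
sym_steady_state <- function(graph) {
  m <- length(graph$vertices)
  rec <- chebotarev_recurrence(graph, m - 1L)
  rho <- lapply(seq_len(m), function(i) rec$Q[[m]][[i, i]])
  names(rho) <- graph$vertices
  rho
}

#' Symbolic mean first-passage times as forest-weight ratios
#'
#' For an augmented symbolic graph, returns the numerator polynomial for
#' each non-terminal start vertex and the common denominator (the weight of
#' spanning trees rooted at the terminal), so that
#' `mFPT_i = num[[i]] / den` exactly.
#'
#' @param gplus A [sym_digraph()] with one absorbing terminal vertex.
#' @param terminal The terminal vertex label.
#' @return List with elements `num` (named list of polynomials) and `den`.
#' @export
sym_mfpt <- function(gplus, terminal) {
  m <- length(gplus$vertices)
  if (any(gplus$from == terminal))
    stop("terminal vertex must have no outgoing edges")
  rec <- chebotarev_recurrence(gplus, m - 1L)
  keep <- which(gplus$vertices != terminal)
  ti <- match(terminal, gplus$vertices)
  den <- rec$Q[[m]][[ti, ti]]
  num <- lapply(keep, function(i) {
    acc <- p_zero()
    for (j in keep) acc <- p_add(acc, rec$Q[[m - 1L]][[i, j]])
    acc
  })
  names(num) <- gplus$vertices[keep]
  list(num = num, den = den)
}

#' Rational functions of polynomials
#'
#' Minimal exact rational-function layer used to verify closed forms:
#' subtraction by cross-multiplication and equality testing as the
#' polynomial identity `num_a * den_b - num_b * den_a = 0`.
#'
#' @param num,den Polynomials ([as_poly()] inputs).
#' @return An object of class `ratefrac`.
#' @export
rfrac <- function(num, den) {
  structure(list(num = as_poly(num), den = as_poly(den)), class = "ratefrac")
}

#' @rdname rfrac
#' @param a,b Rational functions.
#' @export
rfrac_sub <- function(a, b) {
  rfrac(p_sub(p_mul(a$num, b$den), p_mul(b$num, a$den)), p_mul(a$den, b$den))
}

#' @rdname rfrac
#' @export
rfrac_add <- function(a, b) {
  rfrac(p_add(p_mul(a$num, b$den), p_mul(b$num, a$den)), p_mul(a$den, b$den))
}

#' @rdname rfrac
#' @export
rfrac_mul <- function(a, b) rfrac(p_mul(a$num, b$num), p_mul(a$den, b$den))

#' @rdname rfrac
#' @export
rfrac_div <- function(a, b) rfrac(p_mul(a$num, b$den), p_mul(a$den, b$num))

#' @rdname rfrac
#' @param tol Coefficient tolerance.
#' @export
rfrac_equal <- function(a, b, tol = 1e-9) {
  p_is_zero(p_sub(p_mul(a$num, b$den), p_mul(b$num, a$den)), tol)
}
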