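#' Chain model specification
#'
#' A chain (pipeline) model `C_N`: `N` states reversibly connected in a
#' line, producing the readout from the last state. The ligand is implicit;
#' the rates are constants, so the response of a chain is flat in
#' concentration unless rates are supplied as functions of `x`.
#'
#' @param N Number of states (>= 2).
#' @param fwd_rates,bwd_rates Forward (`i -> i+1`) and backward
#'   (`i+1 -> i`) rates, length `N - 1`, in units of the degradation rate
#'   `delta`. Entries may alternatively be functions of the concentration
#'   `x` returning a positive rate.
#' @param r Production rate from state `N` (units of `delta`).
#' @param delta Degradation rate of the readout; fixed to 1 by convention so
#'   that all rates are expressed in its units.
#' @return An object of class `chain_spec`.
#' @export
chain_spec <- function(N, fwd_rates, bwd_rates, r, delta = 1) {
  N <- as.integer(N)
  if (N < 2L) stop("'N' must be at least 2")
  if (length(fwd_rates) != N - 1L || length(bwd_rates) != N - 1L)
    stop("rate vectors must have length N - 1")
  chk <- function(v, nm) {
    num <- !vapply(v, is.function, logical(1))
    vals <- unlist(v[num], use.names = FALSE)
    if (length(vals) && (any(!is.finite(vals)) || any(vals <= 0)))
      stop(sprintf("all %s must be positive and finite", nm))
  }
  chk(as.list(fwd_rates), "forward rates"); chk(as.list(bwd_rates), "backward rates")
  if (!is.finite(r) || r <= 0) stop("'r' must be positive")
  if (!is.finite(delta) || delta <= 0) stop("'delta' must be positive")
  structure(list(N = N, fwd_rates = as.list(fwd_rates),
                 bwd_rates = as.list(bwd_rates), r = r, delta = delta),
            class = "chain_spec")
}

#' Ladder model specification
#'
#' The ladder model `D_N` on `2 N` states: an unbound chain `U1 ... UN` and a
#' bound chain `B1 ... BN`, joined at every index by a binding edge
#' `Ui -> Bi` with label `kon * x` and an unbinding edge `Bi -> Ui` with
#' label `koff`. The horizontal rates of the bound chain are those of the
#' unbound chain multiplied by dimensionless regulatory factors `gamma`;
#' a factor above 1 means the bound ligand promotes that transition, below 1
#' that it hinders it. The readout is produced at rate `r` from the
#' productive vertices `UN` and `BN`.
#'
#' @param N Number of rungs (>= 2).
#' @param fwd_rates,bwd_rates Unbound-chain forward and backward rates,
#'   length `N - 1`, in units of `delta`.
#' @param fwd_gamma,bwd_gamma Regulatory factors for the bound-chain forward
#'   and backward transitions (dimensionless, > 0), length `N - 1`.
#'   Default 1 (no regulation).
#' @param kon Binding rate constant, units of `delta` per concentration unit.
#' @param koff Unbinding rate, units of `delta`.
#' @param r Production rate from `UN` and `BN` (units of `delta`).
#' @param delta Readout degradation rate; 1 by convention.
#' @return An object of class `ladder_spec`.
#' @examples
#' sp <- ladder_spec(3, fwd_rates = c(1, 10), bwd_rates = c(1, 10),
#'                   fwd_gamma = c(1, 10), kon = 1, koff = 1, r = 10)
#' instantiate_ladder(sp, x = 1)
#' @export
ladder_spec <- function(N, fwd_rates, bwd_rates,
                        fwd_gamma = rep(1, N - 1), bwd_gamma = rep(1, N - 1),
                        kon, koff, r, delta = 1) {
  N <- as.integer(N)
  if (N < 2L) stop("'N' must be at least 2")
  lens <- c(length(fwd_rates), length(bwd_rates),
            length(fwd_gamma), length(bwd_gamma))
  if (any(lens != N - 1L))
    stop("rate and gamma vectors must have length N - 1")
  vals <- c(fwd_rates, bwd_rates, fwd_gamma, bwd_gamma, kon, koff, r, delta)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all rates and regulatory factors must be positive and finite")
  structure(list(N = N,
                 fwd_rates = as.numeric(fwd_rates),
                 bwd_rates = as.numeric(bwd_rates),
                 fwd_gamma = as.numeric(fwd_gamma),
                 bwd_gamma = as.numeric(bwd_gamma),
                 kon = kon, koff = koff, r = r, delta = delta),
            class = "ladder_spec")
}

#' @export
print.ladder_spec <- function(x, ...) {
  cat(sprintf("ladder_spec D%d: kon=%g koff=%g r=%g delta=%g\n",
              x$N, x$kon, x$koff, x$r, x$delta))
  cat("  fwd rates:", format(x$fwd_rates), " gamma:", format(x$fwd_gamma), "\n")
  cat("  bwd rates:", format(x$bwd_rates), " gamma:", format(x$bwd_gamma), "\n")
  invisible(x)
}

chain_rate_at <- function(v, x) if (is.function(v)) v(x) else v

#' Instantiate a chain model as a labelled digraph
#' @param spec A `chain_spec`.
#' @param x Concentration at which function-valued rates are evaluated
#'   (ignored for constant rates).
#' @return A `labelled_digraph` with vertices `"1" ... "N"`.
#' @export
instantiate_chain <- function(spec, x = 0) {
  stopifnot(inherits(spec, "chain_spec"))
  N <- spec$N
  v <- as.character(seq_len(N))
  fwd <- vapply(spec$fwd_rates, chain_rate_at, numeric(1), x = x)
  bwd <- vapply(spec$bwd_rates, chain_rate_at, numeric(1), x = x)
  labelled_digraph(v,
                   from = c(v[-N], v[-1]),
                   to = c(v[-1], v[-N]),
                   label = c(fwd, bwd))
}

#' Instantiate a ladder model at a given ligand concentration
#'
#' Returns the `2 N`-vertex graph `D_N` at concentration `x`: unbound-chain
#' edges with the base rates, bound-chain edges with the gamma-scaled rates,
#' unbinding edges at `koff`, and binding edges at `kon * x`. At `x = 0` the
#' binding edges are omitted entirely (the type forbids non-positive labels,
#' and the bound states are then unreachable), so the returned graph is not
#' strongly connected.
#'
#' @param spec A `ladder_spec`.
#' @param x Ligand concentration (>= 0), in concentration units.
#' @return A `labelled_digraph` with vertices `U1..UN`, `B1..BN`.
#' @export
instantiate_ladder <- function(spec, x) {
  stopifnot(inherits(spec, "ladder_spec"))
  if (!is.finite(x) || x < 0) stop("'x' must be a non-negative concentration")
  N <- spec$N
  U <- paste0("U", seq_len(N))
  B <- paste0("B", seq_len(N))
  from <- c(U[-N], U[-1], B[-N], B[-1], B)
  to   <- c(U[-1], U[-N], B[-1], B[-N], U)
  lab  <- c(spec$fwd_rates, spec$bwd_rates,
            spec$fwd_gamma * spec$fwd_rates, spec$bwd_gamma * spec$bwd_rates,
            rep(spec$koff, N))
  if (x > 0) {
    from <- c(from, U); to <- c(to, B); lab <- c(lab, rep(spec$kon * x, N))
  }
  labelled_digraph(c(U, B), from = from, to = to, label = lab)
}

#' Productive vertices of a model
#' @param spec A `chain_spec` or `ladder_spec`.
#' @return Character vector of productive vertex labels (`"N"` for chains,
#'   `UN` and `BN` for ladders).
#' @export
productive_vertices <- function(spec) {
  if (inherits(spec, "chain_spec")) as.character(spec$N)
  else if (inherits(spec, "ladder_spec")) paste0(c("U", "B"), spec$N)
  else stop("unknown spec type")
}

#' The unbound subgraph of a ladder at zero ligand
#'
#' The `N`-state chain over the unbound vertices only, used for explicit
#' `x = 0` evaluations (e.g. the equilibrium-start weights).
#' @param spec A `ladder_spec`.
#' @return A `labelled_digraph` on `U1 ... UN`.
#' @export
unbound_chain <- function(spec) {
  stopifnot(inherits(spec, "ladder_spec"))
  N <- spec$N
  U <- paste0("U", seq_len(N))
  labelled_digraph(U,
                   from = c(U[-N], U[-1]),
                   to = c(U[-1], U[-N]),
                   label = c(spec$fwd_rates, spec$bwd_rates))
}

#' Serialize a model specification to JSON
#'
#' Writes an explicit, unit-annotated JSON document with a schema version
#' field; [spec_from_json()] restores the object.
#'
#' @param spec A `chain_spec` or `ladder_spec`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
spec_to_json <- function(spec, path = NULL) {
  type <- if (inherits(spec, "ladder_spec")) "ladder" else "chain"
  doc <- list(schema_version = 1L, type = type,
              units = list(rates = "delta", kon = "delta per c.u."),
              fields = unclass(spec))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Restore a model specification from JSON
#' @param input A JSON string or path to a JSON file written by
#'   [spec_to_json()].
#' @return A `chain_spec` or `ladder_spec`.
#' @export
spec_from_json <- function(input) {
  doc <- jsonlite::fromJSON(input)
  if (is.null(doc$schema_version)) stop("missing schema_version field")
  f <- doc$fields
  if (identical(doc$type, "ladder"))
    ladder_spec(f$N, f$fwd_rates, f$bwd_rates, f$fwd_gamma, f$bwd_gamma,
                f$kon, f$koff, f$r, f$delta)
  else
    chain_spec(f$N, f$fwd_rates, f$bwd_rates, f$r, f$delta)
}
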