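---
title: "Methods: models, solvers, and the search for decoupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, solvers, and the search for decoupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fptdecouple)
```

# The model

A ligand-regulated molecular system is represented as a continuous-time
Markov process on a finite labelled digraph: vertices are system states,
edges are transitions, and each edge label is a transition rate. The
probability vector evolves under the master equation `dp/dt = L p`, with
`L` the column-oriented graph Laplacian (off-diagonal `(i, j)` entry the
rate of `j -> i`, columns summing to zero). When the graph is strongly
connected the Laplacian kernel is one-dimensional and the normalized
kernel vector is the unique stationary distribution.

Two model families are built in. Chain models `C_N` connect `N` states
reversibly in a line; `C2` is the telegraph model of transcriptional
bursting. Ladder models `D_N` make ligand binding explicit: an unbound
chain `U1..UN` and a bound chain `B1..BN` joined at each rung by a
binding edge `Ui -> Bi` with label `kon * x` (`x` the ligand
concentration) and an unbinding edge `Bi -> Ui` with label `koff`. The
bound chain's horizontal rates are the unbound rates multiplied by
dimensionless regulatory factors `gamma_{i,j}`; a factor above one means
the bound ligand promotes that transition, below one that it hinders it.
Binding and unbinding rates are assumed independent of the rung index:
regulation acts only while the ligand is bound, and progression toward
the productive state does not feed back on the ligand's own kinetics.

The readout is produced at rate `r` from the productive states (state
`N` for chains; `UN` and `BN` for ladders) and degrades at first order
with rate `delta`. Every rate is expressed in units of `delta`
(equivalently `delta = 1`), and `kon` in units of `delta` per
concentration unit; this fixes the time scale and leaves the biology in
the rate ratios.

Two outputs summarize the response at concentration `x`:

* the steady-state level, `SS(x) = (r / delta) * sum(p*_v)` over
  productive `v` — so the normalized level `SS̄(x)` is simply the summed
  stationary probability of the productive states, bounded in `[0, 1]`;
* the activation time, the mean first-passage time (mFPT) to a terminal
  vertex `M` on the augmented graph `G+` that adds one edge `j -> M` at
  rate `r` from each productive `j`. The default start is `U1` (a
  freshly reset regulatory state); the `equilibrium_unbound` mode
  averages the mFPT over the unbound states weighted by their
  zero-ligand stationary probabilities, appropriate for systems that
  equilibrate before the ligand appears.

Normalizing the mFPT by its maximum over the evaluated grid (the maximum
over `x > 0`; the explicit `x = 0` point, when requested, enters the
steady-state range but not the mFPT normalization) gives `mFPT̄ ∈ (0, 1]`.
Dynamic ranges are max-minus-min of each normalized curve, and the
coupling score is

`f = 1 − ΔSS̄ + ΔmFPT̄`,

zero at perfect decoupling and greater than one whenever the activation
time varies more than the level. The sign convention is pinned by two
properties the score must have: perfect decoupling (`ΔSS̄ = 1`,
`ΔmFPT̄ = 0`) gives `f = 0`, and any response whose activation time
varies more than its level (`ΔSS̄ < ΔmFPT̄`) scores above one. The
variant that subtracts both ranges fails the second property and is not
used.

# Solvers and numerical policy

Three independent routes compute the same quantities; their mutual
agreement is the package's core correctness argument, enforced by the
test-suite on hundreds of randomly generated strongly connected graphs.

**Dense linear algebra.** `steady_state_decomposition()` takes the right
singular vector of the smallest singular value of the (rescaled)
Laplacian. The smallest singular value must be below `1e-8` times the
second-smallest; otherwise the kernel is numerically not
one-dimensional (e.g. two cycles joined by vanishingly weak edges) and
the function refuses rather than guesses. `mfpt_linear_solve()` solves
the first-step system — the terminal-deleted sub-matrix of the
row-oriented Laplacian of `G+` against a vector of ones — with row
equilibration and iterative refinement whose residuals are accumulated
in compensated (double-double) arithmetic directly from the raw edge
rates. The refinement matters: on stiff graphs the first-step matrix
condition number reaches `1e13`, where even assembling the matrix in
double precision perturbs the solution by more than `1e-9`; computing
residuals from the rates themselves makes the refined solution agree
with the exact forest-weight ratio to machine precision.

**The spanning-forest recurrence.** The Chebotarev–Agaev recurrence
`Q_{k+1} = −L̃ Q_k + σ_{k+1} I`, `σ_{k+1} = tr(L̃ Q_k)/(k+1)`, `Q_0 = I`,
run on the row-oriented Laplacian `L̃ = −L^T`, produces matrices of
rooted-forest weights in polynomial time: the diagonal of `Q_{m−1}` holds
the spanning-tree weights `rho_j` whose normalization is the steady
state, and mFPTs are ratios of doubly rooted forest weights of `G+`
(`mfpt_recurrence()`). The row orientation is forced by the weights
themselves: on the two-cycle with labels `a` (`1 -> 2`) and `b`
(`2 -> 1`), only the row-oriented run yields `Q_1` diagonal `(b, a)`,
the correct single-root tree weights, which the enumeration oracle
confirms.

In double precision the recurrence cancels catastrophically when edge
labels span many orders of magnitude. The package therefore carries an
*exact* mode: the recurrence is run over one symbol per edge in exact
integer-coefficient polynomial arithmetic (every forest weight is a sum
of products of distinct edge labels, so all coefficients are small
nonnegative integers and the final evaluation at positive rates involves
no subtraction at all). The default `precision = "auto"` runs in double
and re-runs exactly when the computed `Q_m` — identically zero in exact
arithmetic — betrays cancellation, using the threshold
`max|Q_m| > 1e-10 * min(relevant weights)`. The same polynomial engine
provides the fully symbolic mode used to re-derive closed forms as
rational-function identities (cross-multiplied polynomial equality, no
floating tolerance beyond an integer-coefficient guard).

**Enumeration oracle.** `enumerate_forest_weight()` enumerates spanning
forests directly (one outgoing edge per non-root vertex, acyclicity
checked by path-following), capped at eight vertices. Exponential and
only for validation — it arbitrates any disagreement between the fast
routes.

For stationary distributions the workhorse behind the response-curve
kernels is the Grassmann–Taksar–Heyman (GTH) elimination, which uses no
subtractions and is componentwise accurate at any label range — the
test-suite checks detailed-balance ratios at labels spanning twenty
orders of magnitude (`gamma = 1e9` at `x = 1e20`). A caveat stated here
because it shapes the validation metrics: a dense SVD delivers *norm*
accuracy of the kernel vector, not relative accuracy of entries that are
tiny compared to the largest one, so SVD-vs-recurrence agreement is
asserted norm-relative while GTH, enumeration, and both mFPT routes are
held to per-entry relative agreement (all at `1e-9`; observed
deviations are orders of magnitude smaller).

# Response curves and diagnostics

The reference concentration grid is 1000 log-spaced points on
`[1e-20, 1e20]` (log10 step ~0.04004), wide enough that the endpoints
stand in for the zero- and saturating-ligand limits for any parameter
set whose binding scale `koff / kon` lies within the searched bounds. An
explicit `x = 0` evaluation on the unbound subgraph is available
(binding edges are omitted at `x = 0`, not given zero labels, since the
bound states are then unreachable).

`decoupling_summary()` collects: the two dynamic ranges and `f`; the
half-activation concentration `x_half` (log-linear interpolation of the
first midpoint crossing; flagged `NA` for a flat level); the
fastest-response concentration `x_fast` (grid argmin of `mFPT̄`, ties —
within `1e-12` on the normalized scale, so numerically flat curves
resolve deterministically — broken toward the smallest concentration);
monotonicity flags (tolerance `1e-6` of the curve range, since
monotonicity is exact in the relevant regimes but numerics need slack);
and the traversal-interval overlap. The overlap of two curves is
computed from the log-concentration intervals over which each traverses
the central 90% of its range (the 5%-to-95% band) via `max(0, min(b,d) − max(a,c)) / ((b−a) + (d−c))`: zero for
disjoint ranges, one half for identical ones. The symmetric 5%/95%
anchor levels are a package convention; "traverses 90% of its range"
does not by itself fix where the band sits. It quantifies
concentration-dependent decoupling, where both outputs vary but over
largely non-overlapping input ranges.

Closed forms for `C2`, `D2`, and the eight `D3` regulatory cases
(`analytic_library` functions) were re-derived from first-step analysis
and the limiting chains at `x = 0` and `x -> infinity`, verified
symbolically by the polynomial engine, and are cross-checked against
grid numerics to `1e-4` in the tests. Internal consistency is enforced
algebraically: setting the second regulatory factor of any two-edge form
to one reduces it exactly to the corresponding single-edge form, the
steady-state ranges follow from the detailed-balance limiting chains
(e.g. the symmetric case-1.III range `2(gamma−1)/(3(gamma+2))`,
saturating at two thirds), and all activation-time ranges normalize by
the zero-ligand maximum, which is where the mFPT of an activating
response peaks.

# Stochastic validation

`gillespie_fpt()` samples first-passage times by direct stochastic
simulation. Each trajectory derives its own xorshift128+ stream from
`(seed, trajectory index)` via splitmix64, so samples are reproducible
and extending a run leaves earlier trajectories unchanged. Hitting the
per-trajectory event cap (default `1e7`) is an error, never a silent
censoring.

The validation protocol samples 100 combinations of rates from a
log-uniform distribution on `[1e-3, 1e3]` and compares the Monte-Carlo
mFPT at `1e4` trajectories against the exact solvers on a fixed
four-vertex graph, requiring agreement within four standard errors in
at least 99 of 100 combinations. The graph (`protocol_graph_4v()`) has
three mutually connected transient states, each with a direct edge to
the absorbing fourth vertex. That topology is a deliberate choice: it
keeps an exit path from every state, so expected trajectory lengths stay
bounded (about `1e8` events for the whole protocol) across the full rate
range, whereas chain topologies under the same sampling generate
rate-ratio products that make escape probabilities vanish and expected
event counts astronomically large. The statistical property being tested
is topology-independent.

# The optimization campaigns

`decoupling_problem()` fixes a search space over the three-rung ladder:
rates and `kon` bounded in `[1e-4, 1e4]` (units of `delta`; `kon` per
concentration unit), regulatory factors of the chosen regulated edges in
`[1, 1e3]` or `[1e-3, 1e3]` depending on the campaign, optionally an
equality tie (`l12 = l23 = r`, `l21 = l32`) and a rate scale constraint
(RSC): `|log10|` of each horizontal-rate ratio at most the RSC constant.
The absolute value is deliberate — a one-sided bound would not force the
rates onto a common scale. Constraints enter the objective as an
additive penalty `10 * sum(max(0, g_k))`; the tests assert that reported
bests satisfy the constraints to `1e-9`, so the penalty never launders
infeasible solutions.

`pso_minimize()` is a standard global-best particle swarm in
log10-parameter space: Latin-hypercube initialization, velocity update
`V <- omega V + c1 r1 (P − X) + c2 r2 (G − X)` with fresh uniform noise
per particle and dimension, positions clipped to the nearest bound,
`c1 = c2 = 2`, and inertia decaying linearly from 0.9 to 0.4 over the
generation budget — a simple, fully reproducible schedule, recorded in
the result metadata so campaigns are comparable. Defaults: 25 particles
(a standard swarm size), 200 generations (a deterministic cap in place
of any wall-clock budget), termination when
the best score stays below the threshold (0.1 by default) for more than
five consecutive generations. The objective evaluates response curves on
a reduced grid of 161 log-spaced points on `[1e-12, 1e12]` — sufficient
because the half-activation point `~koff/kon` is confined by the
parameter box well inside that span — and `filter_solutions()` re-scores
candidate solutions on the full reference grid before any selection.
Replicate `i` of a campaign uses seed `base_seed + i`.

The two campaign families the tests exercise: the single-edge problem
(only `B2 -> B3` regulated, `gamma23` in `[1, 1e3]`), where nearly all
of 20 replicates reach `f < 0.1` through rate scale separation; and the
two-forward-edge problem under an RSC sweep, where tightening the
constraint raises the attainable coupling score and moves the optimum
from the single-edge regime (`gamma12 ≈ 1`, large `gamma23`) into the
incoherent regime (`gamma12 < 1 < gamma23`). The incoherent mechanism is
further pinned by the closed-form balance relation
`gamma12 = (gamma23 + 2) / (5 gamma23 − 2)` under equal rates, which
equalizes the activation-time endpoints and has solutions with both
factors on the same side of one only at the trivial fixed point.

# What the generators emulate, and what they do not

The fixture generators provide every random input the pipeline needs:
log-uniform rates over stated ranges, Latin-hypercube swarm
initialization (one point per stratum per dimension), strongly connected
random graphs built on a Hamiltonian-cycle backbone (connectivity by
construction rather than rejection, keeping generation deterministic and
linear-time), and the named parameter families of the worked analyses.
All generators are deterministic under a fixed seed.

These are *model-space* fixtures: no experimental noise, no measurement
window, no cell-to-cell variability. Passing tests therefore certify the
mathematics and the search machinery — exact outputs, their closed
forms, and the existence and character of decoupling regimes within the
stated model class — not that any particular biological system occupies
those regimes. Further scope limits: a single ligand and binding site;
unbinding independent of the system state; the activation time is the
time to the *first* production event (measures such as time-to-threshold
behave differently and depend on the degradation rate); no transient
solution of the master equation; and closed forms only for `N <= 3`
(the ladder constructor accepts any `N >= 2`, and all numeric solvers
work on arbitrary strongly connected graphs).

# Problem sizes

The shipped test-suite and acceptance script use desk-scale problem
sizes, chosen once: 200 random graphs (3–6 vertices) for the three-way
solver agreement; the full 100-combination, `1e4`-trajectory simulation
protocol; 20-replicate campaigns for the convergence fraction; 6
replicates per RSC value for the sweep. The fraction-based claims are
robust at these replicate counts, every random quantity is seeded, and
generation caps replace wall-clock limits, so all numbers in the tests
are exactly reproducible.
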