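# Closed-form expressions for the small chain and ladder models, used as
# oracles for the numeric pipeline.  All forms were re-derived from
# first-step analysis and limiting (x = 0 / x -> infinity) chain steady
# states under the stated symmetry assumptions, and are cross-checked
# against the numeric grid pipeline and the symbolic recurrence in the
# test-suite.  Dimensionless groups: alpha = l23 / l12, beta = r / l12.

#' Activation time of the two-state chain
#'
#' Mean first-passage time from the inactive state of the telegraph model
#' `C2` to the production event: `(l12 + l21 + r) / (r * l12)`. Tends to
#' `1 / l12` as `r` grows, which is the basis of decoupling by rate scale
#' separation in the two-state model.
#'
#' @param l12,l21 Activation and deactivation rates (> 0).
#' @param r Production rate (> 0).
#' @return Mean first-passage time (time units).
#' @export
c2_mfpt <- function(l12, l21, r) {
  stopifnot(l12 > 0, l21 > 0, r > 0)
  (l12 + l21 + r) / (r * l12)
}

#' Dynamic ranges of the two-rung ladder under single-edge activation
#'
#' Closed forms for the normalised dynamic ranges of the steady-state level
#' and the activation time in `D2` when the ligand activates by regulating
#' exactly one bound-chain transition: the forward edge `B1 -> B2`
#' (`gamma > 1`) or the backward edge `B2 -> B1` (`gamma < 1`). In the
#' backward case the activation-time range vanishes as `r` grows while the
#' steady-state range is independent of `r` - the two-rung expression of
#' decoupling by rate scale separation.
#'
#' @param case `"forward"` or `"backward"`.
#' @param gamma Regulatory factor of the regulated edge (activator
#'   constraint enforced: `> 1` forward, `< 1` backward).
#' @param l12,l21 Unbound-chain rates.
#' @param r Production rate.
#' @return Named vector `c(delta_ss, delta_mfpt)`.
#' @export
d2_dynamic_ranges <- function(case = c("forward", "backward"), gamma,
                              l12, l21, r) {
  case <- match.arg(case)
  stopifnot(l12 > 0, l21 > 0, r > 0, gamma > 0)
  L <- l12 / l21
  if (case == "forward") {
    if (gamma <= 1) stop("forward activation requires gamma > 1")
    dss <- (gamma - 1) / (gamma * L + gamma + 1 + 1 / L)
    dm <- (gamma - 1) / gamma * (l21 + r) / (l12 + l21 + r)
  } else {
    if (gamma >= 1) stop("backward activation requires gamma < 1")
    dss <- (1 - gamma) / (L + gamma + 1 + gamma / L)
    dm <- (1 - gamma) * l21 / (l12 + l21 + r)
  }
  c(delta_ss = dss, delta_mfpt = dm)
}

#' Dynamic ranges of the three-rung ladder, one regulated transition
#'
#' Closed forms for `D3` with symmetric unbound rates (`l12 = l21`,
#' `l23 = l32`) and a single regulated bound-chain transition promoting
#' readout production. Cases: `"1.I"` regulates `B1 -> B2` (`gamma > 1`),
#' `"1.II"` regulates `B2 -> B1` (`gamma < 1`), `"1.III"` regulates
#' `B2 -> B3` (`gamma > 1`), `"1.IV"` regulates `B3 -> B2` (`gamma < 1`).
#' Expressed in the dimensionless groups `alpha = l23 / l12` and
#' `beta = r / l12`; for all cases except 1.I the activation-time range
#' vanishes as `alpha, beta >> 1` (rate scale separation), while the
#' steady-state range depends only on `gamma`.
#'
#' @param case One of `"1.I"`, `"1.II"`, `"1.III"`, `"1.IV"`.
#' @param gamma Regulatory factor (activator side enforced per case).
#' @param alpha,beta Dimensionless rate ratios (> 0).
#' @return Named vector `c(delta_ss, delta_mfpt)`.
#' @export
d3_single_case_ranges <- function(case = c("1.I", "1.II", "1.III", "1.IV"),
                                  gamma, alpha, beta) {
  case <- match.arg(case)
  stopifnot(alpha > 0, beta > 0, gamma > 0)
  D <- alpha * beta + 3 * alpha + 2 * beta
  switch(case,
    "1.I" = {
      if (gamma <= 1) stop("case 1.I requires gamma > 1")
      c(delta_ss = (gamma - 1) / (3 * (2 * gamma + 1)),
        delta_mfpt = (gamma - 1) / gamma * (alpha + beta + alpha * beta) / D)
    },
    "1.II" = {
      if (gamma >= 1) stop("case 1.II requires gamma < 1")
      c(delta_ss = (1 - gamma) / (3 * (gamma + 2)),
        delta_mfpt = (1 - gamma) * (alpha + beta) / D)
    },
    "1.III" = {
      if (gamma <= 1) stop("case 1.III requires gamma > 1")
      c(delta_ss = 2 * (gamma - 1) / (3 * (gamma + 2)),
        delta_mfpt = (gamma - 1) / gamma * 2 * (alpha + beta) / D)
    },
    "1.IV" = {
      if (gamma >= 1) stop("case 1.IV requires gamma < 1")
      c(delta_ss = 2 * (1 - gamma) / (3 * (2 * gamma + 1)),
        delta_mfpt = (1 - gamma) * 2 * alpha / D)
    })
}

#' Dynamic ranges of the three-rung ladder, two regulated transitions
#'
#' Closed forms for the four coherent two-edge activation regimes of `D3`
#' under the same symmetry assumptions as [d3_single_case_ranges()].
#' Cases and their regulated pairs: `"2.I"` `(gamma12 > 1, gamma23 > 1)`,
#' `"2.II"` `(gamma12 > 1, gamma32 < 1)`, `"2.III"`
#' `(gamma21 < 1, gamma23 > 1)`, `"2.IV"` `(gamma21 < 1, gamma32 < 1)`.
#' Setting the second factor to 1 reduces each form to the corresponding
#' single-edge case.
#'
#' @param case One of `"2.I"`, `"2.II"`, `"2.III"`, `"2.IV"`.
#' @param gamma1,gamma2 The two regulatory factors, in the order the case
#'   lists them (e.g. for 2.III: `gamma1 = gamma21`, `gamma2 = gamma23`).
#' @param alpha,beta Dimensionless rate ratios.
#' @return Named vector `c(delta_ss, delta_mfpt)`.
#' @export
d3_double_case_ranges <- function(case = c("2.I", "2.II", "2.III", "2.IV"),
                                  gamma1, gamma2, alpha, beta) {
  case <- match.arg(case)
  stopifnot(alpha > 0, beta > 0, gamma1 > 0, gamma2 > 0)
  D <- alpha * beta + 3 * alpha + 2 * beta
  a <- alpha; b <- beta
  switch(case,
    "2.I" = {
      g12 <- gamma1; g23 <- gamma2
      if (g12 < 1 || g23 < 1 || (g12 == 1 && g23 == 1))
        stop("case 2.I requires gamma12 >= 1 and gamma23 >= 1 (activation)")
      c(delta_ss = (2 * g12 * g23 - g12 - 1) / (3 * (g12 * g23 + g12 + 1)),
        delta_mfpt = (a * b * g23 * (g12 - 1) +
                        (a + b) * (2 * g12 * g23 - g12 - 1)) /
                     (g12 * g23 * D))
    },
    "2.II" = {
      g12 <- gamma1; g32 <- gamma2
      if (g12 < 1 || g32 > 1) stop("case 2.II requires gamma12 >= 1, gamma32 <= 1")
      c(delta_ss = (2 * g12 - g12 * g32 - g32) / (3 * (g12 * g32 + g12 + g32)),
        delta_mfpt = ((a * b + b) * (g12 - 1) + a * (2 * g12 - g12 * g32 - g32)) /
                     (g12 * D))
    },
    "2.III" = {
      g21 <- gamma1; g23 <- gamma2
      if (g21 > 1 || g23 < 1) stop("case 2.III requires gamma21 <= 1, gamma23 >= 1")
      c(delta_ss = (2 * g23 - g21 - 1) / (3 * (g21 + g23 + 1)),
        delta_mfpt = (a + b) * (2 * g23 - g21 - 1) / (g23 * D))
    },
    "2.IV" = {
      g21 <- gamma1; g32 <- gamma2
      if (g21 > 1 || g32 > 1) stop("case 2.IV requires gamma21 <= 1, gamma32 <= 1")
      c(delta_ss = (2 - g21 * g32 - g32) / (3 * (g21 * g32 + g32 + 1)),
        delta_mfpt = (b * (1 - g21) + a * (2 - g21 * g32 - g32)) / D)
    })
}

#' Zero-ligand activation time of the symmetric three-rung ladder
#'
#' At `x = 0` only the unbound chain is accessible, and for symmetric rates
#' the activation time from `U1` is
#' `(1 / l12) * (1 + (3 alpha + 2 beta) / (alpha beta))`. When both
#' `alpha` and `beta` are large this reduces to `1 / l12`: the slow,
#' unregulated first forward transition alone sets the activation time.
#'
#' @param l12 First forward rate.
#' @param alpha,beta Dimensionless rate ratios.
#' @return Mean first-passage time at zero ligand.
#' @export
d3_mfpt_at_zero <- function(l12, alpha, beta) {
  stopifnot(l12 > 0, alpha > 0, beta > 0)
  (1 / l12) * (1 + (3 * alpha + 2 * beta) / (alpha * beta))
}

#' Incoherent regulatory factor balancing the activation-time endpoints
#'
#' Under equal rates (`l12 = l21 = l23 = l32 = r`) and forward-edge
#' regulation only, the activation time has equal values at zero and
#' saturating ligand exactly when
#' `gamma12 = (gamma23 + 2) / (5 gamma23 - 2)`. The returned factor
#' exceeds 1 precisely when `gamma23 < 1`: balancing requires incoherent
#' regulation (one promoted and one hindered forward transition).
#'
#' @param gamma23 Regulatory factor of `B2 -> B3` (> 2/5, away from the
#'   pole).
#' @return The balancing `gamma12`.
#' @export
incoherent_balance_gamma <- function(gamma23) {
  stopifnot(gamma23 > 0)
  if (abs(5 * gamma23 - 2) < 1e-12)
    stop("gamma23 = 2/5 is a pole of the balance relation")
  if (gamma23 < 2 / 5)
    stop("the balance relation requires gamma23 > 2/5")
  (gamma23 + 2) / (5 * gamma23 - 2)
}
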