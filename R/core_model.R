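#' Gating equilibrium constant from open probability
#'
#' A two-state equilibrium with open probability `po` has equilibrium
#' constant `L = po / (1 - po)`; at a CRC asymptote this is the fully
#' liganded gating constant (`POmax` gives `L2`, `POmin` gives `L0`).
#'
#' @param po open probability, strictly inside (0, 1).
#' @return gating equilibrium constant (dimensionless).
#' @seealso [po_from_gating_constant()] for the inverse.
#' @examples
#' gating_constant_from_po(0.96)  # 24
#' @export
gating_constant_from_po <- function(po) {
  check_probability(po, "po")
  po / (1 - po)
}

#' @rdname gating_constant_from_po
#' @param L gating equilibrium constant, strictly positive.
#' @export
po_from_gating_constant <- function(L) {
  check_positive(L, "L")
  L / (1 + L)
}

#' Resting-state dissociation constant from the CRC midpoint
#'
#' For the two-equivalent-site activation pathway
#' A+C = AC = A2C = A2O the open probability is
#' \deqn{P_O(x) = x^2 L_2 / (1 + 2x + x^2 + x^2 L_2), \quad x = A/K_{dC},}
#' and solving \eqn{P_O(EC_{50}) = P_O^{max}/2} gives the closed form
#' \deqn{K_{dC} = EC_{50}\,(L_2 + 1) / (1 + \sqrt{L_2 + 2}).}
#'
#' @param ec50 CRC midpoint concentration (molar).
#' @param L2 di-liganded gating equilibrium constant.
#' @return `KdC` in molar.
#' @seealso [ec50_from_constants()] for the inverse, [po_curve()].
#' @examples
#' kdc_from_ec50(1070e-6, 1.5) * 1e6  # ~930 uM
#' @export
kdc_from_ec50 <- function(ec50, L2) {
  check_positive(ec50, "ec50")
  check_positive(L2, "L2")
  ec50 * (L2 + 1) / (1 + sqrt(L2 + 2))
}

#' @rdname kdc_from_ec50
#' @param KdC resting-state equilibrium dissociation constant (molar).
#' @export
ec50_from_constants <- function(KdC, L2) {
  check_positive(KdC, "KdC")
  check_positive(L2, "L2")
  KdC * (1 + sqrt(L2 + 2)) / (L2 + 1)
}

#' Open-state dissociation constant from thermodynamic cycle closure
#'
#' Two equivalent and independent sites give `L2/L0 = (KdC/KdO)^2`, so the
#' coupling constant is `c = sqrt(L2/L0)` and `KdO = KdC/c`.  `L2 < L0`
#' (inverse agonism, c < 1) is permitted.
#'
#' @inheritParams ec50_from_constants
#' @param L0 unliganded gating equilibrium constant.
#' @return `KdO` in molar.
#' @examples
#' kdo_from_cycle(174e-6, 26.64, 7.4e-7) * 1e9  # ~29 nM
#' @export
kdo_from_cycle <- function(KdC, L2, L0) {
  check_positive(KdC, "KdC")
  check_positive(L2, "L2")
  check_positive(L0, "L0")
  KdC / sqrt(L2 / L0)
}

#' Coupling constant
#'
#' The ratio `c = KdC/KdO`: the fold increase in binding strength gained in
#' the channel-opening isomerization.
#'
#' @inheritParams kdo_from_cycle
#' @param KdO open-state equilibrium dissociation constant (molar).
#' @return dimensionless coupling constant.
#' @export
coupling_constant <- function(KdC, KdO) {
  check_positive(KdC, "KdC")
  check_positive(KdO, "KdO")
  KdC / KdO
}

#' Binding free energy from a dissociation constant
#'
#' `dG = RT * ln(Kd / 1 M)` in kcal/mol; the 1 M standard state makes the
#' result unit-sensitive, so `Kd` must be in molar.
#'
#' @param Kd equilibrium dissociation constant (molar).
#' @param RT thermal energy in kcal/mol (default 0.59, i.e. 23 degrees C).
#' @return free energy in kcal/mol (negative for sub-molar `Kd`).
#' @examples
#' binding_energy(174e-6)  # ~ -5.1 kcal/mol
#' binding_energy(29e-9)   # ~ -10.2 kcal/mol
#' @export
binding_energy <- function(Kd, RT = 0.59) {
  check_positive(Kd, "Kd")
  check_positive(RT, "RT")
  RT * log(Kd)
}

#' @rdname binding_energy
#' @param dG free energy in kcal/mol.
#' @export
kd_from_energy <- function(dG, RT = 0.59) {
  check_positive(RT, "RT")
  exp(dG / RT)
}

#' Agonist efficiency
#'
#' Efficiency is the maximum output/input energy ratio
#' \deqn{\eta = (\Delta G_{HA} - \Delta G_{LA}) / \Delta G_{HA}
#'       = 1 - \Delta G_{LA}/\Delta G_{HA},}
#' the fraction of the agonist's total binding free energy applied to the
#' channel-opening rearrangement.  Because it is a ratio of logarithms it is
#' invariant to RT and to the logarithm base, but not to the concentration
#' unit — use [efficiency_from_kd()] with a declared unit when starting
#' from dissociation constants.
#'
#' @param dG_LA resting (low-affinity) binding free energy (kcal/mol).
#' @param dG_HA open (high-affinity) binding free energy (kcal/mol); must be
#'   nonzero.
#' @return dimensionless efficiency (typically in (0, 1)).
#' @examples
#' efficiency(-5.1, -10.2)  # ~0.5
#' @export
efficiency <- function(dG_LA, dG_HA) {
  if (any(!is.finite(dG_LA)) || any(!is.finite(dG_HA)))
    stop("free energies must be finite")
  if (any(dG_HA == 0))
    stop("'dG_HA' must be nonzero: efficiency is undefined at zero total binding energy")
  1 - dG_LA / dG_HA
}

#' @rdname efficiency
#' @inheritParams coupling_constant
#' @param unit concentration unit of `KdC` and `KdO` (see [to_molar()]);
#'   must be declared, `"M"` meaning the values are already molar.
#' @export
efficiency_from_kd <- function(KdC, KdO, unit = "M") {
  KdC <- to_molar(KdC, unit)
  KdO <- to_molar(KdO, unit)
  check_positive(KdC, "KdC")
  check_positive(KdO, "KdO")
  if (any(KdO == 1))
    stop("'KdO' of exactly 1 M gives zero high-affinity energy; efficiency undefined")
  1 - log(KdC) / log(KdO)
}

#' Agonist efficacy
#'
#' The free energy difference `lambda = dG_HA - dG_LA` (kcal/mol): the
#' maximum energy the agonist can deliver to the gating machinery.
#' Equivalently `lambda = -RT * ln(c)` with `c` the coupling constant.
#'
#' @inheritParams efficiency
#' @return efficacy in kcal/mol (negative when binding is stronger to O).
#' @export
efficacy_lambda <- function(dG_HA, dG_LA) {
  dG_HA - dG_LA
}

#' Efficiency from the slope of an efficiency plot
#'
#' An efficiency plot (log L2 versus log 1/KdC, intercept log L0) has slope
#' `m = 2 * eta / (1 - eta)` for a class of agonists sharing efficiency
#' `eta`, hence `eta = m / (m + 2)`.
#'
#' @param m slope of the efficiency plot; must be positive.
#' @return efficiency.
#' @seealso [fit_efficiency_plot()]
#' @export
eta_from_slope <- function(m) {
  check_positive(m, "m")
  m / (m + 2)
}

#' @rdname eta_from_slope
#' @param eta efficiency in (0, 1).
#' @export
slope_from_eta <- function(eta) {
  check_probability(eta, "eta")
  2 * eta / (1 - eta)
}

#' Equilibrium open probability of the activation scheme
#'
#' For `n_sites = 2` (the default; two equivalent and independent sites)
#' \deqn{P_O([A]) = x^2 L_2 / (1 + 2x + x^2 + x^2 L_2), \quad x = A/K_{dC};}
#' for `n_sites = 1` the gating constant argument is interpreted as
#' \eqn{L_1} and \eqn{P_O = x L_1 / (1 + x + x L_1)}.  The unliganded and
#' open-state-binding terms are negligible on this pathway (`L0` of order
#' 1e-6) and are omitted.
#'
#' @param A agonist concentration (molar, >= 0); vectorized.
#' @inheritParams ec50_from_constants
#' @param L2 gating equilibrium constant at full occupancy (`L1` when
#'   `n_sites = 1`).
#' @param n_sites 1 or 2.
#' @return open probability.
#' @examples
#' po_curve(40e-6, 174e-6, 26.64)  # ~half of POmax 0.964
#' @export
po_curve <- function(A, KdC, L2, n_sites = 2) {
  if (any(!is.finite(A)) || any(A < 0)) stop("'A' must be nonnegative")
  check_positive(KdC, "KdC")
  check_positive(L2, "L2")
  x <- A / KdC
  if (identical(as.integer(n_sites), 2L)) {
    x^2 * L2 / (1 + 2 * x + x^2 + x^2 * L2)
  } else if (identical(as.integer(n_sites), 1L)) {
    x * L2 / (1 + x + x * L2)
  } else {
    stop("'n_sites' must be 1 or 2")
  }
}

#' Predict CRC descriptors from equilibrium constants
#'
#' The inverse of the CRC analysis: given `KdC`, `KdO` and `L0`, cycle
#' closure gives `L2 = L0 * (KdC/KdO)^2`, and the two-site curve gives
#' `POmax = L2/(1+L2)`, `POmin = L0/(1+L0)` and
#' `EC50 = KdC * (1 + sqrt(L2+2)) / (L2+1)`.
#'
#' @inheritParams coupling_constant
#' @inheritParams kdo_from_cycle
#' @return a list with `EC50` (molar), `POmax`, `POmin` and `L2`.
#' @examples
#' predict_crc(174e-6, 29e-9, 7.4e-7)  # ACh: POmax ~0.96, EC50 ~40 uM
#' @export
predict_crc <- function(KdC, KdO, L0) {
  check_positive(KdC, "KdC")
  check_positive(KdO, "KdO")
  check_positive(L0, "L0")
  L2 <- L0 * (KdC / KdO)^2
  list(EC50 = ec50_from_constants(KdC, L2),
       POmax = po_from_gating_constant(L2),
       POmin = po_from_gating_constant(L0),
       L2 = L2)
}

# ---- first-order (delta-method) error propagation ------------------------

# expression templates for each derived quantity, by input mode; analytic
# partial derivatives are produced by stats::deriv()
.prop_expressions <- local({
  L2 <- "((POmax/(1 - POmax))/fold)"
  KdC <- paste0("(EC50*(", L2, " + 1)/(1 + sqrt(", L2, " + 2)))")
  cc <- paste0("(sqrt(", L2, "/L0))")
  KdO <- paste0("(", KdC, "/", cc, ")")
  list(
    crc = list(
      L2 = L2, KdC = KdC, c = cc, KdO = KdO,
      dG_LA = paste0("(RT*log(", KdC, "))"),
      dG_HA = paste0("(RT*log(", KdO, "))"),
      lambda = paste0("(RT*log(", KdO, ") - RT*log(", KdC, "))"),
      eta = paste0("(1 - log(", KdC, ")/log(", KdO, "))")
    ),
    kd = list(
      c = "(KdC/KdO)",
      dG_LA = "(RT*log(KdC))",
      dG_HA = "(RT*log(KdO))",
      lambda = "(RT*log(KdO) - RT*log(KdC))",
      eta = "(1 - log(KdC)/log(KdO))"
    )
  )
})

#' First-order standard error of a derived activation quantity
#'
#' Propagates measurement standard errors through the closed-form CRC
#' inversion by the delta method, using analytic partial derivatives.  Two
#' input modes are supported: CRC descriptors (`EC50`, `POmax`; `L0` and
#' the background `fold` treated as exact) or dissociation constants
#' (`KdC`, `KdO`).  Errors in the two inputs are taken as independent.
#'
#' @param estimates named list of point estimates: either
#'   `list(EC50 =, POmax =)` (molar, probability) or
#'   `list(KdC =, KdO =)` (molar).
#' @param sems named list of standard errors matching `estimates`.
#' @param target one of `"L2"`, `"KdC"`, `"KdO"`, `"c"`, `"dG_LA"`,
#'   `"dG_HA"`, `"lambda"`, `"eta"` (first four only in CRC mode).
#' @param L0 unliganded gating constant (CRC mode).
#' @param fold background fold correction of L0 (CRC mode, default 1).
#' @param RT thermal energy, kcal/mol.
#' @param covariance covariance between the two input estimates (0 when
#'   they were measured independently; pass the off-diagonal of the fit
#'   covariance when both come from the same curve fit).
#' @return a list with `value` (the derived point estimate) and `sem`.
#' @examples
#' # efficiency of decamethonium from its dissociation constants
#' propagate_sem(list(KdC = 90e-6, KdO = 140e-9),
#'               list(KdC = 7e-6, KdO = 10e-9), "eta")
#' @export
propagate_sem <- function(estimates, sems, target,
                          L0 = NULL, fold = 1, RT = 0.59, covariance = 0) {
  nm <- sort(names(estimates))
  mode <- if (identical(nm, c("EC50", "POmax"))) "crc"
          else if (identical(nm, c("KdC", "KdO"))) "kd"
          else stop("estimates must be named EC50/POmax or KdC/KdO")
  if (!identical(sort(names(sems)), nm))
    stop("'sems' must carry the same names as 'estimates'")
  if (any(unlist(sems) < 0)) stop("standard errors must be nonnegative")
  exprs <- .prop_expressions[[mode]]
  if (!target %in% names(exprs))
    stop("target '", target, "' not available in ", mode, " input mode")
  if (mode == "crc") {
    if (is.null(L0)) stop("'L0' is required in CRC input mode")
    check_positive(L0, "L0")
    check_positive(fold, "fold")
    check_positive(estimates$EC50, "EC50")
    check_probability(estimates$POmax, "POmax")
    vars <- c("EC50", "POmax")
    env <- list2env(list(EC50 = estimates$EC50, POmax = estimates$POmax,
                         fold = fold, L0 = L0, RT = RT))
  } else {
    check_positive(estimates$KdC, "KdC")
    check_positive(estimates$KdO, "KdO")
    if (target %in% c("eta") && abs(log(estimates$KdO)) < 1e-12)
      stop("KdO of 1 M gives zero denominator in efficiency")
    vars <- c("KdC", "KdO")
    env <- list2env(list(KdC = estimates$KdC, KdO = estimates$KdO, RT = RT))
  }
  d <- stats::deriv(parse(text = exprs[[target]])[[1]], vars)
  ev <- eval(d, envir = env)
  grad <- attr(ev, "gradient")[1, vars]
  if (any(!is.finite(grad)))
    stop("degenerate inputs: derivative of '", target, "' is not finite")
  s <- unlist(sems[vars])
  Sigma <- matrix(c(s[1]^2, covariance, covariance, s[2]^2), 2, 2)
  v <- drop(grad %*% Sigma %*% grad)
  if (v < 0) stop("covariance matrix is not positive semidefinite")
  list(value = as.numeric(ev), sem = sqrt(v))
}
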