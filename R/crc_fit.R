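#' Construct a concentration-response dataset
#'
#' Bundles per-concentration cluster open probabilities for one
#' agonist/construct.  Concentrations are converted to molar on ingest
#' (the unit must be declared) and sorted ascending.
#'
#' @param A agonist concentrations (in `unit`).
#' @param po cluster open probabilities in `[0, 1]` (absolute, not
#'   normalized).
#' @param unit concentration unit (see [to_molar()]).
#' @param label agonist / construct identifier.
#' @param sem optional standard errors of `po`.
#' @param n optional replicate counts.
#' @param background background-mutation string (e.g. `"eS450W+eL269F"`).
#' @param voltage_mV membrane potential.
#' @return a `crc_dataset`: a data.frame with columns `A` (molar) and `po`
#'   (plus `sem`, `n` when given) and attributes `label`, `background`,
#'   `voltage_mV`.
#' @export
crc_dataset <- function(A, po, unit = "M", label = "", sem = NULL, n = NULL,
                        background = "", voltage_mV = NA_real_) {
  A <- to_molar(A, unit)
  if (any(!is.finite(A)) || any(A < 0)) stop("concentrations must be >= 0")
  check_probability(po, "po", open = FALSE)
  if (length(A) != length(po)) stop("'A' and 'po' lengths differ")
  if (length(unique(A)) < 3)
    stop("a CRC dataset needs at least 3 distinct concentrations")
  d <- data.frame(A = A, po = po)
  if (!is.null(sem)) d$sem <- sem
  if (!is.null(n)) d$n <- n
  d <- d[order(d$A), , drop = FALSE]
  rownames(d) <- NULL
  structure(d, class = c("crc_dataset", "data.frame"),
            label = label, background = background, voltage_mV = voltage_mV)
}

#' Read concentration-response data from CSV
#'
#' Expected columns: `label`, `concentration`, `concentration_unit`, `po`
#' and optionally `sem`, `n`, `background`, `voltage_mV`.  Rows are split
#' by `label` into one [crc_dataset()] each.
#'
#' @param path CSV file path.
#' @return named list of `crc_dataset` objects.
#' @export
read_crc_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "concentration", "concentration_unit", "po")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0)
    stop("CRC csv lacks column(s): ", paste(missing_cols, collapse = ", "))
  out <- lapply(split(d, d$label), function(g) {
    crc_dataset(A = g$concentration, po = g$po,
                unit = g$concentration_unit,
                label = g$label[1],
                sem = if ("sem" %in% names(g)) g$sem else NULL,
                n = if ("n" %in% names(g)) g$n else NULL,
                background = if ("background" %in% names(g)) g$background[1] else "",
                voltage_mV = if ("voltage_mV" %in% names(g)) g$voltage_mV[1] else NA_real_)
  })
  out
}

#' Fit the monophasic Hill equation to a CRC
#'
#' Least-squares fit of `po = POmax / (1 + (EC50/A)^nH)` (zero baseline for
#' liganded activation; the unliganded open probability is of order 1e-6).
#' The Hill coefficient is either free within `[0.5, 3]` (default) or held
#' fixed; starting values are `POmax = max(po)`, `EC50` at the
#' log-interpolated half-maximal concentration and `nH = 1.5`.
#' Optionally weights points by inverse variance when sems are present.
#'
#' @param data a [crc_dataset()], or any data.frame with molar `A` and `po`.
#' @param nH_mode `"free"` or `"fixed"`.
#' @param nH Hill coefficient used when `nH_mode = "fixed"` (and as the
#'   starting value when free).
#' @param weighting `"none"` or `"inverse-variance"` (requires a `sem`
#'   column with positive entries).
#' @return an object of class `hill_fit`: a list with `params`
#'   (`EC50`, `POmax`, `nH`, `POmin = 0`), `sems`, `vcov`, `rss`,
#'   `converged`, `flagged` (TRUE when the fitted EC50 falls outside the
#'   sampled range extended 10-fold either side), `message` and `data`.
#' @examples
#' d <- crc_dataset(A = c(10, 30, 100, 300, 1000, 3000), unit = "uM",
#'                  po = po_curve(c(10, 30, 100, 300, 1000, 3000) * 1e-6,
#'                                KdC = 200e-6, L2 = 4))
#' fit_hill(d)$params
#' @export
fit_hill <- function(data, nH_mode = c("free", "fixed"), nH = 1.5,
                     weighting = c("none", "inverse-variance")) {
  nH_mode <- match.arg(nH_mode)
  weighting <- match.arg(weighting)
  A <- data$A
  po <- data$po
  if (length(unique(A)) < 3)
    stop("at least 3 distinct concentrations are required")
  if (length(unique(po)) == 1L)
    stop("degenerate data: all po values are identical")
  if (any(A <= 0)) {
    # zero-concentration points carry no information for a zero-baseline fit
    keep <- A > 0
    A <- A[keep]; po <- po[keep]
  }

  pomax0 <- max(po)
  half <- pomax0 / 2
  ec50_0 <- exp(stats::approx(po, log(A), xout = half, ties = "ordered",
                              rule = 2)$y)
  if (!is.finite(ec50_0)) ec50_0 <- exp(mean(log(A)))

  w <- NULL
  if (weighting == "inverse-variance") {
    if (is.null(data$sem) || any(!is.finite(data$sem)) || any(data$sem <= 0))
      stop("inverse-variance weighting requires positive 'sem' values")
    w <- 1 / data$sem[data$A > 0]^2
  }

  df <- data.frame(A = A, po = po)
  lowerb <- c(POmax = 1e-6, EC50 = min(A) / 1e4)
  upperb <- c(POmax = 1, EC50 = max(A) * 1e4)
  if (nH_mode == "free") {
    form <- po ~ POmax / (1 + (EC50 / A)^nH)
    start <- list(POmax = pomax0, EC50 = ec50_0, nH = nH)
    lowerb <- c(lowerb, nH = 0.5); upperb <- c(upperb, nH = 3)
  } else {
    form <- po ~ POmax / (1 + (EC50 / A)^nH_fix)
    df$nH_fix <- nH
    start <- list(POmax = pomax0, EC50 = ec50_0)
  }

  args <- list(form, data = df, start = start, lower = lowerb,
               upper = upperb,
               control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!is.null(w)) args$weights <- w
  fit <- tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) e)

  if (inherits(fit, "error")) {
    return(structure(list(
      params = c(EC50 = NA_real_, POmax = NA_real_, nH = NA_real_, POmin = 0),
      sems = c(EC50 = NA_real_, POmax = NA_real_, nH = NA_real_),
      vcov = NULL, rss = NA_real_, converged = FALSE, flagged = TRUE,
      message = conditionMessage(fit), data = data),
      class = "hill_fit"))
  }

  cf <- coef(fit)
  est <- c(EC50 = unname(cf[["EC50"]]), POmax = unname(cf[["POmax"]]),
           nH = if (nH_mode == "free") unname(cf[["nH"]]) else nH,
           POmin = 0)
  vc <- tryCatch(vcov(fit), error = function(e) NULL)
  sems <- c(EC50 = NA_real_, POmax = NA_real_, nH = NA_real_)
  if (!is.null(vc)) {
    dg <- sqrt(pmax(diag(vc), 0))
    sems[names(dg)] <- dg
  }
  flagged <- est[["EC50"]] < min(A) / 10 || est[["EC50"]] > max(A) * 10
  structure(list(params = est, sems = sems[c("EC50", "POmax", "nH")],
                 vcov = vc, rss = sum(resid(fit)^2), converged = TRUE,
                 flagged = flagged, message = "ok", data = data),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Hill fit: NOT converged (", x$message, ")\n", sep = "")
    return(invisible(x))
  }
  p <- x$params
  cat(sprintf("Hill fit: EC50 = %.4g M, POmax = %.4g, nH = %.3g (rss %.3g)%s\n",
              p[["EC50"]], p[["POmax"]], p[["nH"]], x$rss,
              if (x$flagged) "  [flagged: EC50 outside sampled range]" else ""))
  invisible(x)
}

#' Activation constants and energy profile from CRC descriptors
#'
#' The core inversion: the apparent `L2` is `POmax/(1 - POmax)`, divided by
#' the background `fold` to give the corrected `L2`; `KdC` follows from
#' `EC50` and the corrected `L2` ([kdc_from_ec50()]); cycle closure gives
#' `c` and `KdO` ([kdo_from_cycle()]); energies, efficacy and efficiency
#' follow ([binding_energy()], [efficacy_lambda()], [efficiency()]).
#' Standard errors, when supplied, are propagated by the delta method.
#'
#' @param EC50 CRC midpoint (molar).
#' @param POmax high-concentration asymptote (strictly below 1).
#' @param L0 unliganded gating constant on the wild-type scale.
#' @param fold combined background L0 fold (default 1).
#' @param RT thermal energy, kcal/mol.
#' @param sem_EC50,sem_POmax optional standard errors.
#' @param sem_cov covariance between the EC50 and POmax estimates
#'   (nonzero when both come from one curve fit).
#' @param label identifier carried into the output row.
#' @return one-row data.frame with columns `label`, `EC50`, `POmax`,
#'   `L2_apparent`, `L2`, `KdC`, `KdO`, `c`, `dG_LA`, `dG_HA`, `lambda`,
#'   `eta` and (when sems are given) `KdC_sem`, `KdO_sem`, `c_sem`,
#'   `eta_sem`.
#' @examples
#' activation_profile(EC50 = 1070e-6, POmax = 0.60, L0 = 5.2e-7)
#' @export
activation_profile <- function(EC50, POmax, L0, fold = 1, RT = 0.59,
                               sem_EC50 = NA_real_, sem_POmax = NA_real_,
                               sem_cov = 0, label = "") {
  check_positive(EC50, "EC50")
  check_probability(POmax, "POmax")
  L2_app <- gating_constant_from_po(POmax)
  L2 <- correct_l2(L2_app, fold)
  KdC <- kdc_from_ec50(EC50, L2)
  KdO <- kdo_from_cycle(KdC, L2, L0)
  cc <- coupling_constant(KdC, KdO)
  dG_LA <- binding_energy(KdC, RT)
  dG_HA <- binding_energy(KdO, RT)
  out <- data.frame(label = label, EC50 = EC50, POmax = POmax,
                    L2_apparent = L2_app, L2 = L2, KdC = KdC, KdO = KdO,
                    c = cc, dG_LA = dG_LA, dG_HA = dG_HA,
                    lambda = efficacy_lambda(dG_HA, dG_LA),
                    eta = efficiency(dG_LA, dG_HA),
                    stringsAsFactors = FALSE)
  if (is.finite(sem_EC50) && is.finite(sem_POmax)) {
    est <- list(EC50 = EC50, POmax = POmax)
    se <- list(EC50 = sem_EC50, POmax = sem_POmax)
    for (tg in c("KdC", "KdO", "c", "eta")) {
      out[[paste0(tg, "_sem")]] <-
        propagate_sem(est, se, tg, L0 = L0, fold = fold, RT = RT,
                      covariance = sem_cov)$sem
    }
  }
  out
}

#' Convert a Hill fit into activation constants and an energy profile
#'
#' @param fit a converged [fit_hill()] result.
#' @inheritParams activation_profile
#' @return see [activation_profile()].
#' @export
crc_to_profile <- function(fit, L0, fold = 1, RT = 0.59) {
  if (!inherits(fit, "hill_fit")) stop("'fit' must be a hill_fit")
  if (!fit$converged) stop("cannot profile a non-converged Hill fit")
  p <- fit$params
  if (p[["POmax"]] >= 1)
    stop("POmax >= 1: apparent L2 undefined")
  cov_ep <- 0
  if (!is.null(fit$vcov) &&
      all(c("EC50", "POmax") %in% rownames(fit$vcov)))
    cov_ep <- fit$vcov["EC50", "POmax"]
  activation_profile(EC50 = p[["EC50"]], POmax = p[["POmax"]], L0 = L0,
                     fold = fold, RT = RT,
                     sem_EC50 = fit$sems[["EC50"]],
                     sem_POmax = fit$sems[["POmax"]],
                     sem_cov = cov_ep,
                     label = attr(fit$data, "label") %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Average replicate activation profiles
#'
#' Supports the per-curve analysis mode: each replicate CRC is inverted to
#' its own profile and the profiles are then averaged (mean and standard
#' error of the mean per quantity).  On noiseless data this coincides with
#' profiling the averaged descriptors.
#'
#' @param profiles list of one-row data.frames from [activation_profile()].
#' @return one-row data.frame of means with `_sem` columns.
#' @export
average_profiles <- function(profiles) {
  if (length(profiles) < 1) stop("no profiles to average")
  d <- do.call(rbind, profiles)
  num <- names(d)[vapply(d, is.numeric, logical(1))]
  num <- setdiff(num, grep("_sem$", num, value = TRUE))
  out <- as.data.frame(as.list(colMeans(d[num])))
  for (v in num)
    out[[paste0(v, "_sem")]] <- stats::sd(d[[v]]) / sqrt(nrow(d))
  out$label <- d$label[1]
  out$n <- nrow(d)
  out
}
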