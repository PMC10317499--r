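#' Build a kinetic activation scheme from equilibrium constants
#'
#' Constructs rate constants for the five-state aggregated scheme
#' C = AC = A2C = A2O (= A2D) used by the stochastic simulator.  The
#' liganded opening pathway carries the concentration dependence through
#' the binding steps (`kon_C` per site; `koff_C = kon_C * KdC`); gating is
#' `f2` forward and `b2 = f2 / L2` backward with
#' `L2 = L0 * (KdC/KdO)^2` fixed by thermodynamic cycle closure; a
#' desensitized state is entered from A2O at `kdes` and left at `kres`.
#' Unliganded and mono-liganded open states are not represented: their
#' occupancies are of order `L0 ~ 1e-6` and the analytic curve this
#' simulator is validated against omits them for the same reason.
#' Open-state binding rates (`kon_O`, `koff_O = kon_O * KdO`) are recorded
#' for the thermodynamic-cycle audit, which is asserted at construction:
#' `L2/L0` must equal `((koff_C/kon_C)/(koff_O/kon_O))^2` to 1e-9
#' relative.
#'
#' The default scales are chosen so that simulated records satisfy the
#' working assumptions of the dwell-time analysis: sojourns long relative
#' to the 25 us dead time, intra-cluster shut gaps well below the 20 ms
#' critical time at the simulated concentrations, and desensitized gaps
#' (~0.5 s) well above it (see the methods vignette for the design
#' analysis).
#'
#' @inheritParams predict_crc
#' @param scales named list overriding any of `kon_C` (1e8 M^-1 s^-1 per
#'   site), `f2` (1.6e4 s^-1), `b0` (5000 s^-1, unliganded closing rate,
#'   used by the two-state unliganded simulator), `kon_O` (1e9 M^-1
#'   s^-1), `kdes` (20 s^-1), `kres` (2 s^-1).
#' @return object of class `rate_scheme`.
#' @export
scheme_from_constants <- function(KdC, KdO, L0, scales = list()) {
  check_positive(KdC, "KdC")
  check_positive(KdO, "KdO")
  check_positive(L0, "L0")
  sc <- modifyList(list(kon_C = 1e8, f2 = 1.6e4, b0 = 5000,
                        kon_O = 1e9, kdes = 20, kres = 2), scales)
  for (nm in names(sc)) check_positive(sc[[nm]], nm)
  L2 <- L0 * (KdC / KdO)^2
  koff_C <- sc$kon_C * KdC
  koff_O <- sc$kon_O * KdO
  b2 <- sc$f2 / L2
  f0 <- sc$b0 * L0
  # thermodynamic cycle audit (hard assertion)
  lhs <- L2 / L0
  rhs <- ((koff_C / sc$kon_C) / (koff_O / sc$kon_O))^2
  if (abs(lhs - rhs) > 1e-9 * rhs)
    stop("detailed-balance violation in constructed scheme")
  structure(list(KdC = KdC, KdO = KdO, L0 = L0, L1 = L0 * (KdC / KdO),
                 L2 = L2, kon_C = sc$kon_C, koff_C = koff_C,
                 kon_O = sc$kon_O, koff_O = koff_O,
                 f2 = sc$f2, b2 = b2, f0 = f0, b0 = sc$b0,
                 kdes = sc$kdes, kres = sc$kres,
                 states = c("C", "AC", "A2C", "A2O", "A2D"),
                 open_states = 4L),
            class = "rate_scheme")
}

#' Rate matrix of a scheme at a given agonist concentration
#'
#' @param scheme a [scheme_from_constants()] result.
#' @param A agonist concentration (molar).
#' @return 5x5 generator matrix Q (s^-1), states C, AC, A2C, A2O, A2D.
#' @export
scheme_rate_matrix <- function(scheme, A) {
  if (!inherits(scheme, "rate_scheme")) stop("'scheme' must be a rate_scheme")
  if (!is.finite(A) || A < 0) stop("'A' must be nonnegative")
  s <- scheme
  Q <- matrix(0, 5, 5, dimnames = list(s$states, s$states))
  Q["C", "AC"] <- 2 * s$kon_C * A;  Q["AC", "C"] <- s$koff_C
  Q["AC", "A2C"] <- s$kon_C * A;    Q["A2C", "AC"] <- 2 * s$koff_C
  Q["A2C", "A2O"] <- s$f2;          Q["A2O", "A2C"] <- s$b2
  Q["A2O", "A2D"] <- s$kdes;        Q["A2D", "A2O"] <- s$kres
  diag(Q) <- -rowSums(Q)
  Q
}

#' Stationary state occupancies of a scheme
#'
#' Solves pi Q = 0 by linear algebra.  With
#' `include_desensitized = FALSE` (default) returns occupancies
#' conditioned on the non-desensitized states — for this reversible chain
#' identical to the stationary distribution of the censored submodel —
#' whose A2O entry equals [po_curve()] exactly.
#'
#' @inheritParams scheme_rate_matrix
#' @param include_desensitized keep A2D in the normalization?
#' @return named occupancy vector.
#' @export
scheme_stationary <- function(scheme, A, include_desensitized = FALSE) {
  Q <- scheme_rate_matrix(scheme, A)
  n <- nrow(Q)
  M <- rbind(t(Q), rep(1, n))
  pi_ <- qr.solve(M, c(rep(0, n), 1))
  names(pi_) <- rownames(Q)
  if (!include_desensitized) {
    pi_ <- pi_[scheme$states != "A2D"]
    pi_ <- pi_ / sum(pi_)
  }
  pi_
}

#' Simulate an idealized dwell sequence from a scheme
#'
#' Exact stochastic simulation (exponential holding times, categorical
#' jumps) of the scheme at concentration `A`, aggregated into alternating
#' open/shut sojourns.  The initial state is drawn from the
#' non-desensitized conditional stationary distribution.  Reproducible
#' given `seed`.
#'
#' @inheritParams scheme_rate_matrix
#' @param n_events number of aggregated open/shut sojourns to generate.
#' @param seed RNG seed.
#' @return a [dwell_sequence()] with `origin = "simulated"`.
#' @export
simulate_intervals <- function(scheme, A, n_events, seed = 1) {
  if (n_events < 1) stop("'n_events' must be >= 1")
  Q <- scheme_rate_matrix(scheme, A)
  pi_nd <- scheme_stationary(scheme, A, include_desensitized = FALSE)
  with_seed(seed, {
    start <- sample.int(length(pi_nd), 1L, prob = pi_nd)
    r <- sim_ctmc_intervals(Q, start, as.integer(n_events),
                            scheme$open_states)
    dwell_sequence(r$open == 1L, r$duration_ms, td = 0, origin = "simulated")
  })
}

#' Ground-truth record for a synthetic scenario
#'
#' @inheritParams predict_crc
#' @param concentrations agonist concentrations (molar) of the scenario.
#' @param seed scenario seed, embedded in the record.
#' @return list of class `truth_record` with the equilibrium constants,
#'   energies, efficiency, predicted CRC descriptors and the theoretical
#'   open probability at each concentration.
#' @export
truth_record <- function(KdC, KdO, L0, concentrations, seed = 1) {
  pred <- predict_crc(KdC, KdO, L0)
  structure(list(KdC = KdC, KdO = KdO, L0 = L0, L2 = pred$L2,
                 c = coupling_constant(KdC, KdO),
                 dG_LA = binding_energy(KdC), dG_HA = binding_energy(KdO),
                 eta = efficiency_from_kd(KdC, KdO),
                 EC50 = pred$EC50, POmax = pred$POmax,
                 concentrations = concentrations,
                 po_theoretical = po_curve(concentrations, KdC, pred$L2),
                 seed = seed),
            class = "truth_record")
}

#' Simulate a noisy concentration-response dataset
#'
#' Two noise modes.  `"gaussian"`: adds zero-mean Gaussian noise of the
#' given sd to the theoretical open probabilities, clipped to `[0, 1]`
#' (`sd = 0` returns the theoretical curve exactly).  `"dwell"`: runs the
#' full measurement chain per concentration — stochastic interval
#' simulation, dead-time imposition, tcrit segmentation, left-truncated
#' exponential-mixture fits of the pooled intra-cluster durations, and
#' `cluster_po` from the predominant time constants.
#'
#' @param truth a [truth_record()].
#' @param concentrations molar concentrations (defaults to those in
#'   `truth`).
#' @param noise list: `mode = "gaussian"` with `sd`, or `mode = "dwell"`
#'   with `n_events` per concentration.
#' @param seed RNG seed.
#' @param scales,td,tcrit dwell-mode controls passed to
#'   [scheme_from_constants()], [impose_dead_time()],
#'   [segment_clusters()].
#' @return a [crc_dataset()] with the truth record attached as attribute
#'   `truth`.
#' @export
simulate_crc <- function(truth, concentrations = truth$concentrations,
                         noise = list(mode = "gaussian", sd = 0.03),
                         seed = 1, scales = list(), td = 0.025, tcrit = 20) {
  check_positive(concentrations, "concentrations")
  mode <- match.arg(noise$mode, c("gaussian", "dwell"))
  po_true <- po_curve(concentrations, truth$KdC, truth$L2)
  if (mode == "gaussian") {
    sd_ <- noise$sd %||% 0.03
    po <- if (sd_ == 0) po_true else with_seed(seed, {
      pmin(pmax(po_true + rnorm(length(po_true), 0, sd_), 0), 1)
    })
  } else {
    n_events <- noise$n_events %||% 10000
    scheme <- scheme_from_constants(truth$KdC, truth$KdO, truth$L0, scales)
    po <- vapply(seq_along(concentrations), function(i) {
      s <- simulate_intervals(scheme, concentrations[i], n_events,
                              seed = seed + i)
      r <- suppressWarnings(impose_dead_time(s, td))
      cl <- segment_clusters(r, tcrit = tcrit)
      dur <- cluster_durations(cl)
      fo <- fit_dwell_mixture(dur$open, td = td, seed = seed + i)
      fs <- fit_dwell_mixture(dur$shut, td = td, seed = seed + i + 1L)
      cluster_po(predominant_tau(fo), predominant_tau(fs))
    }, numeric(1))
  }
  structure(crc_dataset(A = concentrations, po = po, unit = "M",
                        label = sprintf("synthetic_seed%d", seed)),
            truth = truth)
}

#' Generate a planted population of efficiency classes
#'
#' Draws per-member efficiencies from Gaussian classes (draws outside
#' (0, 1) are rejected and resampled), draws `KdC` log-uniformly over
#' `kdc_range`, and derives the other constants so that each member lies
#' exactly on its class relation: `ln KdO = ln KdC / (1 - eta)` and
#' `L2 = L0 * (KdC/KdO)^2`.  Defaults plant the five reference classes at
#' the shipped means/sds with 5 members each.
#'
#' @param class_means efficiency class means (in (0, 1)).
#' @param class_sds per-class standard deviations.
#' @param n_per_class members per class (scalar or per-class vector).
#' @param kdc_range range of `KdC` in molar (log-uniform sampling).
#' @param L0 unliganded gating constant used for `L2`.
#' @param seed RNG seed.
#' @return data.frame with columns `class`, `eta_class` (nominal mean),
#'   `eta`, `KdC`, `KdO`, `L2`, `dG_LA`, `dG_HA`.
#' @export
generate_population <- function(class_means = crceta_constants()$eta_class_means,
                                class_sds = crceta_constants()$eta_class_sds,
                                n_per_class = 5,
                                kdc_range = c(1e-6, 1e-2),
                                L0 = 5.2e-7, seed = 1) {
  check_probability(class_means, "class_means")
  if (length(class_sds) == 1) class_sds <- rep(class_sds, length(class_means))
  if (length(n_per_class) == 1)
    n_per_class <- rep(n_per_class, length(class_means))
  stopifnot(length(class_sds) == length(class_means),
            length(n_per_class) == length(class_means))
  check_positive(kdc_range, "kdc_range")
  with_seed(seed, {
    rows <- lapply(seq_along(class_means), function(ci) {
      n <- n_per_class[ci]
      eta <- numeric(n)
      KdC <- exp(runif(n, log(kdc_range[1]), log(kdc_range[2])))
      for (i in seq_len(n)) {
        repeat {
          e <- rnorm(1, class_means[ci], class_sds[ci])
          # reject draws outside (0,1) or so close to 1 that the implied
          # KdO would underflow
          if (e > 0 && e < 1 && log(KdC[i]) / (1 - e) > -700) break
        }
        eta[i] <- e
      }
      KdO <- exp(log(KdC) / (1 - eta))
      data.frame(class = ci, eta_class = class_means[ci], eta = eta,
                 KdC = KdC, KdO = KdO, L2 = L0 * (KdC / KdO)^2,
                 dG_LA = binding_energy(KdC), dG_HA = binding_energy(KdO))
    })
    do.call(rbind, rows)
  })
}

#' Write a complete synthetic scenario to disk
#'
#' Emits the three fixture files for one scenario: a CRC CSV
#' (Gaussian-noise mode), an idealized interval CSV (one dwell simulation
#' at the scenario's EC50) and the ground-truth JSON.  File names embed
#' the seed.
#'
#' @param dir output directory (created if needed).
#' @param truth a [truth_record()].
#' @param noise_sd Gaussian noise sd for the CRC file.
#' @param n_events events for the interval file.
#' @return invisible named vector of the three file paths.
#' @export
write_fixture_scenario <- function(dir, truth, noise_sd = 0.03,
                                   n_events = 2000) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- truth$seed
  crc <- simulate_crc(truth, noise = list(mode = "gaussian", sd = noise_sd),
                      seed = seed)
  crc_path <- file.path(dir, sprintf("crc_seed%d.csv", seed))
  write.csv(data.frame(label = attr(crc, "label"),
                       concentration = crc$A, concentration_unit = "M",
                       po = crc$po), crc_path, row.names = FALSE)
  scheme <- scheme_from_constants(truth$KdC, truth$KdO, truth$L0)
  iv <- simulate_intervals(scheme, truth$EC50, n_events, seed = seed)
  iv_path <- file.path(dir, sprintf("intervals_seed%d.csv", seed))
  write_intervals_csv(iv, iv_path)
  truth_path <- file.path(dir, sprintf("truth_seed%d.json", seed))
  jsonlite::write_json(unclass(truth), truth_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(crc = crc_path, intervals = iv_path, truth = truth_path))
}
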