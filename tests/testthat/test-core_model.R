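test_that("gating constant and open probability interconvert", {
  expect_equal(gating_constant_from_po(0.5), 1.0)
  expect_equal(gating_constant_from_po(0.96), 24.0)
  expect_equal(gating_constant_from_po(0.60), 1.5)
  expect_equal(po_from_gating_constant(24), 0.96)
  for (po in c(1e-6, 0.01, 0.3, 0.5, 0.9, 1 - 1e-9))
    expect_equal(po_from_gating_constant(gating_constant_from_po(po)), po)
  expect_error(gating_constant_from_po(0), "po")
  expect_error(gating_constant_from_po(1), "po")
  expect_error(po_from_gating_constant(-2), "L")
})

test_that("closed-form KdC from EC50 matches a brute-force bisection oracle", {
  # oracle: numerically solve P_O(EC50) = POmax/2 on the two-site curve
  kdc_oracle <- function(ec50, L2) {
    target <- L2 / (1 + L2) / 2
    stats::uniroot(function(K) po_curve(ec50, K, L2) - target,
                   interval = c(ec50 * 1e-7, ec50 * 1e7),
                   tol = 1e-18)$root
  }
  for (L2 in 10^seq(-4, 4, by = 1)) {
    ec50 <- 110e-6
    expect_equal(kdc_from_ec50(ec50, L2), kdc_oracle(ec50, L2),
                 tolerance = 1e-9)
  }
  expect_equal(kdc_from_ec50(110e-6, 4.0) * 1e6, 159.44, tolerance = 1e-4)
  # zero-efficacy limit: KdC -> EC50 / (1 + sqrt(2))
  expect_equal(kdc_from_ec50(1, 1e-12), 1 / (1 + sqrt(2)), tolerance = 1e-6)
  # published anchor: BzTMA
  expect_equal(kdc_from_ec50(1070e-6, 1.5) * 1e6, 930, tolerance = 0.01)
  expect_error(kdc_from_ec50(-1, 2), "ec50")
})

test_that("cycle closure gives the open-state dissociation constant", {
  expect_equal(kdo_from_cycle(174e-6, 26.64, 7.4e-7) * 1e9, 29,
               tolerance = 0.001)
  expect_equal(kdo_from_cycle(5e-5, 3, 3), 5e-5)          # c = 1 identity
  expect_equal(kdo_from_cycle(100e-6, 1.0, 1e-6) * 1e9, 100)
  # inverse agonism permitted
  expect_lt(1, kdo_from_cycle(1e-4, 1e-8, 1e-6) / 1e-4)
  expect_error(kdo_from_cycle(0, 1, 1), "KdC")
})

test_that("coupling constant, binding energy and efficacy behave", {
  expect_equal(coupling_constant(90e-6, 140e-9), 642.86, tolerance = 1e-4)
  expect_equal(coupling_constant(3e-7, 3e-7), 1.0)
  expect_equal(coupling_constant(138e-6, 900e-9), 153.33, tolerance = 1e-4)
  expect_equal(binding_energy(174e-6), -5.107, tolerance = 1e-3)
  expect_equal(binding_energy(1), 0.0)
  expect_equal(binding_energy(29e-9), -10.24, tolerance = 1e-3)
  expect_equal(kd_from_energy(binding_energy(3.3e-5)), 3.3e-5,
               tolerance = 1e-12)
  expect_equal(efficacy_lambda(-10.24, -5.11), -5.13)
  expect_equal(efficacy_lambda(-3, -3), 0)
  # lambda = -RT ln c
  c_ <- 643
  kdc <- 90e-6; kdo <- kdc / c_
  expect_equal(efficacy_lambda(binding_energy(kdo), binding_energy(kdc)),
               -0.59 * log(c_), tolerance = 1e-9)
  expect_error(binding_energy(0), "Kd")
})

test_that("efficiency definitions agree and guard their domain", {
  expect_equal(efficiency(-5.107, -10.240), 0.5013, tolerance = 1e-3)
  expect_equal(efficiency(0, -10), 1.0)
  expect_equal(efficiency_from_kd(90e-6, 140e-9), 0.4097, tolerance = 1e-4)
  # the two routes agree exactly (same RT cancels)
  kdc <- 3.7e-4; kdo <- 6.1e-8
  expect_identical(efficiency(binding_energy(kdc, 0.59),
                              binding_energy(kdo, 0.59)),
                   efficiency_from_kd(kdc, kdo))
  # eta is invariant to RT (ratio of logs)
  expect_equal(efficiency(binding_energy(kdc, 0.7), binding_energy(kdo, 0.7)),
               efficiency_from_kd(kdc, kdo))
  expect_error(efficiency(-5, 0), "dG_HA")
})

test_that("efficiency is unit sensitive by design and units are declared", {
  # same numbers in uM vs M give different eta unless converted
  expect_equal(efficiency_from_kd(90, 0.14, unit = "uM"),
               efficiency_from_kd(90e-6, 0.14e-6))
  expect_false(isTRUE(all.equal(efficiency_from_kd(90, 0.14),
                                efficiency_from_kd(90e-6, 0.14e-6))))
  expect_error(to_molar(5), "unit")
  expect_error(to_molar(5, "mg/mL"), "unknown")
  expect_equal(to_molar(c(174, 29), c("uM", "nM")), c(1.74e-4, 2.9e-8))
  expect_equal(to_molar(1, "µM"), 1e-6)  # micro sign accepted
})

test_that("eta/slope conversions round-trip", {
  expect_equal(eta_from_slope(2.0), 0.5)
  expect_equal(eta_from_slope(2.545), 0.56, tolerance = 1e-3)
  expect_equal(slope_from_eta(0.41), 1.3898, tolerance = 1e-4)
  for (m in c(0.1, 1, 2.5, 10))
    expect_equal(slope_from_eta(eta_from_slope(m)), m, tolerance = 1e-12)
  expect_error(eta_from_slope(-0.2), "m")
})

test_that("the two-site curve has the right limits and midpoint", {
  expect_equal(po_curve(0, 1e-4, 24), 0)
  expect_equal(po_curve(100, 1e-4, 24), 24 / 25, tolerance = 1e-6)
  KdC <- 2e-4; L2 <- 5.3
  ec50 <- ec50_from_constants(KdC, L2)
  expect_equal(po_curve(ec50, KdC, L2), L2 / (1 + L2) / 2, tolerance = 1e-12)
  A <- 10^seq(-7, -2, length.out = 40)
  expect_true(all(diff(po_curve(A, KdC, L2)) > 0))  # monotone
  # one-site variant
  expect_equal(po_curve(1e-4, 1e-4, 3, n_sites = 1), 3 / 5)
  expect_error(po_curve(1e-4, 1e-4, 3, n_sites = 4), "n_sites")
})

test_that("predict_crc inverts back to the constants it came from", {
  expect_equal(predict_crc(174e-6, 29e-9, 7.4e-7)$POmax, 0.9638,
               tolerance = 1e-4)
  expect_equal(predict_crc(174e-6, 29e-9, 7.4e-7)$EC50 * 1e6, 39.98,
               tolerance = 1e-3)
  p0 <- predict_crc(1e-4, 1e-4, 3e-7)
  expect_equal(p0$POmax, p0$POmin)  # KdO = KdC: no coupling
  set.seed(42)
  for (i in 1:20) {
    KdC <- 10^stats::runif(1, -6, -2)
    L2 <- 10^stats::runif(1, -3, 3)
    L0 <- 10^stats::runif(1, -8, -5)
    KdO <- kdo_from_cycle(KdC, L2, L0)
    pred <- predict_crc(KdC, KdO, L0)
    L2_back <- gating_constant_from_po(pred$POmax)
    KdC_back <- kdc_from_ec50(pred$EC50, L2_back)
    KdO_back <- kdo_from_cycle(KdC_back, L2_back, L0)
    expect_equal(KdC_back, KdC, tolerance = 1e-7)
    expect_equal(KdO_back, KdO, tolerance = 1e-7)
    expect_equal(L2_back, L2, tolerance = 1e-7)
    # cycle closure: recomputing c and back reproduces KdO
    expect_equal(KdC / coupling_constant(KdC, KdO), KdO, tolerance = 1e-9)
  }
})

test_that("delta-method sems agree with a parametric bootstrap", {
  est <- list(KdC = 90e-6, KdO = 140e-9)
  sem <- list(KdC = 7e-6, KdO = 10e-9)
  d <- propagate_sem(est, sem, "eta")
  expect_equal(d$value, 0.4097, tolerance = 1e-3)
  expect_equal(round(d$sem, 2), 0.01)  # table rounds to 0.01
  # independent oracle: 1e4-draw parametric bootstrap
  set.seed(7)
  kc <- stats::rnorm(1e4, est$KdC, sem$KdC)
  ko <- stats::rnorm(1e4, est$KdO, sem$KdO)
  boot <- stats::sd(1 - log(kc) / log(ko))
  expect_lt(abs(d$sem - boot) / boot, 0.15)
  # zero in, zero out; and a pure scaling check on a log-free target
  z <- propagate_sem(est, list(KdC = 0, KdO = 0), "c")
  expect_identical(z$sem, 0)
  lin <- propagate_sem(est, list(KdC = 3e-6, KdO = 0), "c")
  expect_equal(lin$sem, 3e-6 / est$KdO)  # c = KdC/KdO is linear in KdC
})

test_that("delta-method sems propagate through the full CRC inversion", {
  est <- list(EC50 = 1070e-6, POmax = 0.60)
  sem <- list(EC50 = 200e-6, POmax = 0.05)
  d <- propagate_sem(est, sem, "eta", L0 = 5.2e-7)
  set.seed(11)
  e <- stats::rnorm(2e4, est$EC50, sem$EC50)
  p <- stats::rnorm(2e4, est$POmax, sem$POmax)
  ok <- e > 0 & p > 0.05 & p < 0.95
  prof <- activation_profile(EC50 = 1, POmax = 0.5, L0 = 5.2e-7) # warm call
  eta_b <- vapply(which(ok)[1:1e4], function(i) {
    L2 <- (p[i] / (1 - p[i]))
    kdc <- kdc_from_ec50(e[i], L2)
    efficiency_from_kd(kdc, kdo_from_cycle(kdc, L2, 5.2e-7))
  }, numeric(1))
  expect_lt(abs(d$sem - stats::sd(eta_b)) / stats::sd(eta_b), 0.15)
  expect_error(propagate_sem(est, sem, "eta"), "L0")
  expect_error(propagate_sem(list(a = 1, b = 2), sem, "eta"), "named")
})
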