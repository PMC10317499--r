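# shared fixture builders; everything is generated in code

hill_po <- function(A, POmax, EC50, nH) POmax / (1 + (EC50 / A)^nH)

# draw durations from an exponential mixture conditioned on >= td
# (memorylessness: shift each component by td and reweight)
rexp_mix_trunc <- function(n, tau, w, td = 0) {
  wp <- w * exp(-td / tau)
  wp <- wp / sum(wp)
  comp <- sample.int(length(tau), n, replace = TRUE, prob = wp)
  td + stats::rexp(n, 1 / tau[comp])
}

# alternating two-state dwell sequence with exponential sojourns (ms)
make_two_state_seq <- function(n_pairs, mean_open_ms, mean_shut_ms) {
  state <- rep(c("shut", "open"), n_pairs)
  dur <- numeric(2 * n_pairs)
  dur[seq(1, 2 * n_pairs, by = 2)] <- stats::rexp(n_pairs, 1 / mean_shut_ms)
  dur[seq(2, 2 * n_pairs, by = 2)] <- stats::rexp(n_pairs, 1 / mean_open_ms)
  dwell_sequence(state, dur)
}

# reference truth used by the end-to-end recovery checks: a weak,
# fast-unbinding agonist whose simulated records satisfy the dead-time and
# tcrit working assumptions of the dwell analysis (see methods vignette);
# six concentrations bracketing the predicted EC50
reference_truth <- function(seed = 1, mults = c(0.25, 0.5, 1, 2, 4, 8)) {
  KdC <- 2e-3; KdO <- 510e-9; L0 <- 5.2e-7
  ec50 <- predict_crc(KdC, KdO, L0)$EC50
  truth_record(KdC, KdO, L0, concentrations = ec50 * mults, seed = seed)
}
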