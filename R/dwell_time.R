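#' Construct an idealized dwell sequence
#'
#' An alternating list of open/shut sojourns, as produced by idealization
#' of a single-channel record.  States must strictly alternate and all
#' durations must be positive.
#'
#' @param state character vector of `"open"`/`"shut"` (or a logical vector,
#'   TRUE = open).
#' @param duration_ms sojourn durations in milliseconds.
#' @param td dead time already imposed on the sequence (ms; 0 for raw
#'   idealizations).
#' @param origin `"imported"` or `"simulated"`.
#' @return a `dwell_sequence`: data.frame with columns `state`,
#'   `duration_ms` and attributes `td`, `origin`.
#' @export
dwell_sequence <- function(state, duration_ms, td = 0, origin = "imported") {
  if (is.logical(state)) state <- ifelse(state, "open", "shut")
  if (!all(state %in% c("open", "shut")))
    stop("states must be 'open' or 'shut'")
  if (length(state) != length(duration_ms)) stop("input lengths differ")
  if (any(!is.finite(duration_ms)) || any(duration_ms <= 0))
    stop("all durations must be positive and finite")
  if (length(state) > 1 && any(state[-1] == state[-length(state)]))
    stop("open/shut states must strictly alternate")
  structure(data.frame(state = state, duration_ms = duration_ms,
                       stringsAsFactors = FALSE),
            class = c("dwell_sequence", "data.frame"),
            td = td, origin = origin)
}

is_open <- function(seq) seq$state == "open"

#' Impose a recording dead time on a dwell sequence
#'
#' Sojourns shorter than `td` are unresolvable: each is merged, together
#' with its following resolvable sojourn, into the preceding resolvable
#' sojourn (which has the same conductance class), so total duration is
#' conserved and alternation preserved.  Unresolvable sojourns at the very
#' start or end of the record have no flanking pair and are trimmed with a
#' warning reporting the count.  The operation is idempotent.
#'
#' @param seq a [dwell_sequence()].
#' @param td dead time in ms (>= 0).
#' @return a `dwell_sequence` in which every duration is >= `td`.
#' @examples
#' s <- dwell_sequence(c("open", "shut", "open"), c(1.0, 0.01, 2.0))
#' impose_dead_time(s, 0.025)  # single open sojourn of 3.01 ms
#' @export
impose_dead_time <- function(seq, td) {
  if (td < 0) stop("'td' must be >= 0")
  dur <- seq$duration_ms
  open <- is_open(seq)
  n <- length(dur)
  trimmed <- 0L

  i <- 1L
  while (i <= n && dur[i] < td) { i <- i + 1L; trimmed <- trimmed + 1L }
  if (i > n) {
    warning("entire sequence unresolved at td = ", td, " ms")
    return(dwell_sequence(character(0), numeric(0), td = td,
                          origin = attr(seq, "origin")))
  }

  out_open <- logical(0); out_dur <- numeric(0)
  co <- open[i]; cd <- dur[i]; i <- i + 1L
  while (i <= n) {
    if (dur[i] >= td) {
      if (open[i] == co) {
        cd <- cd + dur[i]           # same class after an upstream trim/merge
      } else {
        out_open <- c(out_open, co); out_dur <- c(out_dur, cd)
        co <- open[i]; cd <- dur[i]
      }
      i <- i + 1L
    } else {
      # unresolved: absorb it and its follower into the current sojourn
      if (i + 1L <= n) {
        cd <- cd + dur[i] + dur[i + 1L]
        i <- i + 2L
      } else {
        trimmed <- trimmed + 1L     # dangling unresolved tail
        i <- i + 1L
      }
    }
  }
  out_open <- c(out_open, co); out_dur <- c(out_dur, cd)
  if (trimmed > 0L)
    warning(trimmed, " unresolved boundary sojourn(s) trimmed")
  dwell_sequence(out_open, out_dur, td = td, origin = attr(seq, "origin"))
}

#' Segment a dwell sequence into clusters at a critical shut time
#'
#' Shut sojourns longer than `tcrit` are attributed to desensitized states:
#' the sequence is split at each such sojourn (which is discarded), and
#' clusters with fewer than `min_openings` openings are dropped.
#'
#' @param seq a [dwell_sequence()].
#' @param tcrit critical shut duration in ms (default 20).
#' @param min_openings minimum openings a cluster must contain (default 2).
#' @return a `cluster_set`: list of `dwell_sequence` clusters, with
#'   attributes `tcrit` and `n_dropped`.
#' @export
segment_clusters <- function(seq, tcrit = 20, min_openings = 2) {
  td <- attr(seq, "td") %||% 0
  if (tcrit <= td) stop("'tcrit' must exceed the dead time")
  open <- is_open(seq)
  gap <- !open & seq$duration_ms > tcrit
  grp <- cumsum(gap)
  keep <- !gap
  pieces <- split(seq_along(grp)[keep], grp[keep])
  clusters <- list()
  dropped <- 0L
  for (idx in pieces) {
    n_open <- sum(open[idx])
    if (n_open < min_openings) { dropped <- dropped + 1L; next }
    clusters[[length(clusters) + 1L]] <-
      dwell_sequence(open[idx], seq$duration_ms[idx], td = td,
                     origin = attr(seq, "origin"))
  }
  structure(clusters, class = "cluster_set", tcrit = tcrit,
            n_dropped = dropped)
}

#' Pool intra-cluster open and shut durations
#'
#' @param clusters a `cluster_set` from [segment_clusters()].
#' @return list with numeric vectors `open` and `shut` (ms).
#' @export
cluster_durations <- function(clusters) {
  open <- unlist(lapply(clusters, function(cl) cl$duration_ms[is_open(cl)]))
  shut <- unlist(lapply(clusters, function(cl) cl$duration_ms[!is_open(cl)]))
  list(open = open %||% numeric(0), shut = shut %||% numeric(0))
}

# single EM run for a k-component exponential mixture on shifted data y
.em_expmix <- function(y, tau, w, tol = 1e-8, max_iter = 2000) {
  k <- length(tau)
  ll0 <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * dexp(y, 1 / tau[j]), numeric(length(y)))
    dens <- matrix(dens, ncol = k)
    rs <- rowSums(dens)
    rs[rs <= 0] <- .Machine$double.xmin
    ll <- sum(log(rs))
    resp <- dens / rs
    w <- colMeans(resp)
    tau <- colSums(resp * y) / pmax(colSums(resp), 1e-300)
    tau[!is.finite(tau) | tau <= 0] <- 1e-9
    if (is.finite(ll) && abs(ll - ll0) < tol) break
    ll0 <- ll
  }
  list(tau = tau, w = w, logL = ll, iters = it, converged = it < max_iter)
}

#' Maximum-likelihood exponential mixture fit of dwell durations
#'
#' Fits a mixture of exponentials to sojourn durations, accounting for the
#' recording dead time by left truncation: because exponential components
#' are memoryless, the durations shifted by `td` again follow an
#' exponential mixture with the same time constants and with weights
#' `w' = w * exp(-td/tau) / sum(...)`; the fit is run on the shifted data
#' by expectation-maximization with seeded restarts and the reported
#' weights are converted back to the untruncated scale.  The component
#' count grows from 1 until the log likelihood fails to improve by
#' `delta_LL_stop` (default 10) units.
#'
#' @param durations sojourn durations in ms (>= 20 values, all >= `td`).
#' @param td dead time in ms.
#' @param delta_LL_stop stopping increment in log-likelihood units.
#' @param max_components hard cap on the component count.
#' @param restarts seeded EM restarts per component count.
#' @param seed RNG seed for the restarts.
#' @param tol EM convergence tolerance on the log likelihood.
#' @return object of class `dwell_mixture`: list with `components`
#'   (data.frame of `tau` ms and untruncated `weight`, sorted by
#'   descending weight), `k`, `logL` (left-truncated log likelihood),
#'   `logL_path`, `td`, `converged` and `flag` (non-`NULL` when a larger
#'   model failed and the previous count was kept).
#' @examples
#' set.seed(1)
#' f <- fit_dwell_mixture(rexp(2000, 1 / 10), td = 0.025)
#' predominant_tau(f)  # ~10 ms
#' @export
fit_dwell_mixture <- function(durations, td = 0, delta_LL_stop = 10,
                              max_components = 5, restarts = 8, seed = 1,
                              tol = 1e-8) {
  if (length(durations) < 20)
    stop("at least 20 durations are required for a mixture fit")
  if (any(durations < td))
    stop("durations below the dead time present; impose the dead time first")
  y <- durations - td
  y[y <= 0] <- .Machine$double.eps

  fits <- list()
  flag <- NULL
  for (k in seq_len(max_components)) {
    if (k == 1) {
      tau <- mean(y)
      fits[[1]] <- list(tau = tau, w = 1,
                        logL = sum(dexp(y, 1 / tau, log = TRUE)),
                        converged = TRUE)
    } else {
      prev <- fits[[k - 1]]
      cand <- with_seed(seed + k, {
        best <- NULL
        for (r in seq_len(restarts + 1L)) {
          if (r == 1L) {
            # grow the previous solution by one small far component
            tau0 <- c(prev$tau, max(y) * runif(1, 0.5, 1))
            w0 <- c(prev$w * (1 - 1 / (10 * k)), 1 / (10 * k))
          } else {
            tau0 <- as.numeric(quantile(y, (seq_len(k)) / (k + 1))) *
              exp(runif(k, -0.7, 0.7))
            tau0[tau0 <= 0] <- mean(y)
            w0 <- rep(1 / k, k)
          }
          f <- .em_expmix(y, tau0, w0, tol = tol)
          if (is.null(best) || f$logL > best$logL) best <- f
        }
        best
      })
      if (is.null(cand) || !is.finite(cand$logL)) {
        flag <- paste0("EM failed at k = ", k, "; keeping k = ", k - 1)
        break
      }
      fits[[k]] <- cand
      if (cand$logL - fits[[k - 1]]$logL < delta_LL_stop) break
    }
  }
  path <- vapply(fits, function(f) f$logL, numeric(1))
  # keep the last count whose addition improved logL by the stop increment
  k_sel <- 1L
  while (k_sel < length(fits) &&
         path[k_sel + 1] - path[k_sel] >= delta_LL_stop) k_sel <- k_sel + 1L
  sel <- fits[[k_sel]]
  w_untr <- sel$w * exp(td / sel$tau)
  w_untr <- w_untr / sum(w_untr)
  ord <- order(w_untr, decreasing = TRUE)
  comp <- data.frame(tau = sel$tau[ord], weight = w_untr[ord])
  structure(list(components = comp, k = k_sel, logL = sel$logL,
                 logL_path = path, td = td,
                 converged = isTRUE(sel$converged), flag = flag),
            class = "dwell_mixture")
}

#' Predominant time constant of a dwell mixture
#'
#' The component with the largest (untruncated) weight; ties broken in
#' favour of the longer time constant.
#'
#' @param fit a [fit_dwell_mixture()] result.
#' @return time constant in ms.
#' @export
predominant_tau <- function(fit) {
  comp <- fit$components
  top <- comp[comp$weight >= max(comp$weight) - 1e-12, , drop = FALSE]
  max(top$tau)
}

#' @export
print.dwell_mixture <- function(x, ...) {
  cat(sprintf("exponential mixture: %d component(s), logL = %.2f%s\n",
              x$k, x$logL, if (!is.null(x$flag)) paste0(" [", x$flag, "]") else ""))
  print(transform(x$components, tau = signif(tau, 4),
                  weight = signif(weight, 3)), row.names = FALSE)
  invisible(x)
}

#' Cluster open probability from predominant time constants
#'
#' `P_O = tau_o / (tau_s + tau_o)` with `tau_o`, `tau_s` the predominant
#' open and shut time constants of the intra-cluster interval
#' distributions.
#'
#' @param tau_o predominant open time constant (ms).
#' @param tau_s predominant shut time constant (ms).
#' @return open probability.
#' @export
cluster_po <- function(tau_o, tau_s) {
  check_positive(tau_o, "tau_o")
  check_positive(tau_s, "tau_s")
  tau_o / (tau_s + tau_o)
}

#' Unliganded gating constant from a two-state dwell sequence
#'
#' For agonist-free recordings the interval list is treated as a two-state
#' C = O process.  After imposing the dead time, the truncation-corrected
#' maximum-likelihood rate estimates are `f0 = 1/(mean shut - td)` and
#' `b0 = 1/(mean open - td)` (exponential sojourns left-truncated at `td`
#' have MLE mean `sample mean - td`), and `L0 = f0/b0`.  The ratio is
#' invariant to the time unit.
#'
#' @param seq a [dwell_sequence()] of unliganded intervals.
#' @param td dead time in ms (default 0.025).
#' @return list with `f0` and `b0` (s^-1) and `L0`.
#' @export
estimate_unliganded_L0 <- function(seq, td = 0.025) {
  r <- if ((attr(seq, "td") %||% 0) >= td && all(seq$duration_ms >= td))
    seq else impose_dead_time(seq, td)
  open <- r$duration_ms[is_open(r)]
  shut <- r$duration_ms[!is_open(r)]
  if (length(open) < 20 || length(shut) < 20)
    stop("at least 20 resolved intervals per class are required")
  b0 <- 1000 / (mean(open) - td)
  f0 <- 1000 / (mean(shut) - td)
  list(f0 = f0, b0 = b0, L0 = f0 / b0)
}

#' Read / write idealized interval lists as CSV
#'
#' Columns: `state` (`open`/`shut`), `duration_ms`, optional `sweep_id`
#' (each sweep becomes its own sequence on reading).
#'
#' @param path CSV file path.
#' @return `read_intervals_csv`: a list of [dwell_sequence()] objects (one
#'   per sweep; a single unnamed sweep yields a list of length 1).
#' @export
read_intervals_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("state", "duration_ms") %in% names(d)))
    stop("interval csv needs columns 'state' and 'duration_ms'")
  sweep <- if ("sweep_id" %in% names(d)) d$sweep_id else rep(1L, nrow(d))
  lapply(split(d, sweep), function(g)
    dwell_sequence(g$state, g$duration_ms))
}

#' @rdname read_intervals_csv
#' @param seq a [dwell_sequence()] (or list of them) to write.
#' @export
write_intervals_csv <- function(seq, path) {
  if (inherits(seq, "dwell_sequence")) seq <- list(seq)
  rows <- do.call(rbind, lapply(seq_along(seq), function(i)
    data.frame(state = seq[[i]]$state, duration_ms = seq[[i]]$duration_ms,
               sweep_id = i)))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
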