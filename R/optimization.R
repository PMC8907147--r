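#' Energy-offset rebalancing configuration
#'
#' The rebalancing scheme nudges the offsets so that every end state is the
#' maximal contributor equally often at s = 1. The pseudo count
#' `c = f^mc,ideal / x` keeps the correction finite when a state was never
#' sampled; the default intensity factor x = 30 corresponds to capping the
#' correction at a 30-fold under-sampling.
#'
#' @param intensity_factor Pseudo-count intensity factor x (> 0).
#' @return Object of class `rebalance_config`.
#' @export
rebalance_config <- function(intensity_factor = 30) {
  stopifnot(intensity_factor > 0)
  structure(list(intensity_factor = intensity_factor),
            class = "rebalance_config")
}

#' Rebalance energy offsets towards equal state sampling
#'
#' Applies the iterative correction
#' \deqn{\Delta E_i^{corr} = -\frac{1}{\beta}
#'   \ln\frac{f_i^{mc} + c}{f^{mc,ideal} + c}, \qquad c = f^{mc,ideal}/x,}
#' to the current offsets. States sampled more often than the ideal 1/N
#' receive a negative correction (raising their effective energy), unseen
#' states the maximal positive correction `(1/beta) ln(x+1)`. At exactly
#' ideal sampling every correction is zero. The result is re-pinned so
#' state 1 reports an offset of zero (a uniform shift leaves all mixture
#' weights, forces and free-energy differences unchanged).
#'
#' @param report A [sampling_report()] from the s = 1 replica.
#' @param offsets Current offset vector (kJ/mol).
#' @param config A [rebalance_config()].
#' @param thermo A [thermo_context()].
#' @return New offset vector with attribute `correction`.
#' @export
rebalance_offsets <- function(report, offsets, config = rebalance_config(),
                              thermo = thermo_context()) {
  stopifnot(inherits(report, "sampling_report"),
            length(offsets) == length(report$f_mc))
  cc <- report$ideal_fraction / config$intensity_factor
  corr <- -log((report$f_mc + cc) / (report$ideal_fraction + cc)) / thermo$beta
  out <- offsets + corr
  out <- out - out[1L]
  attr(out, "correction") <- corr
  out
}

#' Maximal rebalancing correction
#'
#' The correction applied to a completely unsampled state (`f_i^mc = 0`).
#' With the pseudo count of the literal scheme this is
#' `(1/beta) ln(x + 1)`; the commonly quoted analytic magnitude of an x-fold
#' sampling reduction is `kB T ln(x)` (8.43 kJ/mol for x = 30 at 298.15 K).
#' Both are exposed so the small difference between them stays visible
#' rather than being reconciled silently.
#'
#' @param thermo A [thermo_context()].
#' @param intensity_factor Intensity factor x.
#' @param literal `TRUE` (default) for the pseudo-count cap
#'   `(1/beta) ln(x+1)`; `FALSE` for the x-fold-reduction magnitude
#'   `(1/beta) ln(x)`.
#' @return Correction magnitude in kJ/mol.
#' @export
rebalance_correction_cap <- function(thermo = thermo_context(),
                                     intensity_factor = 30,
                                     literal = TRUE) {
  log(intensity_factor + as.numeric(literal)) / thermo$beta
}

#' Identify per-state exchange bottlenecks
#'
#' For each end state i, the acceptance rate of each neighbouring ladder
#' interval is computed over only those exchange attempts in which state i
#' was the maximal contributor on either side of the pair. The severity of
#' an interval is one minus that acceptance rate; intervals with zero
#' attempts for a state are treated as full bottlenecks (severity 1).
#' Intervals are ranked per state by severity, ties broken towards the
#' larger s-gap and then the lower interval index.
#'
#' @param exchanges Exchange data frame from [run_reeds()] (columns
#'   `i, j, p, accepted, mc_i, mc_j`).
#' @param s_values The ladder the exchanges were run on.
#' @param n_states Number of end states.
#' @return List with `severity` (interval x state matrix) and `ranking`
#'   (list per state of interval indices, worst first).
#' @export
detect_bottlenecks <- function(exchanges, s_values, n_states) {
  s <- as.numeric(s_values)
  m <- length(s)
  stopifnot(m >= 2L)
  sev <- matrix(NA_real_, m - 1L, n_states)
  unattempted <- FALSE
  for (k in seq_len(m - 1L)) {
    at_k <- exchanges$i == k
    for (i in seq_len(n_states)) {
      rel <- at_k & (exchanges$mc_i == i | exchanges$mc_j == i)
      n_att <- sum(rel)
      if (n_att == 0L) {
        sev[k, i] <- 1
        unattempted <- TRUE
      } else {
        sev[k, i] <- 1 - mean(exchanges$accepted[rel])
      }
    }
  }
  if (unattempted)
    warning("interval(s) without exchange attempts treated as full bottlenecks")
  gaps <- s[-m] - s[-1L]
  ranking <- lapply(seq_len(n_states), function(i) {
    order(-sev[, i], -gaps, seq_len(m - 1L))
  })
  list(severity = sev, ranking = ranking)
}

#' One N-LRTO ladder-refinement step
#'
#' Distributes `n_insert` new replicas round-robin over the per-state worst
#' bottleneck intervals: state 1's top interval receives the first
#' insertion, state 2's the second, and so on, cycling. Within an interval
#' receiving m insertions, the new s-values are linearly interpolated with
#' equal spacing between the interval's endpoints. All previous s-values
#' are retained; the result is sorted in decreasing order and near-duplicate
#' values (within 1e-12 relative) are coalesced.
#'
#' @param s_values Current ladder.
#' @param bottlenecks Result of [detect_bottlenecks()].
#' @param n_insert Number of replicas to insert (default 4).
#' @return The enlarged [s_distribution()].
#' @export
nlrto_step <- function(s_values, bottlenecks, n_insert = 4L) {
  stopifnot(n_insert >= 1L)
  s <- as.numeric(s_values)
  n_states <- length(bottlenecks$ranking)
  counts <- integer(length(s) - 1L)
  for (j in seq_len(n_insert)) {
    state <- (j - 1L) %% n_states + 1L
    iv <- bottlenecks$ranking[[state]][1L]
    counts[iv] <- counts[iv] + 1L
  }
  new_s <- unlist(lapply(which(counts > 0L), function(iv) {
    mth <- counts[iv]
    s[iv] + seq_len(mth) / (mth + 1) * (s[iv + 1L] - s[iv])
  }))
  out <- sort(c(s, new_s), decreasing = TRUE)
  keep <- c(TRUE, abs(diff(out)) > 1e-12 * out[-length(out)])
  s_distribution(out[keep])
}

#' Convergence check for the parameter optimization
#'
#' The optimization counts as converged when (a) every end state has a
#' nonzero maximal-contribution fraction at s = 1, (b) at least one round
#' trip occurred (round trips per ns above zero), and (c) the mean
#' round-trip time divided by the number of round trips is below 0.5 ns
#' equivalent. Times in MC steps are converted with `steps_per_ns`
#' (default 5e5, i.e. 2 fs per step in the MD analogy).
#'
#' @param f_mc Maximal-contribution fractions at s = 1.
#' @param round_trips A `round_trip_stats` object.
#' @param steps_per_ns Steps per nanosecond-equivalent.
#' @param tau_over_nrt_max Threshold for `tau_mean / nRT` (ns).
#' @return List with `converged` (logical) and `reasons` (character vector
#'   of failed clauses, empty when converged).
#' @export
check_convergence <- function(f_mc, round_trips, steps_per_ns = 5e5,
                              tau_over_nrt_max = 0.5) {
  reasons <- character(0)
  if (any(f_mc == 0)) reasons <- c(reasons, "state sampling")
  if (round_trips$n_round_trips == 0L) {
    reasons <- c(reasons, "no round trips")
  } else {
    ratio_ns <- (round_trips$mean_round_trip_time / steps_per_ns) /
      round_trips$n_round_trips
    if (!(ratio_ns < tau_over_nrt_max))
      reasons <- c(reasons, "round-trip time")
  }
  list(converged = length(reasons) == 0L, reasons = reasons)
}

#' Iteration-length schedule for the s-optimization
#'
#' Mirrors the reference ramp (first iteration short, then growing by the
#' same increment up to three times the base length) in MC-step units.
#'
#' @param base_steps Steps of the first iteration.
#' @param max_iterations Maximum number of s-optimization iterations.
#' @return Integer vector of per-iteration step counts.
#' @export
optimization_schedule <- function(base_steps = 3000L, max_iterations = 6L) {
  pmin(seq_len(max_iterations), 3L) * as.integer(base_steps)
}

#' Run the parameter-optimization stage
#'
#' Stage 3 of the workflow. First the s-ladder is refined iteratively:
#' short replica-exchange runs are alternated with N-LRTO insertions
#' (`n_insert` replicas per iteration at the per-state exchange
#' bottlenecks) until the round-trip criteria of [check_convergence()] pass
#' or the schedule is exhausted. Then, with the ladder frozen, the energy
#' offsets are rebalanced over further short runs until the
#' maximal-contribution fractions at s = 1 deviate from 1/N by at most
#' `rebalance_tolerance`, or the iteration cap is reached.
#'
#' @param states List of end states.
#' @param s_values Initial ladder.
#' @param offsets Initial offsets (typically from [explore_parameters()]).
#' @param configurations Starting configurations (vector, matrix or list;
#'   recycled/mapped onto the ladder).
#' @param thermo A [thermo_context()].
#' @param schedule Per-iteration step counts for the s-optimization (see
#'   [optimization_schedule()]).
#' @param n_insert Replicas added per N-LRTO iteration (default 4).
#' @param rebalance A [rebalance_config()].
#' @param rebalance_steps Steps per rebalancing run.
#' @param max_rebalance_iterations Cap on rebalancing iterations.
#' @param rebalance_tolerance Allowed max deviation of `f_mc` from 1/N.
#' @param exchange_interval Steps between exchange attempts.
#' @param steps_per_ns Step-to-ns conversion for the convergence rule.
#' @param seed Integer seed.
#' @return Object of class `optimization_state`: final `s_values`,
#'   `offsets`, `configurations`, `converged` flags per phase, `history`
#'   (one row per iteration: phase, n_replicas, nRT, tau_mean, max f_mc
#'   deviation), and the final `run`.
#' @export
run_optimization <- function(states, s_values, offsets,
                             configurations = NULL,
                             thermo = thermo_context(),
                             schedule = optimization_schedule(),
                             n_insert = 4L,
                             rebalance = rebalance_config(),
                             rebalance_steps = 3000L,
                             max_rebalance_iterations = 20L,
                             rebalance_tolerance = 0.12,
                             exchange_interval = 20L,
                             steps_per_ns = 5e5,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(states)
  s <- s_distribution(s_values)
  offsets <- as.numeric(offsets)
  confs <- configurations
  history <- list()
  s_converged <- FALSE
  run <- NULL

  if (length(schedule) == 0L) {
    return(structure(
      list(s_values = s, offsets = offsets, configurations = confs,
           converged = FALSE, s_converged = FALSE,
           rebalance_converged = FALSE,
           history = data.frame(), run = NULL),
      class = "optimization_state"))
  }

  for (it in seq_along(schedule)) {
    ens <- replica_ensemble(states, s, offsets = offsets,
                            configurations = confs, thermo = thermo)
    run <- run_reeds(ens, schedule[it], exchange_interval)
    f_mc <- max_contributing_fractions(physical_trajectory(run))
    conv <- check_convergence(f_mc, run$round_trips, steps_per_ns)
    history[[length(history) + 1L]] <- data.frame(
      phase = "s-optimization", iteration = it, n_replicas = length(s),
      nRT = run$round_trips$n_round_trips,
      tau_mean = run$round_trips$mean_round_trip_time,
      max_fmc_dev = max(abs(f_mc - 1 / n)))
    confs <- run$ensemble$configurations
    if (conv$converged) { s_converged <- TRUE; break }
    if (it == length(schedule)) break
    bn <- suppressWarnings(
      detect_bottlenecks(run$exchanges, s, n))
    s_new <- nlrto_step(s, bn, n_insert)
    confs <- map_configurations(s, confs, s_new)
    s <- s_new
  }

  rebalance_converged <- FALSE
  for (rb in seq_len(max_rebalance_iterations)) {
    ens <- replica_ensemble(states, s, offsets = offsets,
                            configurations = confs, thermo = thermo)
    run <- run_reeds(ens, rebalance_steps, exchange_interval)
    confs <- run$ensemble$configurations
    rep_s1 <- sampling_report(physical_trajectory(run))
    dev <- max(abs(rep_s1$f_mc - 1 / n))
    history[[length(history) + 1L]] <- data.frame(
      phase = "rebalancing", iteration = rb, n_replicas = length(s),
      nRT = run$round_trips$n_round_trips,
      tau_mean = run$round_trips$mean_round_trip_time,
      max_fmc_dev = dev)
    if (dev <= rebalance_tolerance) { rebalance_converged <- TRUE; break }
    offsets <- as.numeric(rebalance_offsets(rep_s1, offsets, rebalance, thermo))
  }

  structure(
    list(s_values = s, offsets = offsets, configurations = confs,
         converged = s_converged && rebalance_converged,
         s_converged = s_converged,
         rebalance_converged = rebalance_converged,
         history = do.call(rbind, history), run = run),
    class = "optimization_state"
  )
}

# When the ladder grows, seed each new level with the configuration of the
# nearest existing level (in log s).
map_configurations <- function(s_old, confs, s_new) {
  if (is.null(confs)) return(NULL)
  if (is.list(confs)) confs <- do.call(cbind, confs)
  if (is.null(dim(confs))) confs <- matrix(confs, nrow = 1L)
  idx <- vapply(as.numeric(s_new), function(sv) {
    which.min(abs(log(as.numeric(s_old)) - log(sv)))
  }, integer(1))
  confs[, idx, drop = FALSE]
}

#' @export
print.optimization_state <- function(x, ...) {
  cat(sprintf("<optimization_state> %d replicas, converged: %s (s: %s, rebalance: %s)\n",
              length(x$s_values), x$converged, x$s_converged,
              x$rebalance_converged))
  if (nrow(x$history)) print(x$history, row.names = FALSE)
  invisible(x)
}
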