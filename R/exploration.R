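#' Exploration-stage configuration
#'
#' Defaults follow the reference RE-EDS protocol: 21 initial s-values
#' log-spaced between 1 and 1e-5, undersampling declared when every state's
#' occurrence fraction (against `T^us` on `V_i - E_i`) is at least 0.75, the
#' ladder lower bound set two levels below the highest undersampling
#' replica, per-state bias offsets of +/-500 kJ/mol, the maximal-contributor
#' criterion checked over the last 30% of each state-optimization run, and a
#' stricter 0.9 occurrence criterion for PEOE replica membership.
#'
#' @param initial_s Initial ladder (an [s_distribution()]).
#' @param undersampling_occurrence_min Occurrence fraction declaring a
#'   replica undersampling for lower-bound detection.
#' @param levels_below Ladder levels below the highest undersampling replica
#'   at which the lower bound is placed.
#' @param bias_offset_magnitude Bias offset magnitude (kJ/mol) for per-state
#'   coordinate optimization.
#' @param state_opt_tail_fraction Final fraction of frames over which the
#'   favoured state must be the maximal contributor.
#' @param peoe_undersampling_min Occurrence fraction for PEOE membership.
#' @param threshold_quantile Quantile for threshold estimation.
#' @param discard_fraction Equilibration fraction discarded before PEOE.
#' @param peoe_n_replicas Ladder size for the offset-estimation run.
#' @return Object of class `exploration_config`.
#' @export
exploration_config <- function(initial_s = log_s_ladder(21L, 1e-5),
                               undersampling_occurrence_min = 0.75,
                               levels_below = 2L,
                               bias_offset_magnitude = 500,
                               state_opt_tail_fraction = 0.30,
                               peoe_undersampling_min = 0.9,
                               threshold_quantile = 0.95,
                               discard_fraction = 0.25,
                               peoe_n_replicas = 12L) {
  structure(
    list(initial_s = s_distribution(initial_s),
         undersampling_occurrence_min = undersampling_occurrence_min,
         levels_below = as.integer(levels_below),
         bias_offset_magnitude = bias_offset_magnitude,
         state_opt_tail_fraction = state_opt_tail_fraction,
         peoe_undersampling_min = peoe_undersampling_min,
         threshold_quantile = threshold_quantile,
         discard_fraction = discard_fraction,
         peoe_n_replicas = as.integer(peoe_n_replicas)),
    class = "exploration_config"
  )
}

#' Determine the lower bound of the s-ladder
#'
#' A replica counts as undersampling when every end state's occurrence
#' fraction against the undersampling thresholds (`V_i - E_i <= T_i^us`)
#' reaches `undersampling_occurrence_min` (default 0.75). To be
#' conservative, the returned lower bound is the ladder value
#' `levels_below` (default two) positions below the highest-s undersampling
#' replica, clamped to the last ladder level.
#'
#' @param traj_by_replica List of [energy_trajectory()] objects, one per
#'   ladder level, ordered by decreasing s (e.g. from [split_by_level()]).
#' @param thresholds A [threshold_set()].
#' @param config An [exploration_config()].
#' @return List with `lower_bound` (s-value), `index` (ladder index used),
#'   `undersampling` (logical per replica), `occurrence` (replica x state
#'   matrix).
#' @export
find_lower_bound <- function(traj_by_replica, thresholds,
                             config = exploration_config()) {
  s <- vapply(traj_by_replica, function(tr) tr$s[1L], numeric(1))
  stopifnot(!is.unsorted(rev(s), strictly = TRUE))
  occ <- t(vapply(traj_by_replica, undersampling_occurrence,
                  numeric(traj_n_states(traj_by_replica[[1L]])),
                  thresholds = thresholds))
  flags <- apply(occ >= config$undersampling_occurrence_min, 1L, all)
  if (!any(flags))
    stop("no undersampling replica found; extend the ladder to lower ",
         "s-values (smallest tried: ", format(min(s)), ")")
  top <- which(flags)[1L]
  idx <- min(top + config$levels_below, length(s))
  list(lower_bound = s[idx], index = idx, undersampling = flags,
       occurrence = occ)
}

#' Optimize a low-energy configuration for each end state
#'
#' For each state i an EDS simulation at s = 1 is run in which state i is
#' favoured by a large positive energy offset (+500 kJ/mol by default) while
#' all other states are suppressed with the negative of that offset. The
#' final configuration is accepted only when state i is the maximal
#' contributor in every frame of the last `state_opt_tail_fraction` of the
#' run; otherwise the run is retried once with doubled length before
#' failing. The per-state trajectories also feed the physical-occurrence
#' threshold estimate.
#'
#' @param states List of end states.
#' @param thermo A [thermo_context()].
#' @param config An [exploration_config()].
#' @param n_steps MC steps per state run.
#' @param start Starting configuration (defaults to the origin).
#' @param seed Integer seed.
#' @return List with `configurations` (list of per-state configurations) and
#'   `trajectories` (list of per-state [energy_trajectory()]).
#' @export
optimize_state_coordinates <- function(states, thermo = thermo_context(),
                                       config = exploration_config(),
                                       n_steps = 2000L, start = NULL,
                                       seed = NULL) {
  n <- length(states)
  stopifnot(n >= 2L)
  if (!is.null(seed)) set.seed(seed)
  d <- state_dimension(states[[1L]])
  if (is.null(start)) start <- rep(0, d)
  mag <- config$bias_offset_magnitude
  confs <- vector("list", n)
  trajs <- vector("list", n)
  for (i in seq_len(n)) {
    bias <- rep(-mag, n)
    bias[i] <- mag
    ref <- reference_state(states, s = 1, offsets = bias, thermo = thermo)
    len <- n_steps
    for (attempt in 1:2) {
      out <- propagate(ref, start, len)
      traj <- out$trajectory
      tail_idx <- traj$time > (1 - config$state_opt_tail_fraction) * max(traj$time)
      U <- t(traj_energy_matrix(traj))[, tail_idx, drop = FALSE] - bias
      ok <- all(max.col(t(-U), ties.method = "first") == i)
      if (ok) break
      len <- 2L * len
    }
    if (!ok)
      stop("state ", states[[i]]$id, " was not constantly the maximal ",
           "contributor in the last ",
           round(100 * config$state_opt_tail_fraction),
           "% of its biased run, even after doubling its length")
    confs[[i]] <- out$conf
    trajs[[i]] <- traj
  }
  list(configurations = confs, trajectories = trajs)
}

#' Parallel energy-offset estimation (PEOE)
#'
#' For every replica k in undersampling, new offsets are extracted as
#' \deqn{E_i^{R,new} = -\frac{1}{\beta}\ln\big\langle
#'   e^{-\beta(V_i - V_R)}\big\rangle_{R(s_k, E^{R,old})},}
#' a Zwanzig estimate of state i's free energy relative to the sampled
#' reference, evaluated with a log-space mean-exp. The per-replica estimates
#' are then averaged (unweighted) over the included replicas; the per-state
#' standard deviation over replicas is reported as the spread.
#'
#' Shifting all old offsets by a constant C shifts `V_R` by -C and therefore
#' every extracted offset by exactly +C (the scheme is translation
#' covariant, so its fixed point is only defined up to the usual state-1
#' pinning); pairwise offset differences are invariant.
#'
#' @param traj_by_replica List of per-level [energy_trajectory()] objects
#'   (decreasing s).
#' @param undersampling_flags Logical vector: which replicas enter the
#'   average. Compute with [peoe_membership()] for the standard >= 0.9
#'   occurrence criterion.
#' @param thermo A [thermo_context()].
#' @return Object of class `peoe_result`: `offsets` (mean over replicas),
#'   `per_replica_offsets` (replicas x N matrix), `spread` (per-state sd),
#'   `included` (ladder indices used).
#' @export
peoe_estimate <- function(traj_by_replica, undersampling_flags,
                          thermo = thermo_context()) {
  stopifnot(length(undersampling_flags) == length(traj_by_replica))
  inc <- which(undersampling_flags)
  if (!length(inc)) stop("no undersampling replica to estimate offsets from")
  beta <- thermo$beta
  per <- t(vapply(traj_by_replica[inc], function(traj) {
    D <- traj_energy_matrix(traj) - traj$V_R   # frames x N of V_i - V_R
    apply(D, 2L, function(u) -logmeanexp(-beta * u) / beta)
  }, numeric(traj_n_states(traj_by_replica[[1L]]))))
  offsets <- colMeans(per)
  structure(
    list(offsets = offsets, per_replica_offsets = per,
         spread = apply(per, 2L, stats::sd), included = inc),
    class = "peoe_result"
  )
}

#' @export
print.peoe_result <- function(x, ...) {
  cat(sprintf("<peoe_result> averaged over %d undersampling replica(s)\n",
              length(x$included)))
  print(data.frame(state = seq_along(x$offsets),
                   offset = round(x$offsets, 3),
                   offset_vs_state1 = round(x$offsets - x$offsets[1L], 3),
                   spread = round(x$spread, 3)), row.names = FALSE)
  invisible(x)
}

#' @rdname peoe_estimate
#' @param thresholds A [threshold_set()].
#' @param config An [exploration_config()] (uses the 0.9 PEOE criterion).
#' @export
peoe_membership <- function(traj_by_replica, thresholds,
                            config = exploration_config()) {
  occ <- t(vapply(traj_by_replica, undersampling_occurrence,
                  numeric(traj_n_states(traj_by_replica[[1L]])),
                  thresholds = thresholds))
  apply(occ >= config$peoe_undersampling_min, 1L, all)
}

logmeanexp <- function(a) logsumexp(a) - log(length(a))

#' Run the full parameter-exploration stage
#'
#' Stage 2 of the workflow: (i) a short replica-exchange run over the
#' initial 21-level ladder with all offsets zero, from which the
#' undersampling thresholds and the ladder lower bound are determined;
#' (ii) per-state coordinate optimization with +/-500 kJ/mol bias offsets,
#' which also yields the physical-occurrence thresholds; (iii) a
#' replica-exchange run on the truncated ladder from which initial energy
#' offsets are estimated with the PEOE scheme (first
#' `discard_fraction` of frames discarded as equilibration).
#'
#' @param states List of end states.
#' @param thermo A [thermo_context()].
#' @param config An [exploration_config()].
#' @param n_steps_explore MC steps per replica for the lower-bound run.
#' @param n_steps_stateopt MC steps per state-optimization run.
#' @param n_steps_peoe MC steps per replica for the offset-estimation run.
#' @param start Starting configuration.
#' @param seed Integer seed.
#' @param start_mode `"SSM"` (replicas seeded with the per-state optimized
#'   coordinates, alternating) or `"1SS"` (all replicas share one start).
#' @return Object of class `exploration_result` with fields `lower_bound`,
#'   `thresholds`, `peoe` ([peoe_estimate()] result), `offsets`,
#'   `state_configurations`, `s_values` (truncated ladder), plus the
#'   underlying runs.
#' @export
explore_parameters <- function(states, thermo = thermo_context(),
                               config = exploration_config(),
                               n_steps_explore = 4000L,
                               n_steps_stateopt = 2000L,
                               n_steps_peoe = 6000L,
                               start = NULL, seed = 1L,
                               start_mode = c("SSM", "1SS")) {
  start_mode <- match.arg(start_mode)
  n <- length(states)
  d <- state_dimension(states[[1L]])
  if (is.null(start)) start <- rep(0, d)
  set.seed(seed)

  # (i) lower bound: initial ladder, zero offsets
  ens0 <- replica_ensemble(states, config$initial_s, offsets = rep(0, n),
                           configurations = start, thermo = thermo)
  run0 <- run_reeds(ens0, n_steps_explore)
  levels0 <- split_by_level(run0$trajectory)
  us_from_lowest <- apply(
    sweep(traj_energy_matrix(levels0[[length(levels0)]]), 2L, rep(0, n)),
    2L, stats::quantile, probs = config$threshold_quantile, names = FALSE)
  pre_thresholds <- threshold_set(rep(Inf, n), us_from_lowest)
  lb <- find_lower_bound(levels0, pre_thresholds, config)

  # (ii) state-coordinate optimization + physical thresholds
  so <- optimize_state_coordinates(states, thermo, config,
                                   n_steps = n_steps_stateopt, start = start)
  thresholds <- estimate_thresholds(so$trajectories,
                                    levels0[[length(levels0)]],
                                    q = config$threshold_quantile)

  # (iii) PEOE on the truncated ladder
  s_peoe <- log_s_ladder(config$peoe_n_replicas, lb$lower_bound)
  starts <- if (start_mode == "SSM") {
    do.call(cbind, lapply(seq_len(config$peoe_n_replicas), function(r) {
      so$configurations[[(r - 1L) %% n + 1L]]
    }))
  } else {
    matrix(start, nrow = d, ncol = config$peoe_n_replicas)
  }
  ens1 <- replica_ensemble(states, s_peoe, offsets = rep(0, n),
                           configurations = starts, thermo = thermo)
  run1 <- run_reeds(ens1, n_steps_peoe)
  levels1 <- split_by_level(discard_equilibration(run1$trajectory,
                                                  config$discard_fraction))
  member <- peoe_membership(levels1, thresholds, config)
  if (!any(member)) {
    warning("no replica met the strict occurrence criterion (>= ",
            config$peoe_undersampling_min, ") for offset estimation; ",
            "falling back to the lowest-s replica")
    member[length(member)] <- TRUE
  }
  peoe <- peoe_estimate(levels1, member, thermo)

  structure(
    list(lower_bound = lb$lower_bound, lower_bound_detail = lb,
         thresholds = thresholds, peoe = peoe, offsets = peoe$offsets,
         state_configurations = so$configurations,
         state_trajectories = so$trajectories,
         s_values = s_peoe, start_mode = start_mode,
         explore_run = run0, peoe_run = run1),
    class = "exploration_result"
  )
}

#' @export
print.exploration_result <- function(x, ...) {
  cat(sprintf("<exploration_result> lower bound s = %g (%s start)\n",
              x$lower_bound, x$start_mode))
  print(x$peoe)
  invisible(x)
}
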