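#' Replica ladders in s-space
#'
#' `s_distribution()` validates a replica ladder: a strictly decreasing
#' vector of smoothing parameters in (0, 1] whose first element is exactly
#' 1.0 — the physical replica from which free energies are finally
#' estimated. `log_s_ladder()` builds the standard logarithmically spaced
#' ladder between 1 and a lower bound (default 1e-5, 21 values, the usual
#' initial exploration ladder).
#'
#' @param s_values Numeric vector of smoothing parameters.
#' @return The validated numeric vector (class `s_distribution`).
#' @export
s_distribution <- function(s_values) {
  s <- as.numeric(s_values)
  if (length(s) < 1L || any(!is.finite(s)) || any(s <= 0) || any(s > 1))
    stop("s-values must be finite and in (0, 1]")
  if (s[1L] != 1)
    stop("the ladder must start at s = 1.0 (the physical replica)")
  if (length(s) > 1L && any(diff(s) >= 0))
    stop("s-values must be strictly decreasing")
  structure(s, class = "s_distribution")
}

#' @rdname s_distribution
#' @param n Number of replicas.
#' @param lower Smallest s-value.
#' @export
log_s_ladder <- function(n = 21L, lower = 1e-5) {
  stopifnot(n >= 1L, lower > 0, lower <= 1)
  if (n == 1L) return(s_distribution(1))
  s_distribution(exp(seq(0, log(lower), length.out = n)))
}

#' Replica ensemble
#'
#' Bundles everything a replica-exchange EDS run needs: the end states, the
#' thermodynamic context, the s-ladder, one shared offset vector (a single
#' set of energy offsets serves all replicas), and one starting
#' configuration per replica.
#'
#' @param states List of `end_state` objects.
#' @param s_values Ladder of smoothing parameters (see [s_distribution()]).
#' @param offsets Energy offsets `E^R` in kJ/mol (default all zero).
#' @param configurations Either one numeric configuration recycled to all
#'   replicas, or a d x M matrix / list with one configuration per replica.
#' @param thermo A [thermo_context()].
#' @return An object of class `replica_ensemble`.
#' @export
replica_ensemble <- function(states, s_values, offsets = NULL,
                             configurations = NULL,
                             thermo = thermo_context()) {
  s <- s_distribution(s_values)
  n <- length(states)
  d <- state_dimension(states[[1L]])
  m <- length(s)
  if (is.null(offsets)) offsets <- rep(0, n)
  stopifnot(length(offsets) == n, all(is.finite(offsets)))
  X <- configurations
  if (is.null(X)) X <- rep(0, d)
  if (is.list(X)) X <- do.call(cbind, X)
  if (is.null(dim(X))) X <- matrix(X, nrow = d, ncol = m)
  stopifnot(nrow(X) == d, ncol(X) == m, all(is.finite(X)))
  structure(
    list(states = states, thermo = thermo, s = as.numeric(s),
         offsets = as.numeric(offsets), configurations = X,
         n_states = n, n_replicas = m, dimension = d),
    class = "replica_ensemble"
  )
}

default_step_size <- function(states, thermo) {
  ks <- unlist(lapply(states, function(st) if (!is.null(st$k)) st$k else NULL))
  if (is.null(ks)) return(0.05)
  sqrt(1 / (thermo$beta * mean(ks)))
}

# Vectorised Metropolis block: advances M walkers (one per ladder level, each
# under its own s) by n_steps Gaussian-proposal MC steps. Exactly canonical
# for the EDS reference potential at each level.
mc_block <- function(states, X, s, offsets, beta, n_steps, step_sd,
                     V = NULL, VR = NULL) {
  d <- nrow(X); m <- ncol(X)
  if (is.null(V)) V <- system_energy_matrix(states, X)
  if (is.null(VR)) VR <- eds_energy_from_matrix(V, s, offsets, beta)
  if (any(!is.finite(VR)))
    stop("non-finite reference energy at block start (replica ",
         which(!is.finite(VR))[1L], ")")
  n_acc <- 0L
  for (t in seq_len(n_steps)) {
    Xp <- X + matrix(stats::rnorm(d * m, sd = step_sd), d, m)
    Vp <- system_energy_matrix(states, Xp)
    VRp <- eds_energy_from_matrix(Vp, s, offsets, beta)
    if (any(is.nan(VRp)))
      stop("energy diverged at MC step ", t, " (replica ",
           which(is.nan(VRp))[1L], ")")
    acc <- log(stats::runif(m)) < -beta * (VRp - VR)
    if (any(acc)) {
      X[, acc] <- Xp[, acc]
      V[, acc] <- Vp[, acc]
      VR[acc] <- VRp[acc]
      n_acc <- n_acc + sum(acc)
    }
  }
  list(X = X, V = V, VR = VR, acceptance = n_acc / max(1, n_steps * m))
}

#' Canonical Monte Carlo propagation of one EDS reference state
#'
#' Samples the canonical ensemble of [eds_energy()] at the reference state's
#' temperature with a Metropolis random walk (Gaussian proposals). Exact for
#' any proposal width; the default width is matched to the Boltzmann width
#' of the toy wells. With `n_steps = 0` the configuration is returned
#' unchanged.
#'
#' @param ref A [reference_state()].
#' @param conf Starting configuration (numeric vector).
#' @param n_steps Number of MC steps.
#' @param step_size Proposal standard deviation (nm); `NULL` for automatic.
#' @param store_interval Store one frame every this many steps.
#' @param seed Optional integer seed (same seed, same trajectory).
#' @return List with `conf` (final configuration), `trajectory` (an
#'   [energy_trajectory()]), and `acceptance` (fraction of accepted moves).
#' @export
propagate <- function(ref, conf, n_steps, step_size = NULL,
                      store_interval = 20L, seed = NULL) {
  stopifnot(inherits(ref, "reference_state"), n_steps >= 0L)
  conf <- check_conf(ref, conf)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(step_size)) step_size <- default_step_size(ref$states, ref$thermo)
  X <- matrix(conf, ncol = 1L)
  beta <- ref$thermo$beta
  n_blocks <- n_steps %/% store_interval
  rem <- n_steps %% store_interval
  frames <- vector("list", n_blocks + (rem > 0L))
  state <- list(X = X, V = NULL, VR = NULL)
  acc <- numeric(0)
  blens <- c(rep(store_interval, n_blocks), if (rem > 0L) rem)
  tnow <- 0L
  for (b in seq_along(blens)) {
    state <- mc_block(ref$states, state$X, ref$s, ref$offsets, beta,
                      blens[b], step_size, state$V, state$VR)
    tnow <- tnow + blens[b]
    acc <- c(acc, state$acceptance)
    frames[[b]] <- c(time = tnow, replica = 1, s = ref$s, V_R = state$VR,
                     stats::setNames(as.numeric(state$V),
                                     paste0("V_", seq_len(ref$n_states))))
  }
  fr <- if (length(frames)) {
    as.data.frame(do.call(rbind, frames))
  } else {
    cols <- c("time", "replica", "s", "V_R", paste0("V_", seq_len(ref$n_states)))
    as.data.frame(matrix(numeric(0), 0L, length(cols),
                         dimnames = list(NULL, cols)))
  }
  traj <- energy_trajectory(fr, offsets = ref$offsets)
  list(conf = as.numeric(state$X), trajectory = traj,
       acceptance = if (length(acc)) mean(acc) else NA_real_)
}

#' Replica-exchange acceptance probability
#'
#' Metropolis-Hastings criterion for swapping the configurations of two
#' replicas that share end states, offsets and temperature but differ in s:
#' \deqn{p_{k,l} = \min\!\big(1, e^{-\beta[(H_R(r_k;s_l)+H_R(r_l;s_k)) -
#'   (H_R(r_l;s_l)+H_R(r_k;s_k))]}\big).}
#' Identical s-values give p = 1, and the expression is symmetric under
#' swapping the two replicas.
#'
#' @param ref_k,ref_l Reference states of the two replicas (must differ only
#'   in s).
#' @param conf_k,conf_l Current configurations of the two replicas.
#' @return Acceptance probability in \[0, 1\].
#' @export
exchange_probability <- function(ref_k, ref_l, conf_k, conf_l) {
  if (!isTRUE(all.equal(ref_k$offsets, ref_l$offsets)) ||
      ref_k$thermo$beta != ref_l$thermo$beta)
    stop("replicas must differ only in the smoothing parameter s")
  beta <- ref_k$thermo$beta
  delta <- (eds_energy(with_s(ref_k, ref_l$s), conf_k) +
              eds_energy(with_s(ref_l, ref_k$s), conf_l)) -
    (eds_energy(ref_l, conf_l) + eds_energy(ref_k, conf_k))
  min(1, exp(-beta * delta))
}

#' Run a replica-exchange EDS simulation
#'
#' Alternates vectorised Monte Carlo propagation of all ladder levels with
#' neighbour-exchange sweeps (even/odd pairs on alternating attempts).
#' Accepted exchanges swap the two configurations between s-levels; replica
#' identities are tracked across the ladder so round trips (top -> bottom ->
#' top per replica) can be counted. Energies of every end state are recorded
#' for every level at every exchange interval — the energy trajectory that
#' all downstream analyses consume.
#'
#' @param ensemble A [replica_ensemble()].
#' @param n_steps MC steps per replica.
#' @param exchange_interval Steps between exchange attempts (default 20).
#' @param step_size Proposal width; `NULL` for automatic.
#' @param seed Optional integer seed.
#' @param record_coordinates Keep the configurations of every stored frame
#'   (a d x n_levels x n_sweeps array under `coordinates`); off by default.
#' @return An object of class `reeds_run`: list with `trajectory`
#'   ([energy_trajectory()] covering all levels), `exchanges` (data frame
#'   `step, i, j, p, accepted, mc_i, mc_j`), `round_trips`
#'   ([count_round_trips()] result), `positions` (time x replica ladder-index
#'   matrix), `ensemble` (final state, configurations updated), and
#'   `acceptance` (MC move acceptance).
#' @export
run_reeds <- function(ensemble, n_steps, exchange_interval = 20L,
                      step_size = NULL, seed = NULL,
                      record_coordinates = FALSE) {
  stopifnot(inherits(ensemble, "replica_ensemble"),
            n_steps >= 1L, exchange_interval >= 1L)
  if (!is.null(seed)) set.seed(seed)
  th <- ensemble$thermo
  beta <- th$beta
  s <- ensemble$s
  m <- ensemble$n_replicas
  nst <- ensemble$n_states
  offsets <- ensemble$offsets
  if (is.null(step_size)) step_size <- default_step_size(ensemble$states, th)

  n_sweeps <- max(1L, n_steps %/% exchange_interval)
  X <- ensemble$configurations
  V <- system_energy_matrix(ensemble$states, X)
  VR <- eds_energy_from_matrix(V, s, offsets, beta)
  replica_at_level <- seq_len(m)

  frame_list <- vector("list", n_sweeps)
  ex_list <- vector("list", n_sweeps)
  positions <- matrix(NA_integer_, n_sweeps, m)
  acc_mc <- numeric(n_sweeps)
  coords <- if (record_coordinates)
    array(NA_real_, c(ensemble$dimension, m, n_sweeps)) else NULL

  for (sw in seq_len(n_sweeps)) {
    blk <- mc_block(ensemble$states, X, s, offsets, beta,
                    exchange_interval, step_size, V, VR)
    X <- blk$X; V <- blk$V; VR <- blk$VR
    acc_mc[sw] <- blk$acceptance
    tnow <- sw * exchange_interval

    frame_list[[sw]] <- cbind(time = tnow, replica = replica_at_level,
                              s = s, V_R = VR, t(V))
    if (record_coordinates) coords[, , sw] <- X

    if (m >= 2L) {
      first <- if (sw %% 2L == 1L) 1L else 2L
      pairs <- if (first <= m - 1L) seq(first, m - 1L, by = 2L) else integer(0)
      if (length(pairs)) {
        mc_state <- max.col(t(-(V - offsets)), ties.method = "first")
        recs <- matrix(NA_real_, length(pairs), 7L)
        for (pi in seq_along(pairs)) {
          k <- pairs[pi]; l <- k + 1L
          cross <- eds_energy_from_matrix(V[, c(k, l), drop = FALSE],
                                          c(s[l], s[k]), offsets, beta)
          delta <- (cross[1L] + cross[2L]) - (VR[k] + VR[l])
          p <- min(1, exp(-beta * delta))
          accepted <- stats::runif(1) < p
          recs[pi, ] <- c(tnow, k, l, p, accepted, mc_state[k], mc_state[l])
          if (accepted) {
            X[, c(k, l)] <- X[, c(l, k)]
            V[, c(k, l)] <- V[, c(l, k)]
            VR[c(k, l)] <- cross[c(2L, 1L)]
            replica_at_level[c(k, l)] <- replica_at_level[c(l, k)]
          }
        }
        ex_list[[sw]] <- recs
      }
    }
    positions[sw, replica_at_level] <- seq_len(m)
  }

  fr <- as.data.frame(do.call(rbind, frame_list))
  names(fr) <- c("time", "replica", "s", "V_R", paste0("V_", seq_len(nst)))
  traj <- energy_trajectory(fr, offsets = offsets)

  ex <- do.call(rbind, ex_list)
  exchanges <- if (is.null(ex)) {
    data.frame(step = numeric(0), i = integer(0), j = integer(0),
               p = numeric(0), accepted = logical(0),
               mc_i = integer(0), mc_j = integer(0))
  } else {
    data.frame(step = ex[, 1L], i = as.integer(ex[, 2L]),
               j = as.integer(ex[, 3L]), p = ex[, 4L],
               accepted = as.logical(ex[, 5L]),
               mc_i = as.integer(ex[, 6L]), mc_j = as.integer(ex[, 7L]))
  }

  rt <- count_round_trips(positions,
                          times = seq_len(n_sweeps) * exchange_interval)
  ensemble$configurations <- X
  structure(
    list(trajectory = traj, exchanges = exchanges, round_trips = rt,
         positions = positions, ensemble = ensemble, coordinates = coords,
         acceptance = mean(acc_mc), exchange_interval = exchange_interval,
         n_steps = n_sweeps * exchange_interval),
    class = "reeds_run"
  )
}

#' @export
print.reeds_run <- function(x, ...) {
  cat(sprintf("<reeds_run> %d replicas x %d steps, exchange every %d\n",
              ncol(x$positions), x$n_steps, x$exchange_interval))
  cat(sprintf("  MC acceptance %.2f, exchange acceptance %.2f, round trips %d\n",
              x$acceptance,
              if (nrow(x$exchanges)) mean(x$exchanges$accepted) else NA,
              x$round_trips$n_round_trips))
  invisible(x)
}

#' Count replica round trips
#'
#' A round trip is one replica's traversal from the top of the ladder
#' (s = 1, level 1) to the bottom level and back to the top. Counting is a
#' deterministic state machine per replica over its ladder-index time
#' series; the mean round-trip time is averaged over all completed trips of
#' all replicas and reported as `NA` when no trip completed.
#'
#' @param positions Time x replica matrix of ladder indices (1 = top).
#' @param times Optional time stamps per row (defaults to row numbers).
#' @param bottom Ladder index of the bottom level (defaults to the maximum
#'   observed).
#' @return List of class `round_trip_stats`: `n_round_trips`,
#'   `mean_round_trip_time`, `durations`, `per_replica_positions`.
#' @export
count_round_trips <- function(positions, times = NULL, bottom = NULL) {
  positions <- as.matrix(positions)
  if (is.null(times)) times <- seq_len(nrow(positions))
  if (is.null(bottom)) bottom <- max(positions, 1L)
  durations <- numeric(0)
  n_rt <- 0L
  if (bottom > 1L && nrow(positions) > 0L) {
    for (r in seq_len(ncol(positions))) {
      phase <- 0L  # 0: waiting for top; 1: seen top; 2: seen top then bottom
      start <- NA_real_
      for (t in seq_len(nrow(positions))) {
        pos <- positions[t, r]
        if (pos == 1L) {
          if (phase == 2L) {
            n_rt <- n_rt + 1L
            durations <- c(durations, times[t] - start)
          }
          phase <- 1L
          start <- times[t]
        } else if (pos == bottom && phase == 1L) {
          phase <- 2L
        }
      }
    }
  }
  structure(
    list(n_round_trips = n_rt,
         mean_round_trip_time = if (n_rt > 0L) mean(durations) else NA_real_,
         durations = durations, per_replica_positions = positions),
    class = "round_trip_stats"
  )
}

#' @export
print.round_trip_stats <- function(x, ...) {
  cat(sprintf("<round_trip_stats> nRT = %d, mean time = %s\n",
              x$n_round_trips,
              if (is.na(x$mean_round_trip_time)) "NA"
              else format(x$mean_round_trip_time)))
  invisible(x)
}

#' Overdamped Langevin propagation (optional integrator)
#'
#' Euler-Maruyama integration of overdamped Langevin dynamics on the EDS
#' reference potential, for users who want an MD-like propagator. Unlike the
#' Metropolis default it carries a finite-timestep discretisation bias, so
#' the exactness-sensitive pipeline stages use [propagate()] instead.
#'
#' @param ref A [reference_state()].
#' @param conf Starting configuration.
#' @param n_steps Number of integration steps.
#' @param dt Time step (arbitrary units).
#' @param diffusion Diffusion coefficient.
#' @param seed Optional integer seed.
#' @return List with `conf` and a matrix `path` of visited configurations.
#' @export
propagate_langevin <- function(ref, conf, n_steps, dt = 1e-4, diffusion = 1,
                               seed = NULL) {
  stopifnot(inherits(ref, "reference_state"), n_steps >= 0L, dt > 0)
  conf <- check_conf(ref, conf)
  if (!is.null(seed)) set.seed(seed)
  beta <- ref$thermo$beta
  d <- length(conf)
  path <- matrix(NA_real_, n_steps, d)
  sig <- sqrt(2 * diffusion * dt)
  for (t in seq_len(n_steps)) {
    f <- eds_forces(ref, conf)
    conf <- conf + diffusion * beta * f * dt + stats::rnorm(d, sd = sig)
    if (!all(is.finite(conf))) stop("Langevin integration diverged at step ", t)
    path[t, ] <- conf
  }
  list(conf = conf, path = path)
}
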