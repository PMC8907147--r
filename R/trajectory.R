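#' Energy trajectories
#'
#' The universal currency between pipeline stages: one row per stored frame
#' with the time stamp (MC steps), the replica identity occupying the ladder
#' level, the level's smoothing parameter s, the reference-state energy
#' `V_R`, and every end-state energy `V_1 .. V_N` (all kJ/mol). The offsets
#' in force when the frames were produced are carried as an attribute, so
#' `V_R` can always be recomputed from the stored end-state energies.
#'
#' @param frames Data frame with columns `time`, `replica`, `s`, `V_R`,
#'   `V_1` ... `V_N`.
#' @param offsets Offset vector used during production.
#' @return The data frame with class `energy_trajectory` and attribute
#'   `offsets`.
#' @export
energy_trajectory <- function(frames, offsets) {
  frames <- as.data.frame(frames)
  need <- c("time", "replica", "s", "V_R")
  if (!all(need %in% names(frames)))
    stop("trajectory needs columns ", paste(need, collapse = ", "))
  vcols <- grep("^V_[0-9]+$", names(frames), value = TRUE)
  n <- length(vcols)
  if (n < 1L) stop("trajectory needs at least one V_i column")
  if (length(offsets) != n)
    stop("offset vector length ", length(offsets),
         " does not match ", n, " states in trajectory")
  attr(frames, "offsets") <- as.numeric(offsets)
  class(frames) <- c("energy_trajectory", "data.frame")
  frames
}

traj_offsets <- function(traj) attr(traj, "offsets")

traj_n_states <- function(traj) {
  sum(grepl("^V_[0-9]+$", names(traj)))
}

# frames x N matrix of end-state energies
traj_energy_matrix <- function(traj) {
  as.matrix(traj[, paste0("V_", seq_len(traj_n_states(traj))), drop = FALSE])
}

#' Split a run's trajectory by ladder level
#'
#' @param traj An [energy_trajectory()].
#' @return Named list of trajectories, one per distinct s-value, ordered by
#'   decreasing s.
#' @export
split_by_level <- function(traj) {
  svals <- sort(unique(traj$s), decreasing = TRUE)
  out <- lapply(svals, function(sv) {
    energy_trajectory(traj[traj$s == sv, , drop = FALSE], traj_offsets(traj))
  })
  names(out) <- format(svals)
  out
}

#' Extract the physical (s = 1) frames of a run
#'
#' @param run A `reeds_run` or an [energy_trajectory()].
#' @return An [energy_trajectory()] restricted to s = 1.
#' @export
physical_trajectory <- function(run) {
  traj <- if (inherits(run, "reeds_run")) run$trajectory else run
  stopifnot(inherits(traj, "energy_trajectory"))
  energy_trajectory(traj[traj$s == 1, , drop = FALSE], traj_offsets(traj))
}

#' Verify the internal consistency of a trajectory
#'
#' Recomputes `V_R` from the stored end-state energies, s-values and offsets
#' and reports the largest absolute deviation from the stored `V_R`.
#'
#' @param traj An [energy_trajectory()].
#' @param thermo A [thermo_context()].
#' @return Largest absolute `V_R` reconstruction error in kJ/mol.
#' @export
verify_trajectory <- function(traj, thermo = thermo_context()) {
  V <- t(traj_energy_matrix(traj))
  vr <- eds_energy_from_matrix(V, traj$s, traj_offsets(traj), thermo$beta)
  max(abs(vr - traj$V_R))
}

#' Discard an initial equilibration fraction
#'
#' @param traj An [energy_trajectory()].
#' @param fraction Fraction of the earliest frames (by time) to drop.
#' @return The truncated trajectory.
#' @export
discard_equilibration <- function(traj, fraction = 0.25) {
  stopifnot(fraction >= 0, fraction < 1)
  if (fraction == 0) return(traj)
  tcut <- stats::quantile(unique(traj$time), fraction, names = FALSE)
  energy_trajectory(traj[traj$time > tcut, , drop = FALSE],
                    traj_offsets(traj))
}
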