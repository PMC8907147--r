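#' Sampling diagnostics for RE-EDS trajectories
#'
#' Three per-state metrics quantify how well a reference-state simulation
#' covers its end states:
#'
#' * `max_contributing_fractions()` — the fraction of frames in which state
#'   i is the *maximally contributing* state, i.e. has the lowest
#'   `V_i - E_i^R`. Exactly one state wins each frame (ties go to the lowest
#'   state index, a documented deterministic tie-break), so the fractions
#'   sum to one. Ideal sampling is `f_i^mc = 1/N` for every state.
#' * `occurrence_fractions()` — the fraction of frames in which state i is
#'   "physically occurring", `V_i <= T_i^phys`. Several states can occur in
#'   the same frame when their phase spaces overlap; with no overlap the
#'   occurrence fractions nearly coincide with the maximal-contribution
#'   fractions.
#' * `undersampling_frames()` — a frame is in undersampling when *every*
#'   state satisfies `V_i - E_i^R <= T_i^us`; the regime at small s where
#'   all end states contribute simultaneously.
#'
#' @param traj An [energy_trajectory()].
#' @param offsets Offset vector `E^R`; defaults to the trajectory's own.
#' @param thresholds A [threshold_set()].
#' @return `max_contributing_fractions` and `occurrence_fractions`: numeric
#'   vector of length N. `undersampling_frames`: list with `fraction` and
#'   logical `flags` per frame.
#' @export
max_contributing_fractions <- function(traj, offsets = NULL) {
  if (nrow(traj) == 0L) stop("empty trajectory")
  if (is.null(offsets)) offsets <- traj_offsets(traj)
  U <- t(traj_energy_matrix(traj)) - offsets   # N x frames
  idx <- max.col(t(-U), ties.method = "first")
  tabulate(idx, nbins = nrow(U)) / length(idx)
}

#' @rdname max_contributing_fractions
#' @export
occurrence_fractions <- function(traj, thresholds) {
  if (nrow(traj) == 0L) stop("empty trajectory")
  tp <- thresholds$physical
  V <- traj_energy_matrix(traj)
  if (length(tp) != ncol(V)) stop("need one physical threshold per state")
  unname(colMeans(V <= rep(tp, each = nrow(V))))
}

#' @rdname max_contributing_fractions
#' @export
undersampling_frames <- function(traj, thresholds, offsets = NULL) {
  if (nrow(traj) == 0L) stop("empty trajectory")
  if (is.null(offsets)) offsets <- traj_offsets(traj)
  tu <- thresholds$undersampling
  V <- traj_energy_matrix(traj)
  n <- ncol(V)
  if (length(tu) != n) stop("need one undersampling threshold per state")
  ok <- sweep(V, 2L, offsets) <= rep(tu, each = nrow(V))
  flags <- unname(rowSums(ok) == n)
  list(fraction = mean(flags), flags = flags)
}

# occurrence against the undersampling thresholds on V_i - E_i; the
# criterion behind lower-bound detection and PEOE replica selection
undersampling_occurrence <- function(traj, thresholds, offsets = NULL) {
  if (is.null(offsets)) offsets <- traj_offsets(traj)
  tu <- thresholds$undersampling
  V <- traj_energy_matrix(traj)
  colMeans(sweep(V, 2L, offsets) <= rep(tu, each = nrow(V)))
}

#' Threshold set for occurrence and undersampling detection
#'
#' @param physical Per-state physical-occurrence thresholds `T_i^phys`
#'   (kJ/mol, on raw `V_i`).
#' @param undersampling Per-state undersampling thresholds `T_i^us` (kJ/mol,
#'   on `V_i - E_i^R`).
#' @return Object of class `threshold_set`.
#' @export
threshold_set <- function(physical, undersampling) {
  stopifnot(length(physical) == length(undersampling),
            all(is.finite(undersampling)))
  structure(list(physical = as.numeric(physical),
                 undersampling = as.numeric(undersampling)),
            class = "threshold_set")
}

#' Estimate occurrence and undersampling thresholds
#'
#' `T_i^phys` is taken as an empirical quantile (default 0.95) of `V_i` over
#' the frames of state i's own biased exploration run in which i is the
#' maximal contributor; `T_i^us` is the same quantile of `V_i - E_i` in the
#' trajectory of the lowest-s replica. The quantile estimator is a package
#' choice — the underlying workflow only prescribes *that* thresholds are
#' estimated from these two runs, not how.
#'
#' @param per_state_trajs List of N [energy_trajectory()] objects, the i-th
#'   from the run biased towards state i.
#' @param lowest_s_traj Trajectory of the lowest-s replica of the
#'   exploration run.
#' @param q Quantile (default 0.95).
#' @return A [threshold_set()].
#' @export
estimate_thresholds <- function(per_state_trajs, lowest_s_traj, q = 0.95) {
  n <- length(per_state_trajs)
  stopifnot(n >= 1L, traj_n_states(lowest_s_traj) == n)
  phys <- vapply(seq_len(n), function(i) {
    traj <- per_state_trajs[[i]]
    U <- t(traj_energy_matrix(traj)) - traj_offsets(traj)
    own <- max.col(t(-U), ties.method = "first") == i
    if (!any(own))
      stop("state ", i, " is never the maximal contributor in its own ",
           "biased run; state optimization failed")
    stats::quantile(traj_energy_matrix(traj)[own, i], q, names = FALSE)
  }, numeric(1))
  Vus <- sweep(traj_energy_matrix(lowest_s_traj), 2L,
               traj_offsets(lowest_s_traj))
  us <- apply(Vus, 2L, stats::quantile, probs = q, names = FALSE)
  threshold_set(phys, us)
}

#' Per-state sampling report
#'
#' Combines the three diagnostics for one trajectory (usually the s = 1
#' replica) into a single report.
#'
#' @param traj An [energy_trajectory()].
#' @param thresholds Optional [threshold_set()]; without it the occurrence
#'   and undersampling entries are `NA`.
#' @param offsets Offsets to use; defaults to the trajectory's own.
#' @return Object of class `sampling_report`: `f_mc`, `f_occur`,
#'   `undersampling_fraction`, `ideal_fraction` (= 1/N), `n_frames`.
#' @export
sampling_report <- function(traj, thresholds = NULL, offsets = NULL) {
  n <- traj_n_states(traj)
  f_mc <- max_contributing_fractions(traj, offsets)
  f_occur <- rep(NA_real_, n)
  us <- NA_real_
  if (!is.null(thresholds)) {
    f_occur <- occurrence_fractions(traj, thresholds)
    us <- undersampling_frames(traj, thresholds, offsets)$fraction
  }
  structure(
    list(f_mc = f_mc, f_occur = f_occur, undersampling_fraction = us,
         ideal_fraction = 1 / n, n_frames = nrow(traj)),
    class = "sampling_report"
  )
}

#' @export
print.sampling_report <- function(x, ...) {
  cat(sprintf("<sampling_report> %d frames, ideal f_mc = %.3f\n",
              x$n_frames, x$ideal_fraction))
  print(data.frame(state = seq_along(x$f_mc), f_mc = round(x$f_mc, 4),
                   f_occur = round(x$f_occur, 4)), row.names = FALSE)
  if (!is.na(x$undersampling_fraction))
    cat(sprintf("undersampling fraction: %.3f\n", x$undersampling_fraction))
  invisible(x)
}
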