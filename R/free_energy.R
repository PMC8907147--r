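#' Multistate Zwanzig free-energy estimation
#'
#' Applies the Zwanzig (exponential-averaging) formula twice through the
#' sampled reference state: for each end state i the log-average weight
#' \deqn{L_i = \ln\big\langle e^{-\beta (V_i - V_R)}\big\rangle_R}
#' is computed with a log-mean-exp over the retained frames of the s = 1
#' replica, and every pairwise difference follows from one pass,
#' \deqn{\Delta G_{ji} = -\tfrac{1}{\beta}(L_j - L_i).}
#' Because all pairs derive from the single vector L, the matrix is exactly
#' antisymmetric and every thermodynamic cycle closes to machine precision
#' by construction.
#'
#' Uncertainties are per-state Gaussian (first-order) propagation of the
#' blocked standard error of the exponential average (see
#' [gaussian_uncertainty()]); the pairwise uncertainty is
#' `sqrt(sigma_Lj^2 + sigma_Li^2) / beta`. A state whose weights vanish
#' numerically on every frame yields an infinite uncertainty and a warning.
#'
#' @param traj [energy_trajectory()] of the s = 1 replica.
#' @param thermo A [thermo_context()].
#' @param discard_fraction Initial fraction of frames dropped (default 0;
#'   the parameter stages already equilibrate the system).
#' @param n_blocks Blocks for the blocked standard error (default 10).
#' @param environment_label Free-text label (e.g. "water", "complex").
#' @return Object of class `free_energy_result`: `dG` (N x N matrix, entry
#'   \[j, i\] = dG_ji in kJ/mol), `uncertainty` (N x N), `logL` (the L
#'   vector), `n_frames_used`, `environment_label`.
#' @export
zwanzig_multistate <- function(traj, thermo = thermo_context(),
                               discard_fraction = 0, n_blocks = 10L,
                               environment_label = "toy") {
  stopifnot(inherits(traj, "energy_trajectory"))
  if (any(traj$s != 1))
    stop("free energies must be estimated from the s = 1 replica; ",
         "use physical_trajectory() first")
  traj <- discard_equilibration(traj, discard_fraction)
  if (nrow(traj) < 2L) stop("need at least two retained frames")
  beta <- thermo$beta
  A <- -beta * (traj_energy_matrix(traj) - traj$V_R)  # frames x N log-weights
  L <- apply(A, 2L, logmeanexp)
  sigma_L <- vapply(seq_len(ncol(A)), function(i) {
    blocked_log_sem(A[, i], n_blocks)
  }, numeric(1))
  if (any(!is.finite(L))) {
    warning("state(s) ", paste(which(!is.finite(L)), collapse = ", "),
            " carry numerically zero weight on every frame; ",
            "their uncertainties are infinite")
    sigma_L[!is.finite(L)] <- Inf
  }
  dG <- outer(L, L, function(a, b) -(a - b) / beta)
  unc <- sqrt(outer(sigma_L^2, sigma_L^2, `+`)) / beta
  diag(unc) <- 0
  n <- length(L)
  labels <- paste0("S", seq_len(n))
  dimnames(dG) <- dimnames(unc) <- list(labels, labels)
  structure(
    list(dG = dG, uncertainty = unc, logL = L, n_frames_used = nrow(traj),
         environment_label = environment_label),
    class = "free_energy_result"
  )
}

#' @export
print.free_energy_result <- function(x, ...) {
  cat(sprintf("<free_energy_result> '%s', %d frames\n",
              x$environment_label, x$n_frames_used))
  cat("dG_ji [kJ/mol] (row j, column i):\n")
  print(round(x$dG, 3))
  invisible(x)
}

# Blocked standard error of ln<w> from log-weights a = ln w: relative block
# means r_b = exp(logmeanexp(block) - logmeanexp(all)) are O(1), so
# SEM(w)/mean(w) = sd(r_b)/sqrt(B) stays stable however extreme the weights.
blocked_log_sem <- function(a, n_blocks = 10L) {
  n <- length(a)
  if (n < n_blocks) {
    warning("fewer frames (", n, ") than blocks (", n_blocks,
            "); falling back to a single block (no uncertainty estimate)")
    return(NA_real_)
  }
  Lall <- logmeanexp(a)
  if (!is.finite(Lall)) return(Inf)
  idx <- split(seq_len(n), cut(seq_len(n), n_blocks, labels = FALSE))
  r <- vapply(idx, function(ii) exp(logmeanexp(a[ii]) - Lall), numeric(1))
  stats::sd(r) / sqrt(length(r))
}

#' Gaussian uncertainty of one pairwise free-energy difference
#'
#' First-order ("Gaussian") error propagation through the two exponential
#' averages of the double-Zwanzig estimate: the standard error of each
#' `ln<w_i>` is estimated as `SEM(w)/mean(w)` from `n_blocks` consecutive
#' blocks (a blocked standard error, so autocorrelation within the
#' trajectory inflates the estimate as it should), computed entirely in log
#' space.
#'
#' @param traj [energy_trajectory()] of the s = 1 replica.
#' @param j,i State indices of the pair (result refers to `dG_ji`).
#' @param thermo A [thermo_context()].
#' @param n_blocks Number of blocks (default 10).
#' @return Standard error of `dG_ji` in kJ/mol.
#' @export
gaussian_uncertainty <- function(traj, j, i, thermo = thermo_context(),
                                 n_blocks = 10L) {
  beta <- thermo$beta
  A <- -beta * (traj_energy_matrix(traj) - traj$V_R)
  sj <- blocked_log_sem(A[, j], n_blocks)
  si <- blocked_log_sem(A[, i], n_blocks)
  sqrt(sj^2 + si^2) / beta
}

#' Combine two environments into relative binding free energies
#'
#' Element-wise difference of the pairwise free-energy matrices of two
#' environments,
#' \deqn{\Delta\Delta G^{bind}_{ji} = \Delta G_{ji}^{complex} -
#'   \Delta G_{ji}^{water},}
#' with uncertainties added in quadrature. When a reference matrix (e.g.
#' experimental values) is supplied, summary statistics are computed over
#' all N(N-1) ordered pairs: RMSE (with a 100-fold bootstrap over pairs for
#' its uncertainty), MAE with the standard deviation of the absolute
#' errors, and the Spearman rank correlation.
#'
#' @param water `free_energy_result` for the first environment (subtracted).
#' @param complex `free_energy_result` for the second environment.
#' @param reference_ddG Optional N x N reference matrix.
#' @param n_boot Bootstrap resamples for the RMSE uncertainty.
#' @return Object of class `relative_binding_result`: `ddG`, `uncertainty`,
#'   and (given a reference) `rmse`, `rmse_sd`, `mae`, `mae_sd`, `spearman`.
#' @export
combine_environments <- function(water, complex, reference_ddG = NULL,
                                 n_boot = 100L) {
  stopifnot(inherits(water, "free_energy_result"),
            inherits(complex, "free_energy_result"))
  if (!identical(dimnames(water$dG), dimnames(complex$dG)))
    stop("state labels of the two environments do not match")
  ddG <- complex$dG - water$dG
  unc <- sqrt(complex$uncertainty^2 + water$uncertainty^2)
  out <- list(ddG = ddG, uncertainty = unc)
  if (!is.null(reference_ddG)) {
    stopifnot(all(dim(reference_ddG) == dim(ddG)))
    off <- which(row(ddG) != col(ddG))
    err <- ddG[off] - reference_ddG[off]
    boot <- vapply(seq_len(n_boot), function(b) {
      e <- err[sample.int(length(err), replace = TRUE)]
      sqrt(mean(e^2))
    }, numeric(1))
    out$rmse <- sqrt(mean(err^2))
    out$rmse_sd <- stats::sd(boot)
    out$mae <- mean(abs(err))
    out$mae_sd <- stats::sd(abs(err))
    out$spearman <- stats::cor(ddG[off], reference_ddG[off],
                               method = "spearman")
  }
  structure(out, class = "relative_binding_result")
}

#' @export
print.relative_binding_result <- function(x, ...) {
  cat("<relative_binding_result> ddG [kJ/mol]:\n")
  print(round(x$ddG, 3))
  if (!is.null(x$rmse))
    cat(sprintf("RMSE %.2f +/- %.2f, MAE %.2f +/- %.2f, Spearman %.2f\n",
                x$rmse, x$rmse_sd, x$mae, x$mae_sd, x$spearman))
  invisible(x)
}

#' Anchored absolute free energies
#'
#' Converts a relative matrix into per-state absolute values using one or
#' more experimental anchor values: for anchor state a,
#' `G_i = anchor_a + dG_ia`; with several anchors all choices are evaluated
#' and the per-state mean and standard deviation over the anchor choices is
#' reported, so no single anchor biases the ranking.
#'
#' @param dG N x N relative matrix (entry \[j, i\] = value of j minus i);
#'   either pairwise `dG` or `ddG`.
#' @param anchors Named or positional numeric vector of anchor values
#'   (kJ/mol); `NA` entries mark states without an anchor.
#' @return Data frame with `state`, `G` (mean over anchors), `sd`.
#' @export
anchored_absolute <- function(dG, anchors) {
  n <- nrow(dG)
  stopifnot(ncol(dG) == n, length(anchors) == n)
  usable <- which(is.finite(anchors))
  if (!length(usable)) stop("need at least one anchor value")
  per <- vapply(usable, function(a) anchors[a] + dG[, a], numeric(n))
  data.frame(
    state = seq_len(n),
    G = rowMeans(per),
    sd = if (length(usable) > 1L) apply(per, 1L, stats::sd) else rep(0, n)
  )
}
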