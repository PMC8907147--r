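#' End-state potentials
#'
#' An end state is one physical system (in the alchemical setting: one ligand
#' active, all others dummy) described by a potential-energy function
#' `V_i(r)` in kJ/mol over configurations `r`. Configurations are plain
#' numeric vectors (nm for molecular toys, or dimensionless); all coordinates
#' must be finite.
#'
#' `end_state()` builds a generic end state from an energy closure and an
#' optional analytic gradient; when no gradient is supplied, central finite
#' differences with step 1e-6 are used (documented fallback, slower).
#' Specialised constructors with analytic gradients and vectorised batch
#' evaluation live in the toy-system module ([harmonic_state()],
#' [polywell_state()]).
#'
#' @param energy_fn Function mapping a numeric coordinate vector to a single
#'   finite energy in kJ/mol.
#' @param gradient_fn Optional function returning the energy gradient
#'   (kJ/mol/nm) as a vector of the same length as the coordinates.
#' @param dimension Dimensionality of the configuration space.
#' @param id Label for the state (used in error messages and reports).
#' @return An object of class `end_state`.
#' @export
end_state <- function(energy_fn, gradient_fn = NULL, dimension = 1L,
                      id = "state") {
  stopifnot(is.function(energy_fn), dimension >= 1L)
  if (is.null(gradient_fn)) {
    gradient_fn <- function(x) fd_gradient(energy_fn, x)
  }
  structure(
    list(energy_fn = energy_fn, gradient_fn = gradient_fn,
         dimension = as.integer(dimension), id = as.character(id)),
    class = "end_state"
  )
}

fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(k) {
    xp <- x; xm <- x
    xp[k] <- xp[k] + h
    xm[k] <- xm[k] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

#' Evaluate an end-state potential
#'
#' @param state An `end_state` (or subclass) object.
#' @param x Numeric coordinate vector.
#' @return Energy in kJ/mol (`state_energy`), gradient vector in kJ/mol/nm
#'   (`state_gradient`).
#' @export
state_energy <- function(state, x) UseMethod("state_energy")

#' @export
state_energy.end_state <- function(state, x) state$energy_fn(x)

#' @rdname state_energy
#' @export
state_gradient <- function(state, x) UseMethod("state_gradient")

#' @export
state_gradient.end_state <- function(state, x) state$gradient_fn(x)

# Batch evaluation over a d x M matrix of configurations (one per column).
# The generic fallback loops; toy subclasses vectorise.
state_energy_multi <- function(state, X) UseMethod("state_energy_multi")

#' @export
state_energy_multi.end_state <- function(state, X) {
  apply(X, 2L, state$energy_fn)
}

# N x M matrix of all end-state energies for M configurations.
system_energy_matrix <- function(states, X) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  do.call(rbind, lapply(states, function(st) state_energy_multi(st, X)))
}

state_dimension <- function(state) state$dimension

#' EDS reference state
#'
#' The enveloping-distribution-sampling reference state combines N end-state
#' potentials into one smoothed mixture Hamiltonian
#' \deqn{V_R(r; s, E^R) = -\frac{1}{\beta s}\ln\sum_{i=1}^{N}
#'   e^{-\beta s (V_i(r) - E_i^R)},}
#' where `s` in (0, 1] is the smoothing parameter and `E^R` the per-state
#' energy offsets. At `s = 1` the reference landscape retains every end
#' state's minima; as `s` decreases the barriers between them are flattened
#' until, in the undersampling regime, all states contribute equally.
#'
#' @param states List of `end_state` objects (length N >= 1), all with the
#'   same dimension.
#' @param s Smoothing parameter in (0, 1].
#' @param offsets Numeric vector of N energy offsets `E_i^R` in kJ/mol.
#' @param thermo A [thermo_context()].
#' @return An object of class `reference_state`.
#' @export
reference_state <- function(states, s, offsets = NULL,
                            thermo = thermo_context()) {
  stopifnot(is.list(states), length(states) >= 1L,
            is.numeric(s), length(s) == 1L, s > 0, s <= 1,
            is_thermo(thermo))
  n <- length(states)
  dims <- vapply(states, state_dimension, integer(1))
  if (length(unique(dims)) != 1L)
    stop("all end states must share one dimension; got ",
         paste(dims, collapse = ", "))
  if (is.null(offsets)) offsets <- rep(0, n)
  stopifnot(length(offsets) == n, all(is.finite(offsets)))
  structure(
    list(states = states, s = s, offsets = as.numeric(offsets),
         thermo = thermo, n_states = n, dimension = dims[[1L]]),
    class = "reference_state"
  )
}

#' @export
print.reference_state <- function(x, ...) {
  cat(sprintf("<reference_state> N = %d states, dim = %d, s = %g, T = %g K\n",
              x$n_states, x$dimension, x$s, x$thermo$temperature))
  cat("offsets:", paste(signif(x$offsets, 6), collapse = " "), "kJ/mol\n")
  invisible(x)
}

with_s <- function(ref, s) { ref$s <- s; ref }
with_offsets <- function(ref, offsets) {
  stopifnot(length(offsets) == ref$n_states)
  ref$offsets <- as.numeric(offsets)
  ref
}

check_conf <- function(ref, x) {
  if (length(x) != ref$dimension)
    stop("configuration has length ", length(x), ", reference state expects ",
         ref$dimension)
  if (!all(is.finite(x))) stop("non-finite coordinates in configuration")
  x
}

endstate_energies <- function(ref, x) {
  v <- vapply(ref$states, state_energy, numeric(1), x = x)
  bad <- which(!is.finite(v))
  if (length(bad))
    stop("non-finite end-state energy for state(s) ",
         paste(vapply(ref$states[bad], `[[`, "", "id"), collapse = ", "))
  v
}

# Shifted log-sum-exp of the Boltzmann-like factors a_i = -beta*s*(V_i - E_i),
# the single numerical primitive behind energies and weights. Works on a
# vector (one configuration) or, via eds_energy_from_matrix, on a matrix of
# configurations with a per-column s.
logsumexp <- function(a) {
  m <- max(a)
  m + log(sum(exp(a - m)))
}

#' EDS reference-state energy, weights and forces
#'
#' `eds_energy()` evaluates the reference potential `V_R` at one
#' configuration via a max-shifted log-sum-exp, so arbitrarily large
#' end-state energy gaps (hundreds of kJ/mol, typical for dummy states) do
#' not overflow even at `s` as small as 1e-5. Because the offsets enter as
#' `V_i - E_i`, raising every offset by a constant C lowers `V_R` by exactly
#' C and leaves the mixture weights unchanged.
#'
#' `eds_weights()` returns the softmax factors
#' \deqn{w_i = e^{-\beta s (V_i - E_i)} / \sum_j e^{-\beta s (V_j - E_j)},}
#' computed in log space; they sum to one and give each end state's
#' contribution to the reference-state forces.
#'
#' `eds_forces()` returns the force vector `-dV_R/dr = -sum_i w_i dV_i/dr`.
#'
#' @param ref A [reference_state()].
#' @param x Numeric configuration vector.
#' @return `eds_energy`: scalar kJ/mol; `eds_weights`: probability vector of
#'   length N; `eds_forces`: vector of length `dimension` in kJ/mol/nm.
#' @examples
#' th <- thermo_context(300)
#' st <- list(harmonic_state(1000, 0), harmonic_state(1000, 0.5, shift = 5))
#' ref <- reference_state(st, s = 0.3, offsets = c(0, 0), thermo = th)
#' eds_energy(ref, 0.2)
#' eds_weights(ref, 0.2)
#' eds_forces(ref, 0.2)
#' @export
eds_energy <- function(ref, x) {
  x <- check_conf(ref, x)
  v <- endstate_energies(ref, x)
  bs <- ref$thermo$beta * ref$s
  -logsumexp(-bs * (v - ref$offsets)) / bs
}

#' @rdname eds_energy
#' @export
eds_weights <- function(ref, x) {
  x <- check_conf(ref, x)
  v <- endstate_energies(ref, x)
  softmax(-ref$thermo$beta * ref$s * (v - ref$offsets))
}

softmax <- function(a) {
  m <- max(a)
  e <- exp(a - m)
  e / sum(e)
}

#' @rdname eds_energy
#' @export
eds_forces <- function(ref, x) {
  x <- check_conf(ref, x)
  w <- eds_weights(ref, x)
  g <- vapply(ref$states, state_gradient, numeric(ref$dimension), x = x)
  g <- matrix(g, nrow = ref$dimension)
  -as.numeric(g %*% w)
}

# V_R for a precomputed N x M end-state energy matrix under a per-column
# smoothing parameter. umin-shifted form: with u_i = V_i - E_i,
#   V_R = umin - log(sum exp(-beta*s*(u - umin))) / (beta*s).
eds_energy_from_matrix <- function(V, s, offsets, beta) {
  U <- V - offsets
  if (is.null(dim(U))) U <- matrix(U, ncol = 1L)
  m <- ncol(U)
  if (length(s) == 1L) s <- rep(s, m)
  idx <- max.col(t(-U), ties.method = "first")
  umin <- U[cbind(idx, seq_len(m))]
  bs <- beta * s
  W <- exp(-(U - rep(umin, each = nrow(U))) * rep(bs, each = nrow(U)))
  umin - log(.colSums(W, nrow(W), m)) / bs
}
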