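#' Harmonic-oscillator end state
#'
#' A d-dimensional harmonic well
#' \deqn{V(x) = c + \tfrac12 \sum_d k_d (x_d - m_d)^2,}
#' the workhorse toy end state: its partition function, and hence pairwise
#' free-energy differences, are known in closed form, so it serves as the
#' oracle for every downstream estimator.
#'
#' @param force_constants Per-dimension force constants in kJ/mol/nm^2, all
#'   > 0.
#' @param minimum Position of the minimum (nm), one value per dimension.
#' @param shift Additive energy shift `c` in kJ/mol.
#' @param id State label.
#' @return An `end_state` of subclass `harmonic_state`.
#' @export
harmonic_state <- function(force_constants, minimum = 0, shift = 0,
                           id = "harmonic") {
  k <- as.numeric(force_constants)
  m <- as.numeric(minimum)
  if (length(m) == 1L && length(k) > 1L) m <- rep(m, length(k))
  if (length(k) == 1L && length(m) > 1L) k <- rep(k, length(m))
  stopifnot(length(k) == length(m), all(k > 0), all(is.finite(m)),
            is.finite(shift))
  obj <- end_state(
    energy_fn = function(x) shift + 0.5 * sum(k * (x - m)^2),
    gradient_fn = function(x) k * (x - m),
    dimension = length(k), id = id
  )
  obj$k <- k
  obj$minimum <- m
  obj$shift <- shift
  class(obj) <- c("harmonic_state", class(obj))
  obj
}

#' @export
state_energy_multi.harmonic_state <- function(state, X) {
  D <- (X - state$minimum)^2       # minimum recycled down columns (d x M)
  state$shift + 0.5 * .colSums(state$k * D, nrow(X), ncol(X))
}

#' One-dimensional multi-well polynomial end state
#'
#' A polynomial potential `V(x) = sum_j coef[j] * x^(j-1)` (kJ/mol) with
#' analytic gradient. The leading coefficient must be positive and of even
#' order so the Boltzmann factor is integrable; free-energy differences
#' against such states are computed by adaptive quadrature.
#'
#' @param coefficients Polynomial coefficients, constant term first.
#' @param id State label.
#' @return An `end_state` of subclass `polywell_state`.
#' @export
polywell_state <- function(coefficients, id = "polywell") {
  cf <- as.numeric(coefficients)
  stopifnot(length(cf) >= 3L, all(is.finite(cf)))
  deg <- length(cf) - 1L
  if (deg %% 2L != 0L || cf[length(cf)] <= 0)
    stop("polynomial must have positive even-order leading term for an ",
         "integrable Boltzmann factor")
  dcf <- cf[-1L] * seq_len(deg)
  obj <- end_state(
    energy_fn = function(x) sum(cf * x^(0:deg)),
    gradient_fn = function(x) sum(dcf * x^(0:(deg - 1L))),
    dimension = 1L, id = id
  )
  obj$coefficients <- cf
  class(obj) <- c("polywell_state", class(obj))
  obj
}

#' @export
state_energy_multi.polywell_state <- function(state, X) {
  x <- as.numeric(X)
  cf <- state$coefficients
  v <- rep(cf[length(cf)], length(x))
  for (j in rev(seq_len(length(cf) - 1L))) v <- v * x + cf[j]
  v
}

#' Toy-system specification and construction
#'
#' `toy_system_spec()` describes a reproducible synthetic multistate system;
#' `make_toy_system()` realises it as a list of end states with analytic
#' gradients. When `states` is `NULL`, N harmonic states are drawn
#' deterministically from `seed`: minima spread over about 1 nm, force
#' constants in \[500, 5000\] kJ/mol/nm^2, energy shifts in \[-80, 20\]
#' kJ/mol — gaps of the size met when estimating energy offsets for real
#' ligand sets.
#'
#' @param n_states Number of end states (>= 2).
#' @param dimension Configuration-space dimension (1-3).
#' @param states Optional list of pre-built `end_state` objects.
#' @param seed Integer seed controlling random generation.
#' @return `toy_system_spec`: a spec object; `make_toy_system`: a list of
#'   `end_state` objects.
#' @examples
#' sys <- make_toy_system(toy_system_spec(3, seed = 7))
#' length(sys)
#' @export
toy_system_spec <- function(n_states = 5L, dimension = 1L, states = NULL,
                            seed = 1L) {
  stopifnot(n_states >= 2L, dimension >= 1L, dimension <= 3L)
  if (!is.null(states)) {
    stopifnot(is.list(states), length(states) == n_states)
    dims <- vapply(states, state_dimension, integer(1))
    if (any(dims != dimension))
      stop("state dimensions (", paste(dims, collapse = ", "),
           ") do not match spec dimension ", dimension)
  }
  structure(
    list(n_states = as.integer(n_states), dimension = as.integer(dimension),
         states = states, seed = as.integer(seed)),
    class = "toy_system_spec"
  )
}

#' @rdname toy_system_spec
#' @param spec A `toy_system_spec`.
#' @export
make_toy_system <- function(spec) {
  stopifnot(inherits(spec, "toy_system_spec"))
  if (!is.null(spec$states)) return(spec$states)
  n <- spec$n_states
  d <- spec$dimension
  rng <- local_rng(spec$seed)
  minima <- matrix(rng$runif(n * d, -0.5, 0.5), nrow = d)
  ks <- matrix(rng$runif(n * d, 500, 5000), nrow = d)
  shifts <- rng$runif(n, -80, 20)
  lapply(seq_len(n), function(i) {
    harmonic_state(ks[, i], minima[, i], shift = shifts[i],
                   id = paste0("S", i))
  })
}

# Seeded draws that do not disturb the caller's RNG stream.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  }
  draw <- function(fn) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- fn(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    out
  }
  list(runif = draw(stats::runif), rnorm = draw(stats::rnorm))
}

#' Benchmark and bottleneck toy presets
#'
#' `toy_benchmark()` is the default five-state one-dimensional harmonic
#' benchmark used throughout the tests: minima spread over about 1 nm, force
#' constants between 500 and 5000 kJ/mol/nm^2, and energy shifts between -80
#' and 20 kJ/mol, so the offset-estimation stages are exercised over
#' realistic free-energy gaps.
#'
#' `toy_bottleneck()` places the five minima in two clusters far apart, so a
#' naive logarithmic replica ladder exhibits an exchange gap at intermediate
#' smoothing — the situation the round-trip-time ladder optimizer is designed
#' to repair.
#'
#' @return A list of `end_state` objects.
#' @export
toy_benchmark <- function() {
  list(
    harmonic_state(1000, -0.50, shift =   0, id = "S1"),
    harmonic_state(2500, -0.25, shift = -35, id = "S2"),
    harmonic_state( 600,  0.05, shift =  15, id = "S3"),
    harmonic_state(4000,  0.30, shift = -80, id = "S4"),
    harmonic_state(1600,  0.50, shift = -20, id = "S5")
  )
}

#' @rdname toy_benchmark
#' @export
toy_bottleneck <- function() {
  list(
    harmonic_state(2000, 0.00, shift =   0, id = "A1"),
    harmonic_state(3000, 0.08, shift = -12, id = "A2"),
    harmonic_state(1500, 0.16, shift =  10, id = "A3"),
    harmonic_state(2500, 2.00, shift = -30, id = "B1"),
    harmonic_state(2000, 2.10, shift = -15, id = "B2")
  )
}

#' Analytic pairwise free-energy difference
#'
#' Free-energy oracle for toy end states: `dG_ji = G_j - G_i` with
#' `G = -(1/beta) ln Z`. For harmonic pairs the closed form
#' \deqn{\Delta G_{ji} = \Delta c + \frac{1}{2\beta}\sum_d \ln(k_{j,d}/k_{i,d})}
#' is used; any other one-dimensional pair falls back to adaptive quadrature
#' of the Boltzmann integrals (absolute tolerance ~1e-6 kJ/mol). The oracle
#' is exactly antisymmetric and additive over triples, so cycle closure holds
#' by construction.
#'
#' @param state_j,state_i End states (order: result is `G_j - G_i`).
#' @param thermo A [thermo_context()].
#' @return Free-energy difference in kJ/mol.
#' @export
analytic_free_energy <- function(state_j, state_i, thermo = thermo_context()) {
  stopifnot(is_thermo(thermo))
  if (inherits(state_j, "harmonic_state") && inherits(state_i, "harmonic_state")) {
    if (state_j$dimension != state_i$dimension)
      stop("states have different dimensions")
    return((state_j$shift - state_i$shift) +
             sum(log(state_j$k / state_i$k)) / (2 * thermo$beta))
  }
  if (state_dimension(state_j) != 1L || state_dimension(state_i) != 1L)
    stop("quadrature oracle is available for 1D states only")
  log_partition_1d(state_j, thermo) * (-1 / thermo$beta) -
    log_partition_1d(state_i, thermo) * (-1 / thermo$beta)
}

# ln Z for a 1D state by adaptive quadrature, stabilised around the
# potential minimum so deep wells do not underflow.
log_partition_1d <- function(state, thermo) {
  f <- function(x) vapply(x, function(xx) state_energy(state, xx), numeric(1))
  lo <- -20; hi <- 20
  if (inherits(state, "harmonic_state")) {
    sd <- sqrt(1 / (thermo$beta * state$k))
    lo <- state$minimum - 12 * sd
    hi <- state$minimum + 12 * sd
  }
  vmin <- stats::optimize(f, c(lo, hi))$objective
  g <- function(x) exp(-thermo$beta * (f(x) - vmin))
  int <- stats::integrate(g, lo, hi, rel.tol = 1e-10, abs.tol = 0,
                          subdivisions = 500L)
  if (int$message != "OK") stop("quadrature failed: ", int$message)
  -thermo$beta * vmin + log(int$value)
}

#' Pairwise analytic free-energy matrix
#'
#' @param states List of end states.
#' @param thermo A [thermo_context()].
#' @return N x N matrix with entry \[j, i\] = `dG_ji` in kJ/mol.
#' @export
analytic_free_energy_matrix <- function(states, thermo = thermo_context()) {
  n <- length(states)
  g <- vapply(states, function(st) analytic_free_energy(st, states[[1L]], thermo),
              numeric(1))
  outer(g, g, `-`)
}
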