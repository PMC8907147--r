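# Shared fixtures and independent oracles used across the suite.

# Brute-force log-sum-exp with Kahan-compensated summation: an independent
# high-precision route to the EDS reference energy.
kahan_sum <- function(x) {
  s <- 0; c <- 0
  for (xi in x) {
    y <- xi - c
    t <- s + y
    c <- (t - s) - y
    s <- t
  }
  s
}

brute_eds_energy <- function(v, e, s, beta) {
  a <- -beta * s * (v - e)
  m <- max(a)
  -(m + log(kahan_sum(exp(a - m)))) / (beta * s)
}

brute_eds_weights <- function(v, e, s, beta) {
  w <- exp(-beta * s * (v - e - min(v - e)))
  w / sum(w)
}

# Constant-energy end state: V(x) = value everywhere (zero force).
constant_state <- function(value, dimension = 1L, id = "const") {
  force(value)
  end_state(function(x) value, function(x) rep(0, length(x)),
            dimension = dimension, id = id)
}

# Build an energy trajectory directly from an N-column energy matrix,
# recomputing V_R consistently; s and offsets recycled over frames.
mk_traj <- function(V, s = 1, offsets = rep(0, ncol(V)),
                    thermo = thermo_context()) {
  V <- as.matrix(V)
  vr <- reedsim:::eds_energy_from_matrix(t(V), rep(s, nrow(V)), offsets,
                                         thermo$beta)
  fr <- data.frame(time = seq_len(nrow(V)) * 20,
                   replica = rep(1L, nrow(V)),
                   s = rep(s, nrow(V)), V_R = as.numeric(vr))
  for (i in seq_len(ncol(V))) fr[[paste0("V_", i)]] <- V[, i]
  energy_trajectory(fr, offsets)
}

# Independent round-trip counter: collapse each replica's walk to its
# top/bottom touches and scan the token run-length sequence for
# top -> bottom -> top segments.
rescan_round_trips <- function(positions, bottom = max(positions)) {
  total <- 0L
  for (r in seq_len(ncol(positions))) {
    tok <- rle(positions[positions[, r] %in% c(1L, bottom), r])$values
    i <- 1L
    while (i + 2L <= length(tok)) {
      if (tok[i] == 1L && tok[i + 1L] == bottom && tok[i + 2L] == 1L) {
        total <- total + 1L
        i <- i + 2L
      } else i <- i + 1L
    }
  }
  total
}

two_state_close <- function() {
  list(harmonic_state(1000, 0.00, shift = 0, id = "A"),
       harmonic_state(4000, 0.05, shift = 7, id = "B"))
}
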