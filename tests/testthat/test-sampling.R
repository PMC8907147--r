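th300 <- thermo_context(300)

test_that("ladder validation enforces the descending-from-one convention", {
  expect_silent(s_distribution(c(1, 0.5, 0.1)))
  expect_error(s_distribution(c(0.9, 0.5)), "s = 1")
  expect_error(s_distribution(c(1, 0.5, 0.5)), "decreasing")
  expect_error(s_distribution(c(1, 0, -1)), "in \\(0, 1\\]")
  lad <- log_s_ladder(21, 1e-5)
  expect_length(lad, 21)
  expect_equal(as.numeric(lad[1]), 1)
  expect_equal(as.numeric(lad[21]), 1e-5, tolerance = 1e-12)
})

test_that("zero-step propagation is the identity and seeds reproduce", {
  st <- list(harmonic_state(1000, 0))
  ref <- reference_state(st, s = 1, thermo = th300)
  out <- propagate(ref, 0.123, 0)
  expect_equal(out$conf, 0.123)
  a <- propagate(ref, 0, 500, seed = 4)
  b <- propagate(ref, 0, 500, seed = 4)
  expect_equal(a$conf, b$conf)
  expect_equal(a$trajectory$V_R, b$trajectory$V_R)
})

test_that("MC sampling reproduces the equipartition variance", {
  k <- 1000
  st <- list(harmonic_state(k, 0))
  ref <- reference_state(st, s = 1, thermo = th300)
  run <- propagate(ref, 0, 1e5, store_interval = 10, seed = 11)
  # reconstruct x^2 from the stored harmonic energies: V = k x^2 / 2
  x2 <- 2 * run$trajectory$V_1 / k
  target <- 1 / (th300$beta * k)
  blocks <- split(x2, cut(seq_along(x2), 10, labels = FALSE))
  bm <- vapply(blocks, mean, numeric(1))
  se <- sd(bm) / sqrt(length(bm))
  expect_lt(abs(mean(x2) - target), 3 * se + 1e-12)
})

test_that("exchange probability is one for equal s and symmetric in its pair", {
  st <- toy_benchmark()
  rk <- reference_state(st, s = 0.4, thermo = th300)
  rl <- reference_state(st, s = 0.4, thermo = th300)
  expect_equal(exchange_probability(rk, rl, -0.3, 0.4), 1)
  rl2 <- reference_state(st, s = 0.1, thermo = th300)
  p1 <- exchange_probability(rk, rl2, -0.3, 0.4)
  p2 <- exchange_probability(rl2, rk, 0.4, -0.3)
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_true(p1 >= 0 && p1 <= 1)
  rdiff <- reference_state(st, s = 0.1, offsets = rep(1, 5), thermo = th300)
  expect_error(exchange_probability(rk, rdiff, 0, 0), "differ only")
})

test_that("exchange probability matches a hand-evaluated criterion", {
  # constant-energy states make every H_R analytic:
  # H_R(s) = -log(e^{-b s v1} + e^{-b s v2})/(b s)
  v <- c(3, 20)
  st <- lapply(v, constant_state)
  b <- th300$beta
  hr <- function(s) -log(sum(exp(-b * s * v))) / (b * s)
  rk <- reference_state(st, s = 0.8, thermo = th300)
  rl <- reference_state(st, s = 0.2, thermo = th300)
  # configurations are irrelevant for constant states: delta reduces to 0
  expect_equal(exchange_probability(rk, rl, 0, 0),
               min(1, exp(-b * ((hr(0.2) + hr(0.8)) - (hr(0.2) + hr(0.8))))))
  expect_equal(exchange_probability(rk, rl, 0, 0), 1)
})

test_that("single-replica runs have no exchanges and no round trips", {
  ens <- replica_ensemble(two_state_close(), 1, thermo = th300)
  run <- run_reeds(ens, 200, seed = 1)
  expect_equal(nrow(run$exchanges), 0)
  expect_equal(run$round_trips$n_round_trips, 0L)
  expect_true(is.na(run$round_trips$mean_round_trip_time))
})

test_that("replica exchange with a ladder accepts richly and trips round", {
  st <- toy_benchmark()
  off <- analytic_free_energy_matrix(st, th300)[, 1]
  ens <- replica_ensemble(st, log_s_ladder(11, 0.005), offsets = off,
                          thermo = th300)
  run <- run_reeds(ens, 8000, seed = 2)
  expect_gt(mean(run$exchanges$accepted), 0.2)
  expect_gt(run$round_trips$n_round_trips, 0L)
  # deterministic under the seed
  run2 <- run_reeds(replica_ensemble(st, log_s_ladder(11, 0.005),
                                     offsets = off, thermo = th300),
                    8000, seed = 2)
  expect_equal(run$trajectory$V_R, run2$trajectory$V_R)
  expect_equal(run$positions, run2$positions)
})

test_that("stored reference energies are reproducible from the frames", {
  st <- toy_benchmark()
  ens <- replica_ensemble(st, log_s_ladder(7, 0.01), thermo = th300)
  run <- run_reeds(ens, 1000, seed = 3)
  expect_lt(verify_trajectory(run$trajectory, th300), 1e-8)
})

test_that("exchange bookkeeping preserves the replica permutation", {
  st <- two_state_close()
  ens <- replica_ensemble(st, log_s_ladder(6, 0.02), thermo = th300)
  run <- run_reeds(ens, 2000, seed = 5)
  for (t in seq_len(nrow(run$positions))) {
    expect_setequal(run$positions[t, ], 1:6)
  }
  # replicas move at most one level per sweep (neighbour exchanges only)
  moves <- abs(diff(run$positions))
  expect_true(all(moves <= 1))
})

test_that("round-trip counting matches constructed walks and a re-scan", {
  # top -> bottom -> top -> bottom -> top: two round trips
  walk <- matrix(c(1, 2, 3, 2, 3, 1, 2, 3, 2, 1), ncol = 1)
  rt <- count_round_trips(walk, bottom = 3)
  expect_equal(rt$n_round_trips, 2L)
  expect_equal(rt$durations, c(5, 4))
  # a walk that never reaches the bottom counts nothing
  rt0 <- count_round_trips(matrix(c(1, 2, 2, 1, 2, 1), ncol = 1), bottom = 3)
  expect_equal(rt0$n_round_trips, 0L)
  expect_true(is.na(rt0$mean_round_trip_time))
  # random walks: state machine equals the independent token re-scan
  set.seed(13)
  for (rep in 1:20) {
    m <- sample(3:5, 1)
    P <- matrix(sample.int(m, 200, replace = TRUE), ncol = 2)
    expect_equal(count_round_trips(P, bottom = m)$n_round_trips,
                 rescan_round_trips(P, bottom = m))
  }
})

test_that("two-replica occupancy matches the analytic Boltzmann mixture", {
  # N = 2 harmonic states; at s = 1 the reference density is an analytic
  # two-Gaussian mixture, binned and compared by a chi-squared GOF test.
  st <- list(harmonic_state(1000, 0), harmonic_state(1000, 0.15, shift = 2))
  ens <- replica_ensemble(st, s_distribution(c(1, 0.25)), thermo = th300)
  run <- run_reeds(ens, 40000, seed = 8, record_coordinates = TRUE)
  x <- run$coordinates[1, 1, ] # s = 1 level over sweeps
  x <- x[seq(1, length(x), by = 5)] # thin to reduce autocorrelation
  b <- th300$beta
  w <- exp(-b * c(0, 2)) # equal widths: mixture weights from the shifts
  w <- w / sum(w)
  sd1 <- sqrt(1 / (b * 1000))
  edges <- c(-Inf, seq(-0.08, 0.22, by = 0.05), Inf)
  probs <- diff(w[1] * pnorm(edges, 0, sd1) + w[2] * pnorm(edges, 0.15, sd1))
  counts <- table(cut(x, edges))
  gof <- suppressWarnings(chisq.test(as.numeric(counts), p = probs))
  expect_gt(gof$p.value, 0.01)
})

test_that("langevin integration stays near the well and is seeded", {
  ref <- reference_state(list(harmonic_state(1000, 0.1)), s = 1,
                         thermo = th300)
  a <- propagate_langevin(ref, 0.1, 2000, dt = 1e-5, seed = 6)
  bb <- propagate_langevin(ref, 0.1, 2000, dt = 1e-5, seed = 6)
  expect_equal(a$conf, bb$conf)
  expect_lt(abs(mean(a$path) - 0.1), 0.05)
})
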