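th300 <- thermo_context(300)

mk_exchanges <- function(i, accepted, mc_i, mc_j) {
  data.frame(step = seq_along(i) * 20, i = i, j = i + 1L,
             p = as.numeric(accepted), accepted = accepted,
             mc_i = mc_i, mc_j = mc_j)
}

test_that("bottleneck severities are one minus per-state acceptance", {
  s <- c(1, 0.5, 0.1)
  # all attempts accepted: severity 0 everywhere it was attempted
  ex <- mk_exchanges(c(1L, 2L, 1L, 2L), rep(TRUE, 4),
                     c(1L, 1L, 2L, 2L), c(1L, 1L, 2L, 2L))
  bn <- detect_bottlenecks(ex, s, 2)
  expect_equal(bn$severity, matrix(0, 2, 2))
  # a pair without a single accepted swap ranks first for every state
  ex2 <- mk_exchanges(c(1L, 1L, 2L, 2L), c(TRUE, TRUE, FALSE, FALSE),
                      c(1L, 2L, 1L, 2L), c(1L, 2L, 1L, 2L))
  bn2 <- suppressWarnings(detect_bottlenecks(ex2, s, 2))
  for (state in 1:2) expect_equal(bn2$ranking[[state]][1], 2L)
  # zero attempts for a state in an interval count as a full bottleneck
  ex3 <- mk_exchanges(c(1L, 2L), c(TRUE, TRUE), c(1L, 1L), c(1L, 1L))
  expect_warning(bn3 <- detect_bottlenecks(ex3, s, 2), "bottleneck")
  expect_equal(bn3$severity[, 2], c(1, 1))
})

test_that("bottleneck detection matches a brute-force recount", {
  set.seed(51)
  s <- log_s_ladder(6, 0.01)
  n_states <- 3L
  ex <- mk_exchanges(sample(1:5, 300, replace = TRUE),
                     sample(c(TRUE, FALSE), 300, replace = TRUE),
                     sample.int(n_states, 300, replace = TRUE),
                     sample.int(n_states, 300, replace = TRUE))
  bn <- suppressWarnings(detect_bottlenecks(ex, s, n_states))
  for (k in 1:5) for (i in seq_len(n_states)) {
    rel <- ex$i == k & (ex$mc_i == i | ex$mc_j == i)
    want <- if (!any(rel)) 1 else 1 - mean(ex$accepted[rel])
    expect_equal(bn$severity[k, i], want)
  }
})

test_that("ladder refinement interpolates linearly and retains history", {
  s <- s_distribution(c(1, 0.1, 0.01))
  bn <- list(ranking = list(c(2L, 1L))) # one state, worst interval [0.1, 0.01]
  out <- nlrto_step(s, bn, 1L)
  expect_true(any(abs(as.numeric(out) - 0.055) < 1e-12))
  expect_true(all(as.numeric(s) %in% as.numeric(out)))
  # four insertions into [0.5, ~0] spread evenly
  s2 <- s_distribution(c(1, 0.5, 1e-12))
  bn2 <- list(ranking = list(c(2L, 1L)))
  out2 <- nlrto_step(s2, bn2, 4L)
  expect_equal(sort(setdiff(round(as.numeric(out2), 12),
                            round(as.numeric(s2), 12))),
               c(0.1, 0.2, 0.3, 0.4), tolerance = 1e-6)
  # round-robin across states with different worst intervals
  s3 <- s_distribution(c(1, 0.6, 0.2))
  bn3 <- list(ranking = list(c(1L, 2L), c(2L, 1L)))
  out3 <- nlrto_step(s3, bn3, 2L)
  expect_length(out3, 5)
  expect_true(any(abs(as.numeric(out3) - 0.8) < 1e-12)) # state 1's interval
  expect_true(any(abs(as.numeric(out3) - 0.4) < 1e-12)) # state 2's interval
})

test_that("ladder growth is monotone and coalesces duplicates", {
  set.seed(53)
  s <- log_s_ladder(5, 0.01)
  for (rep in 1:10) {
    bn <- list(ranking = list(sample(1:4), sample(1:4)))
    n_ins <- sample(1:4, 1)
    out <- nlrto_step(s, bn, n_ins)
    expect_true(all(as.numeric(s) %in% as.numeric(out)))
    expect_true(all(diff(as.numeric(out)) < 0))
    expect_lte(length(out), length(s) + n_ins)
    s <- out
  }
})

test_that("rebalancing is exact at the fixed point and bounded elsewhere", {
  rep5 <- structure(list(f_mc = rep(0.2, 5), ideal_fraction = 0.2),
                    class = "sampling_report")
  off <- c(0, -5, 10, 2, -1)
  out <- rebalance_offsets(rep5, off, thermo = th300)
  expect_equal(as.numeric(out), off - off[1])
  expect_equal(attr(out, "correction"), rep(0, 5))
  # literal correction for a never-sampled state: (1/beta) ln(31)
  rep0 <- structure(list(f_mc = c(0, 0.5, 0.5), ideal_fraction = 1 / 3),
                    class = "sampling_report")
  out0 <- rebalance_offsets(rep0, rep(0, 3), thermo = th300)
  expect_equal(attr(out0, "correction")[1], log(31) / th300$beta,
               tolerance = 1e-12)
  expect_equal(attr(out0, "correction")[1], 8.566, tolerance = 1e-3)
  # over-sampled states are pushed down
  expect_lt(attr(out0, "correction")[2], 0)
  # correction magnitudes never exceed the cap, over random reports
  set.seed(59)
  for (r in 1:50) {
    n <- sample(2:8, 1)
    f <- runif(n); f <- f / sum(f)
    rp <- structure(list(f_mc = f, ideal_fraction = 1 / n),
                    class = "sampling_report")
    co <- attr(rebalance_offsets(rp, rep(0, n), thermo = th300), "correction")
    expect_true(all(abs(co) <= log(31) / th300$beta + 1e-12))
  }
})

test_that("the correction cap reproduces both published magnitudes", {
  expect_equal(rebalance_correction_cap(thermo_context(298.15), 30,
                                        literal = FALSE),
               8.43, tolerance = 1e-3)
  expect_equal(rebalance_correction_cap(th300, 30, literal = TRUE),
               log(31) / th300$beta)
})

test_that("convergence needs sampled states, round trips and a fast ladder", {
  rt0 <- count_round_trips(matrix(c(1, 2, 2, 1), ncol = 1), bottom = 3)
  c1 <- check_convergence(c(0.5, 0, 0.5), rt0)
  expect_false(c1$converged)
  expect_true("state sampling" %in% c1$reasons)
  expect_true("no round trips" %in% c1$reasons)
  rt2 <- count_round_trips(matrix(c(1, 3, 1, 3, 1), ncol = 1), bottom = 3)
  c2 <- check_convergence(rep(1 / 3, 3), rt2, steps_per_ns = 1)
  expect_false(c2$converged) # tau/nRT = 1 ns > 0.5 ns
  expect_equal(c2$reasons, "round-trip time")
  c3 <- check_convergence(rep(1 / 3, 3), rt2, steps_per_ns = 5e5)
  expect_true(c3$converged)
})

test_that("an empty schedule returns the input unchanged and unconverged", {
  st <- toy_benchmark()
  out <- run_optimization(st, log_s_ladder(5, 0.01), rep(0, 5),
                          schedule = integer(0))
  expect_false(out$converged)
  expect_equal(as.numeric(out$s_values), as.numeric(log_s_ladder(5, 0.01)))
  expect_equal(out$offsets, rep(0, 5))
  expect_equal(nrow(out$history), 0L)
})

test_that("an ideal start converges within a couple of iterations", {
  st <- toy_benchmark()
  truth <- analytic_free_energy_matrix(st, th300)[, 1]
  out <- run_optimization(st, log_s_ladder(12, 0.005), truth,
                          schedule = optimization_schedule(4000, 2),
                          rebalance_steps = 3000, seed = 61)
  expect_true(out$rebalance_converged)
  hist_rb <- out$history[out$history$phase == "rebalancing", ]
  expect_lte(nrow(hist_rb), 3)
  expect_lte(tail(hist_rb$max_fmc_dev, 1), 0.12)
})

test_that("rebalancing recovers a deliberately detuned offset", {
  st <- toy_benchmark()
  truth <- analytic_free_energy_matrix(st, th300)[, 1]
  detuned <- truth + c(0, 10, 0, 0, 0)
  wins <- 0
  for (seed in 1:5) {
    ens <- replica_ensemble(st, log_s_ladder(10, 0.005), offsets = detuned,
                            thermo = th300)
    run <- run_reeds(ens, 3000, seed = seed)
    rep0 <- sampling_report(physical_trajectory(run))
    mad0 <- mean(abs(rep0$f_mc - 0.2))
    off <- detuned
    mads <- mad0
    for (it in 1:4) {
      off <- as.numeric(rebalance_offsets(
        sampling_report(physical_trajectory(run)), off, thermo = th300))
      ens <- replica_ensemble(st, log_s_ladder(10, 0.005), offsets = off,
                              configurations = run$ensemble$configurations,
                              thermo = th300)
      run <- run_reeds(ens, 3000, seed = seed + 100 * it)
      mads <- c(mads, mean(abs(sampling_report(
        physical_trajectory(run))$f_mc - 0.2)))
    }
    if (min(mads[-1]) < mad0) wins <- wins + 1
  }
  expect_gte(wins, 4)
})
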