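th300 <- thermo_context(300)

test_that("identical and constant-shifted states give exact differences", {
  set.seed(63)
  base <- rnorm(40, 0, 5)
  V <- cbind(base, base, base + 3.7)
  traj <- mk_traj(V)
  fe <- zwanzig_multistate(traj, th300)
  expect_equal(fe$dG[2, 1], 0)
  expect_equal(fe$dG[3, 1], 3.7, tolerance = 1e-10)
  expect_equal(fe$dG[3, 2], 3.7, tolerance = 1e-10)
})

test_that("the pairwise matrix is antisymmetric with exact cycle closure", {
  set.seed(65)
  V <- matrix(rnorm(200, 0, 30), ncol = 4)
  fe <- zwanzig_multistate(mk_traj(V), th300)
  expect_equal(fe$dG, -t(fe$dG))
  expect_equal(diag(fe$dG), rep(0, 4), ignore_attr = TRUE)
  n <- 4
  for (a in 1:n) for (b in 1:n) for (cc in 1:n) {
    expect_lt(abs(fe$dG[cc, a] - fe$dG[cc, b] - fe$dG[b, a]), 1e-10)
  }
})

test_that("estimates are invariant to the offsets used during production", {
  set.seed(67)
  V <- matrix(rnorm(300, 0, 20), ncol = 3)
  t0 <- mk_traj(V, s = 1, offsets = c(0, 0, 0))
  tC <- mk_traj(V, s = 1, offsets = c(4, 4, 4)) # V_R shifted by -4... recompute
  fe0 <- zwanzig_multistate(t0, th300)
  feC <- zwanzig_multistate(tC, th300)
  expect_equal(fe0$dG, feC$dG, tolerance = 1e-10)
})

test_that("only s = 1 frames are accepted and emptiness errors", {
  V <- matrix(rnorm(20), ncol = 2)
  expect_error(zwanzig_multistate(mk_traj(V, s = 0.5), th300), "s = 1")
  expect_error(zwanzig_multistate(mk_traj(V[1, , drop = FALSE]), th300),
               "two retained")
})

test_that("a converged two-state run recovers the analytic width term", {
  st <- list(harmonic_state(1000, 0), harmonic_state(4000, 0.03))
  truth <- analytic_free_energy(st[[2]], st[[1]], th300) # ln(4)/(2 beta)
  ens <- replica_ensemble(st, s_distribution(c(1, 0.4, 0.15, 0.05)),
                          offsets = c(0, truth), thermo = th300)
  run <- run_reeds(ens, 30000, seed = 71)
  fe <- zwanzig_multistate(physical_trajectory(run), th300)
  expect_lt(abs(fe$dG[2, 1] - truth), 2 * fe$uncertainty[2, 1])
})

test_that("constant weights have zero uncertainty", {
  V <- cbind(rep(2, 50), rep(5, 50))
  traj <- mk_traj(V)
  fe <- zwanzig_multistate(traj, th300)
  expect_equal(fe$uncertainty[2, 1], 0)
  expect_equal(gaussian_uncertainty(traj, 2, 1, th300), 0)
})

test_that("uncertainty shrinks like one over root n for iid frames", {
  set.seed(73)
  ratios <- vapply(1:10, function(r) {
    V1 <- cbind(rnorm(400, 0, 2), rnorm(400, 5, 2))
    V2 <- cbind(rnorm(800, 0, 2), rnorm(800, 5, 2))
    u1 <- gaussian_uncertainty(mk_traj(V1), 2, 1, th300)
    u2 <- gaussian_uncertainty(mk_traj(V2), 2, 1, th300)
    u2 / u1
  }, numeric(1))
  expect_equal(mean(ratios), 1 / sqrt(2), tolerance = 0.15)
})

test_that("gaussian errors agree with a bootstrap on iid weights", {
  set.seed(75)
  V <- cbind(rnorm(2000, 0, 3), rnorm(2000, 4, 3))
  traj <- mk_traj(V)
  g <- gaussian_uncertainty(traj, 2, 1, th300)
  A <- -th300$beta * (cbind(V[, 1], V[, 2]) - traj$V_R)
  boot <- vapply(1:200, function(b) {
    idx <- sample.int(nrow(A), replace = TRUE)
    lme <- function(a) {
      m <- max(a); m + log(mean(exp(a - m)))
    }
    -(lme(A[idx, 2]) - lme(A[idx, 1])) / th300$beta
  }, numeric(1))
  expect_lt(abs(g - sd(boot)) / sd(boot), 0.3)
})

test_that("too few frames for blocking warns and degrades gracefully", {
  V <- matrix(rnorm(12), ncol = 2)
  traj <- mk_traj(V)
  ws <- capture_warnings(u <- gaussian_uncertainty(traj, 2, 1, th300,
                                                   n_blocks = 10))
  expect_match(ws, "blocks", all = TRUE)
  expect_true(is.na(u))
})

test_that("environment combination and summary statistics are exact", {
  set.seed(77)
  Vw <- matrix(rnorm(150, 0, 10), ncol = 3)
  few <- zwanzig_multistate(mk_traj(Vw), th300, environment_label = "water")
  # identical environments cancel exactly
  same <- combine_environments(few, few)
  expect_equal(same$ddG, matrix(0, 3, 3), ignore_attr = TRUE)
  # hand-built 3-state matrices
  g_w <- c(0, 2, -1); g_c <- c(0, 5, 1)
  mw <- outer(g_w, g_w, `-`); mc <- outer(g_c, g_c, `-`)
  dimnames(mw) <- dimnames(mc) <- dimnames(few$dG)
  few$dG <- mw; few$uncertainty <- 0 * mw
  fec <- few; fec$dG <- mc
  truth <- outer(c(0, 3, 2), c(0, 3, 2), `-`)
  # the all-zero reference makes the rank correlation degenerate; only the
  # error statistics are checked here
  res <- suppressWarnings(
    combine_environments(few, fec, reference_ddG = truth * 0))
  expect_equal(res$ddG, truth, ignore_attr = TRUE)
  err <- truth[row(truth) != col(truth)]
  expect_equal(res$rmse, sqrt(mean(err^2)))
  expect_equal(res$mae, mean(abs(err)))
  # reversing a pair flips the sign
  expect_equal(res$ddG[2, 1], -res$ddG[1, 2])
  # mismatched labels are rejected
  bad <- fec; dimnames(bad$dG) <- list(letters[1:3], letters[1:3])
  expect_error(combine_environments(few, bad), "labels")
})

test_that("spearman and bootstrap errors behave on noisy references", {
  set.seed(79)
  g <- c(0, -3, 5, 2)
  dd <- outer(g, g, `-`)
  fe1 <- list(dG = dd, uncertainty = 0 * dd)
  fe2 <- list(dG = 2 * dd, uncertainty = 0 * dd)
  dimnames(fe1$dG) <- dimnames(fe2$dG) <- dimnames(fe1$uncertainty) <-
    dimnames(fe2$uncertainty) <- list(paste0("S", 1:4), paste0("S", 1:4))
  class(fe1) <- class(fe2) <- "free_energy_result"
  res <- combine_environments(fe1, fe2, reference_ddG = dd)
  # ddG = 2dd - dd = dd equals the reference: rmse 0, perfect rank order
  expect_equal(res$rmse, 0)
  expect_equal(res$spearman, 1)
  expect_true(res$rmse_sd >= 0)
})

test_that("anchoring averages over every anchor choice", {
  g <- c(-40, -38, -35)
  dd <- outer(g, g, `-`)
  one <- anchored_absolute(dd, c(-40, NA, NA))
  expect_equal(one$G, g)
  expect_equal(one$sd, rep(0, 3))
  all3 <- anchored_absolute(dd, g)
  expect_equal(all3$G, g)
  expect_equal(all3$sd, rep(0, 3))
  # perturbed matrix: means equal the brute-force enumeration
  set.seed(81)
  pert <- dd + matrix(rnorm(9, 0, 0.5), 3, 3)
  res <- anchored_absolute(pert, g)
  brute <- sapply(1:3, function(a) g[a] + pert[, a])
  expect_equal(res$G, rowMeans(brute))
  expect_equal(res$sd, apply(brute, 1, sd))
  expect_error(anchored_absolute(dd, rep(NA_real_, 3)), "anchor")
})
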