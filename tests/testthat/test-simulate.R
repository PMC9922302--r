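ff <- forcefield_parameters()

test_that("steepest descent relaxes a stretched dimer to the bond minimum", {
  s2 <- residue_sequence("AA")
  x0 <- rbind(c(0, 0, 0), c(0.48, 0, 0))
  xm <- minimize_steepest_descent(x0, s2, ff)
  expect_equal(sqrt(sum((xm[2, ] - xm[1, ])^2)), 0.38, tolerance = 1e-4)
  # starting at the minimum returns essentially unchanged
  x1 <- rbind(c(0, 0, 0), c(0.38, 0, 0))
  xm1 <- minimize_steepest_descent(x1, s2, ff)
  expect_lt(max(abs(xm1 - x1)), 1e-6)
})

test_that("minimization never increases the energy", {
  sys <- random_test_system(10L, 3L, spread = 2)
  e0 <- cg_energy(sys$conf, sys$seq, ff)$total
  traj_e <- numeric(0)
  x <- sys$conf
  for (i in 1:10) {
    x <- minimize_steepest_descent(x, sys$seq, ff, max_steps = 20L)
    traj_e <- c(traj_e, attr(x, "energy"))
  }
  expect_true(all(diff(c(e0, traj_e)) <= 1e-9))
})

test_that("Langevin trajectories are deterministic for a fixed seed", {
  s <- make_fixture_sequences("polyAla", 20L)[[1]]
  x0 <- minimize_steepest_descent(init_random_coordinates(s, 1L), s, ff)
  pr <- simulation_protocol(n_steps = 20000L, save_interval_ps = 40,
                            seed = 5L)
  e1 <- langevin_simulate(x0, s, ff, pr)
  e2 <- langevin_simulate(x0, s, ff, pr)
  expect_identical(e1$xyz, e2$xyz)
  pr2 <- simulation_protocol(n_steps = 20000L, save_interval_ps = 40,
                             seed = 6L)
  e3 <- langevin_simulate(x0, s, ff, pr2)
  expect_false(identical(e1$xyz, e3$xyz))
  expect_equal(n_frames(e1), 10L)  # 20000 steps / (40 ps / 0.02 ps)
})

test_that("the scaled reference protocol concatenates equal-length runs", {
  s <- make_fixture_sequences("polyAla", 20L)[[1]]
  ens <- reference_protocol(s, ff, scale = 0.002, seed = 3L)
  # 0.002 * 5000 frames per run = 10 frames x 5 runs
  expect_equal(n_frames(ens), 50L)
  run_id <- attr(ens, "run_id")
  expect_equal(as.numeric(table(run_id)), rep(10, 5))
  # independent runs differ
  expect_false(identical(ens$xyz[1, , ], ens$xyz[11, , ]))
})

test_that("a long trimer run reproduces the Boltzmann bond distribution", {
  # two-sample KS between simulated bond lengths and quadrature-sampled
  # ones stays below a pre-registered threshold
  s3 <- residue_sequence("AAA")
  x0 <- rbind(c(0, 0, 0), c(0.38, 0, 0), c(0.76, 0, 0))
  pr <- simulation_protocol(n_steps = 5e5, save_interval_ps = 2, seed = 11L)
  ens <- langevin_simulate(x0, s3, ff, pr)
  bl <- sqrt(rowSums((ens$xyz[, 1, ] - ens$xyz[, 2, ])^2))
  n <- length(bl)
  expect_equal(n, 5000L)
  # inverse-CDF sample of the quadrature density
  kBT <- 0.00831446261815324 * 298
  grid <- seq(0.25, 0.55, length.out = 4000)
  dens <- grid^2 * exp(-ff$k_bond * (grid - 0.38)^2 / (2 * kBT))
  cdf <- cumsum(dens); cdf <- cdf / cdf[length(cdf)]
  oracle <- approx(cdf, grid, xout = (seq_len(n) - 0.5) / n,
                   rule = 2)$y
  ks <- suppressWarnings(ks.test(bl, oracle)$statistic)
  expect_lt(ks, 0.05)
})

test_that("blow-ups are reported with the step index", {
  s2 <- residue_sequence("AA")
  x0 <- rbind(c(0, 0, 0), c(0.38, 0, 0))
  pr <- simulation_protocol(timestep = 50, n_steps = 1000L,
                            save_interval_ps = 5000, seed = 1L)
  expect_error(langevin_simulate(x0, s2, ff, pr), "blow-up.*step")
})
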