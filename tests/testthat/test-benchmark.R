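test_that("plateau detection reproduces the hand-worked scripted trace", {
  tr <- efficiency_trace(n = c(100, 200, 300, 400, 500, 600),
                         time_s = 1:6 / 10,
                         kld_r = c(0.5, 0.3, 0.2, 0.2, 0.2, 0.2),
                         source = "generator")
  res <- detect_plateau(tr, window = 300L)
  expect_true(res$converged)
  expect_equal(res$kld_r_top, 0.2)
  expect_equal(res$n_at_plateau, 300)
  expect_equal(res$t_gen, 0.3)
})

test_that("strictly decreasing traces are flagged not converged", {
  tr <- efficiency_trace(n = c(100, 200, 300, 400),
                         time_s = 1:4,
                         kld_r = c(0.5, 0.4, 0.3, 0.2),
                         source = "generator")
  res <- detect_plateau(tr, window = 200L)
  expect_false(res$converged)
  expect_equal(res$kld_r_top, 0.2)
})

test_that("constant traces plateau at the first point", {
  tr <- efficiency_trace(n = c(50, 100, 150), time_s = c(1, 2, 3),
                         kld_r = rep(0.33, 3), source = "generator")
  res <- detect_plateau(tr, window = 100L)
  expect_true(res$converged)
  expect_equal(res$n_at_plateau, 50)
  expect_equal(res$t_gen, 1)
})

test_that("crossing uses strict improvement over the plateau value", {
  sim <- efficiency_trace(n = c(100, 200, 300, 400),
                          time_s = c(10, 20, 30, 40),
                          kld_r = c(0.5, 0.3, 0.15, 0.1),
                          source = "simulator")
  res <- simulator_crossing_time(sim, kld_r_top = 0.2)
  expect_true(res$crossed)
  expect_equal(res$t_MD, 30)
  # a plateau of exactly zero can never be strictly improved upon
  res0 <- simulator_crossing_time(sim, kld_r_top = 0)
  expect_false(res0$crossed)
  expect_true(is.na(res0$t_MD))
  # crossing at the first point
  res1 <- simulator_crossing_time(sim, kld_r_top = 0.6)
  expect_equal(res1$t_MD, 10)
})

test_that("source types are enforced", {
  g <- efficiency_trace(1:3 * 100, 1:3, c(0.3, 0.2, 0.2), "generator")
  s <- efficiency_trace(1:3 * 100, 1:3, c(0.3, 0.2, 0.2), "simulator")
  expect_error(detect_plateau(s), "generator")
  expect_error(simulator_crossing_time(g, 0.1), "simulator")
  expect_error(efficiency_trace(c(100, 100), c(1, 2), c(0.1, 0.1),
                                "generator"), "increasing")
})

test_that("efficiency reports combine times and repeats", {
  plateau <- list(kld_r_top = 0.2, t_gen = 3, converged = TRUE)
  crossing <- list(t_MD = 300, crossed = TRUE)
  rep <- efficiency_report(list(), plateau, crossing,
                           repeats = c(80, 100, 120))
  expect_equal(rep$ratio, 100)
  expect_equal(rep$ratio_min, 80)
  expect_equal(rep$ratio_max, 120)
  # round-trips through JSON
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(unclass(rep), path, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(path)
  expect_equal(back$ratio, 100)
})

test_that("a reference compared with its own prefix trace reaches zero", {
  s <- make_fixture_sequences("polyAla", 20L)[[1]]
  ref <- random_ensemble(s, 400L, seed = 91L)
  tr <- kld_r_convergence_trace("simulator", ref,
                                sample_schedule = c(50L, 200L, 400L),
                                sim_ens = ref, time_per_frame = 0.5)
  expect_equal(nrow(tr), 3L)
  expect_equal(tr$kld_r[3], 0)          # full self-comparison
  expect_true(all(diff(tr$kld_r) <= 1e-9))
  expect_equal(tr$time_s, c(25, 100, 200))
  expect_error(kld_r_convergence_trace("simulator", ref, c(100L, 500L),
                                       sim_ens = ref), "exceeds")
})
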