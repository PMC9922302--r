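ff <- forcefield_parameters()

make_rigid_ensemble <- function(seq, conf, n) {
  conformational_ensemble(seq, replicate(n, conf, simplify = FALSE),
                          provenance = "fixture")
}

test_that("contact maps count threshold crossings per pair", {
  s <- residue_sequence("AAAA")
  near <- init_random_coordinates(s, 1L) * 0.9  # compact
  c1 <- rbind(c(0, 0, 0), c(0.38, 0, 0), c(0.5, 0.3, 0), c(0.3, 0.6, 0))
  c2 <- rbind(c(0, 0, 0), c(0.38, 0, 0), c(0.5, 0.3, 0), c(1.5, 1.5, 0))
  ens <- conformational_ensemble(s, list(c1, c2), provenance = "fixture")
  cm <- contact_map(ens)
  expect_equal(cm[1, 4], 0.5)   # pair under 0.8 nm in 1 of 2 frames
  expect_equal(cm[1, 3], 1)     # always in contact
  expect_true(isSymmetric(unclass(cm)[, ]))
  far <- conformational_ensemble(s, list(c2 * 3), provenance = "fixture")
  expect_equal(contact_map(far)[1, 4], 0)
})

test_that("contact-map MSE matches its hand-evaluated case", {
  # identical maps give zero
  s <- residue_sequence("AAAA")
  ens <- make_rigid_ensemble(s, init_random_coordinates(s, 2L), 3L)
  m <- contact_map(ens)
  expect_equal(mse_c(m, m), 0)
  # one pair 0.5 vs 0 (-> pseudo 0.01), remaining five pairs equal:
  # (ln 50)^2 / 6
  a <- b <- matrix(0.3, 4, 4)
  a[1, 2] <- a[2, 1] <- 0.5
  b[1, 2] <- b[2, 1] <- 0
  expect_equal(mse_c(a, b), log(50)^2 / 6, tolerance = 1e-12)
  expect_equal(mse_c(a, b), mse_c(b, a))
})

test_that("mean-distance MSE detects a constant shift", {
  s <- residue_sequence("AAA")
  c1 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  ens1 <- make_rigid_ensemble(s, c1, 2L)
  expect_equal(mse_d(ens1, ens1), 0)
  # scale all distances up by exactly 0.1 nm
  c2 <- c1 * (1 + 0.1 / 1)  # right triangle: sides 1,1,sqrt2 scale by 1.1
  ens2 <- make_rigid_ensemble(s, c2, 2L)
  d1 <- distance_features(c1)
  expect_equal(mse_d(ens1, ens2), mean((0.1 * d1)^2), tolerance = 1e-12)
})

test_that("histogram KLD reproduces the two-bin closed form", {
  # P = (0.5, 0.5), Q = (0.25, 0.75) with 2 bins
  ref <- c(rep(0.25, 5), rep(0.75, 5))
  gen <- c(rep(0.25, 3), rep(0.75, 9))
  kld <- histogram_kld(ref, gen, n_bins = 2L)
  expect_equal(kld, 0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-12)
  expect_equal(histogram_kld(ref, ref), 0)
  expect_warning(out <- histogram_kld(rep(1, 5), rep(1, 3)), "degenerate")
  expect_equal(as.numeric(out), 0)
})

test_that("histogram KLD respects Gibbs' inequality on random samples", {
  set.seed(99)
  for (i in 1:200) {
    a <- rnorm(50, sd = runif(1, 0.5, 2))
    b <- rnorm(50, mean = runif(1, -1, 1))
    expect_gte(histogram_kld(a, b), 0)
  }
})

test_that("radius of gyration matches hand geometry", {
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(1, 0, 0))), 0.5)
  sside <- 0.7
  tri <- rbind(c(0, 0, 0), c(sside, 0, 0),
               c(sside / 2, sside * sqrt(3) / 2, 0))
  expect_equal(radius_of_gyration(tri), sside / sqrt(3), tolerance = 1e-12)
  # ensemble helper agrees with the per-frame function
  s <- residue_sequence("AAA")
  ens <- conformational_ensemble(s, list(tri, tri * 2),
                                 provenance = "fixture")
  expect_equal(rg_values(ens), c(sside / sqrt(3), 2 * sside / sqrt(3)),
               tolerance = 1e-12)
})

test_that("dRMSD reproduces the triangle/collinear hand case", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  lin <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_equal(drmsd(tri, tri), 0)
  expect_equal(drmsd(tri, lin), sqrt(1 / 3), tolerance = 1e-12)
  # mirror images have identical internal distances
  expect_equal(drmsd(tri, reflect_conformation(tri)), 0)
  expect_error(drmsd(tri, tri[1:2, ]), "different lengths")
})

test_that("EMD-dRMSD is zero on identical and permuted ensembles", {
  s <- make_fixture_sequences("polyAla", 20L)[[1]]
  ens <- random_ensemble(s, 12L, seed = 20L)
  expect_equal(emd_drmsd(ens, ens), 0, tolerance = 1e-12)
  perm <- subset_frames(ens, sample(12L))
  expect_equal(emd_drmsd(ens, perm), 0, tolerance = 1e-12)
})

test_that("EMD-dRMSD equals the exhaustive-permutation minimum", {
  s <- residue_sequence("AAAAA")
  set.seed(7)
  for (trial in 1:10) {
    n <- sample(3:6, 1)
    a <- random_ensemble(s, n, seed = 100 + trial)
    b <- random_ensemble(s, n, seed = 200 + trial)
    expect_equal(emd_drmsd(a, b), brute_force_emd(a, b), tolerance = 1e-10)
  }
})

test_that("median energy difference has the right sign and zero point", {
  s <- make_fixture_sequences("polyAla", 20L)[[1]]
  ens <- random_ensemble(s, 9L, seed = 30L)
  expect_equal(median_energy_difference(ens, ens, s, ff), 0)
  # compressing coordinates creates clashes -> higher generated energies
  squeezed <- conformational_ensemble(s, ens$xyz * 0.55,
                                      provenance = "generated")
  expect_gt(median_energy_difference(ens, squeezed, s, ff), 0)
})

test_that("PCA free-energy maps are reference-anchored", {
  s <- make_fixture_sequences("polyAla", 20L)[[1]]
  ref <- random_ensemble(s, 80L, seed = 40L)
  maps <- pca_pmf(ref, ref, bins = 12L)
  expect_equal(maps$reference$F, maps$query$F)
  expect_gte(maps$reference$explained[1], maps$reference$explained[2])
  # empty cells are missing, not infinite
  expect_true(all(is.na(maps$reference$F) |
                    is.finite(maps$reference$F)))
})

test_that("memorization search finds planted training frames", {
  s <- make_fixture_sequences("polyAla", 20L)[[1]]
  train <- random_ensemble(s, 15L, seed = 50L)
  # generated set = 3 copies of training frames + 2 fresh shapes
  gen <- conformational_ensemble(
    s, c(lapply(1:3, function(i) get_frame(train, i)),
         lapply(1:2, function(i) get_frame(random_ensemble(s, 2L, 999L), i))),
    provenance = "generated")
  nn <- memorization_search(gen, list(train), crop_len = 20L)
  expect_length(nn, 5L)
  expect_equal(nn[1:3], rep(0, 3), tolerance = 1e-12)
  expect_true(all(nn[4:5] > 0))
})

test_that("all six metrics vanish on a self-comparison", {
  s <- make_fixture_sequences("charge_blocks", 20L)[[1]]
  ens <- random_ensemble(s, 25L, seed = 60L)
  rep <- metric_report(ens, ens, s, ff)
  expect_equal(rep$MSE_c, 0)
  expect_equal(rep$MSE_d, 0)
  expect_equal(rep$aKLD_d, 0)
  expect_equal(rep$EMD_dRMSD, 0, tolerance = 1e-12)
  expect_equal(rep$KLD_r, 0)
  expect_equal(rep$MED, 0)
})

test_that("metrics are invariant to rigid motion and reflection", {
  s <- make_fixture_sequences("charge_blocks", 20L)[[1]]
  ens <- random_ensemble(s, 10L, seed = 70L)
  moved <- ens
  for (i in 1:10)
    moved$xyz[i, , ] <- random_rigid_motion(get_frame(ens, i), 300 + i,
                                            reflect = i %% 2 == 0)
  expect_lt(mse_c(contact_map(ens), contact_map(moved)), 1e-12)
  expect_lt(mse_d(ens, moved), 1e-18)
  expect_lt(akld_d(ens, moved), 1e-12)
  expect_equal(as.numeric(kld_r(ens, moved)), 0, tolerance = 1e-12)
  expect_equal(median_energy_difference(ens, moved, s, ff), 0,
               tolerance = 1e-7)
})
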