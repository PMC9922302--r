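# Ensemble-comparison metric suite: contact-map MSE, mean-distance MSE,
# histogram Kullback-Leibler divergences (per-pair distances and radius of
# gyration), Hungarian-matched EMD-dRMSD, and median energy differences.
# All metrics are purely distance-based and therefore invariant to rigid
# motions and reflections of every conformation.

#' Residue contact map of an ensemble
#'
#' @param ens A [conformational_ensemble()].
#' @param threshold Contact distance threshold, nm (default 0.8 nm = 8 A).
#' @return Object of class `contact_map`: the `L x L` symmetric matrix of
#'   contact frequencies (diagonal `NA`), with the threshold as attribute.
#' @export
contact_map <- function(ens, threshold = 0.8) {
  L <- dim(ens$xyz)[2L]
  idx <- pair_index(L)
  d <- ensemble_distances(ens)
  p <- colMeans(d < threshold)
  m <- matrix(NA_real_, L, L)
  m[idx[, c("i", "j")]] <- p
  m[idx[, c("j", "i")]] <- p
  structure(m, threshold = threshold, class = c("contact_map", "matrix"))
}

#' Contact-map mean squared error (log scale)
#'
#' Mean over residue pairs of the squared difference of log contact
#' frequencies, with zero frequencies replaced by a pseudo-count.
#'
#' @param ref,gen [contact_map()] objects of equal size.
#' @param pseudo Pseudo-count substituted for zero frequencies.
#' @return Non-negative scalar.
#' @export
mse_c <- function(ref, gen, pseudo = 0.01) {
  if (!all(dim(ref) == dim(gen)))
    stop("contact maps have different lengths")
  idx <- pair_index(nrow(ref))
  p <- ref[idx[, c("i", "j")]]
  q <- gen[idx[, c("i", "j")]]
  p[p == 0] <- pseudo
  q[q == 0] <- pseudo
  mean((log(p) - log(q))^2)
}

#' Mean-distance mean squared error
#'
#' Mean over residue pairs of the squared difference of average pair
#' distances between two ensembles.
#'
#' @param ref_ens,gen_ens [conformational_ensemble()] objects with equal
#'   sequence length.
#' @return Non-negative scalar, nm^2.
#' @export
mse_d <- function(ref_ens, gen_ens) {
  if (dim(ref_ens$xyz)[2L] != dim(gen_ens$xyz)[2L])
    stop("ensembles have different sequence lengths")
  m <- colMeans(ensemble_distances(ref_ens))
  mh <- colMeans(ensemble_distances(gen_ens))
  mean((m - mh)^2)
}

#' Approximate histogram Kullback-Leibler divergence
#'
#' The shared range (pooled minimum to maximum over both samples) is split
#' into `n_bins` equal-width bins; frequencies are counts over sample size,
#' zero frequencies are replaced by `pseudo` (without renormalizing), and
#' `KLD = sum P_k log(P_k / Q_k)` with P from the reference sample.
#'
#' @param ref_values,gen_values Numeric samples (reference, generated).
#' @param n_bins Number of bins.
#' @param pseudo Pseudo-count substituted for zero frequencies.
#' @return Scalar divergence. A degenerate pooled range (min == max)
#'   returns 0 with attribute `degenerate = TRUE` and a warning.
#' @export
histogram_kld <- function(ref_values, gen_values, n_bins = 50L,
                          pseudo = 0.001) {
  stopifnot(length(ref_values) > 0L, length(gen_values) > 0L)
  lo <- min(ref_values, gen_values)
  hi <- max(ref_values, gen_values)
  if (hi <= lo) {
    warning("degenerate value range in histogram KLD; returning 0")
    return(structure(0, degenerate = TRUE))
  }
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  bin_of <- function(x) pmin(pmax(findInterval(x, breaks,
                                               rightmost.closed = TRUE), 1L),
                             n_bins)
  P <- tabulate(bin_of(ref_values), nbins = n_bins) / length(ref_values)
  Q <- tabulate(bin_of(gen_values), nbins = n_bins) / length(gen_values)
  P[P == 0] <- pseudo
  Q[Q == 0] <- pseudo
  sum(P * log(P / Q))
}

#' Average per-pair distance-distribution divergence
#'
#' Mean of [histogram_kld()] over the `L(L-1)/2` pair distance
#' distributions of two ensembles.
#'
#' @inheritParams mse_d
#' @param n_bins,pseudo Passed to [histogram_kld()].
#' @return Scalar.
#' @export
akld_d <- function(ref_ens, gen_ens, n_bins = 50L, pseudo = 0.001) {
  if (dim(ref_ens$xyz)[2L] != dim(gen_ens$xyz)[2L])
    stop("ensembles have different sequence lengths")
  dr <- ensemble_distances(ref_ens)
  dg <- ensemble_distances(gen_ens)
  vals <- vapply(seq_len(ncol(dr)), function(p)
    suppressWarnings(as.numeric(histogram_kld(dr[, p], dg[, p],
                                              n_bins, pseudo))),
    numeric(1L))
  mean(vals)
}

#' Radius of gyration of a C-alpha conformation
#'
#' Unweighted: the root mean squared distance of the beads from their
#' centroid.
#'
#' @param conf `L x 3` coordinate matrix, nm.
#' @return Scalar, nm.
#' @export
radius_of_gyration <- function(conf) {
  conf <- as.matrix(conf)
  c0 <- colMeans(conf)
  sqrt(mean(rowSums((conf - matrix(c0, nrow(conf), 3L, byrow = TRUE))^2)))
}

#' Radii of gyration over an ensemble
#' @param ens A [conformational_ensemble()].
#' @return Numeric vector, one value per frame (nm).
#' @export
rg_values <- function(ens) {
  xyz <- ens$xyz
  n <- dim(xyz)[1L]
  ctr <- apply(xyz, c(1L, 3L), mean)             # n x 3 centroids
  dev <- sweep(xyz, c(1L, 3L), ctr, "-")
  sqrt(apply(dev^2, 1L, mean) * 3)               # mean over L*3 -> *3
}

#' Radius-of-gyration distribution divergence
#'
#' [histogram_kld()] between the radius-of-gyration samples of two
#' ensembles, reference first.
#'
#' @inheritParams akld_d
#' @return Scalar.
#' @export
kld_r <- function(ref_ens, gen_ens, n_bins = 50L, pseudo = 0.001) {
  histogram_kld(rg_values(ref_ens), rg_values(gen_ens), n_bins, pseudo)
}

#' Distance RMSD between two conformations
#'
#' Root of the mean squared difference over all residue pairs of the two
#' internal distance sets; superposition-free and blind to reflections.
#'
#' @param a,b `L x 3` coordinate matrices of equal length, nm.
#' @return Scalar, nm.
#' @export
drmsd <- function(a, b) {
  if (nrow(a) != nrow(b)) stop("conformations have different lengths")
  da <- distance_features(a)
  db <- distance_features(b)
  sqrt(mean((da - db)^2))
}

# n_a x n_b dRMSD matrix from distance-feature matrices (Gram trick)
drmsd_matrix <- function(feat_a, feat_b) {
  P <- ncol(feat_a)
  g <- tcrossprod(feat_a, feat_b)
  s2 <- outer(rowSums(feat_a^2), rowSums(feat_b^2), "+") - 2 * g
  sqrt(pmax(s2, 0) / P)
}

#' Earth mover's distance between ensembles via dRMSD
#'
#' Both ensembles are subsampled (seeded) to the same size
#' `min(n_ref, n_gen, max_n)`; the Hungarian algorithm then pairs each
#' reference conformation with a generated one minimizing the total dRMSD,
#' and the mean dRMSD over matched pairs is returned.
#'
#' @inheritParams mse_d
#' @param max_n Subsample cap for the assignment problem.
#' @param seed Integer seed for the subsampling.
#' @return Scalar, nm.
#' @export
emd_drmsd <- function(ref_ens, gen_ens, max_n = 1000L, seed = 1L) {
  if (dim(ref_ens$xyz)[2L] != dim(gen_ens$xyz)[2L])
    stop("ensembles have different sequence lengths")
  n <- min(n_frames(ref_ens), n_frames(gen_ens), max_n)
  rng <- local_rng(seed)
  ir <- if (n_frames(ref_ens) > n) rng$sample_int(n_frames(ref_ens), n)
        else seq_len(n_frames(ref_ens))
  ig <- if (n_frames(gen_ens) > n) rng$sample_int(n_frames(gen_ens), n)
        else seq_len(n_frames(gen_ens))
  fr <- ensemble_distances(subset_frames(ref_ens, ir))
  fg <- ensemble_distances(subset_frames(gen_ens, ig))
  cost <- drmsd_matrix(fr, fg)
  assign <- cpp_hungarian(cost)
  # exact per-pair recomputation (the Gram-trick cost matrix carries ~1e-8
  # cancellation noise, enough to blur the self-comparison zero)
  mean(sqrt(rowMeans((fr - fg[assign, , drop = FALSE])^2)))
}

#' Median energy difference between ensembles
#'
#' Median total coarse-grained potential energy of the generated ensemble
#' minus that of the reference ensemble.
#'
#' @inheritParams mse_d
#' @param seq [residue_sequence()] shared by both ensembles.
#' @param ff [forcefield_parameters()].
#' @return Scalar, kJ/mol (can be negative).
#' @export
median_energy_difference <- function(ref_ens, gen_ens, seq,
                                     ff = forcefield_parameters()) {
  median(ensemble_energies(gen_ens, ff)) - median(ensemble_energies(ref_ens, ff))
}

#' Potential of mean force in reference PCA space
#'
#' Fits a PCA basis on the reference ensemble's interatomic distance
#' features only, projects both ensembles onto the first two components,
#' and converts normalized cell frequencies on a 2-D grid (spanning the
#' reference projection range) into free energies `-kB T ln(frequency)`.
#' Empty cells are `NA`, not infinite.
#'
#' @param ref_ens Reference [conformational_ensemble()] (defines the
#'   basis and the grid).
#' @param query_ens Ensemble to project onto the reference basis.
#' @param bins Grid resolution per component.
#' @param temperature Temperature for the free-energy scale, K.
#' @return List of two `pmf_map` objects (`reference`, `query`), each with
#'   elements `F` (bins x bins free-energy matrix, kJ/mol), `xbreaks`,
#'   `ybreaks`, and the explained variance of the two components.
#' @export
pca_pmf <- function(ref_ens, query_ens, bins = 40L, temperature = 298) {
  fr <- ensemble_distances(ref_ens)
  if (nrow(fr) < 3L) stop("reference ensemble too small to fit 2 components")
  pc <- prcomp(fr, center = TRUE, scale. = FALSE, rank. = 2L)
  if (ncol(pc$rotation) < 2L || pc$sdev[2L] <= 0)
    stop("reference distance features are rank-deficient")
  proj_r <- pc$x[, 1:2, drop = FALSE]
  fq <- ensemble_distances(query_ens)
  proj_q <- scale(fq, center = pc$center, scale = FALSE) %*% pc$rotation[, 1:2]
  xb <- seq(min(proj_r[, 1L]), max(proj_r[, 1L]), length.out = bins + 1L)
  yb <- seq(min(proj_r[, 2L]), max(proj_r[, 2L]), length.out = bins + 1L)
  grid_pmf <- function(p) {
    ix <- pmin(pmax(findInterval(p[, 1L], xb, rightmost.closed = TRUE), 0L), bins)
    iy <- pmin(pmax(findInterval(p[, 2L], yb, rightmost.closed = TRUE), 0L), bins)
    keep <- ix >= 1L & iy >= 1L
    counts <- matrix(0, bins, bins)
    if (any(keep)) {
      tab <- table(factor(ix[keep], levels = seq_len(bins)),
                   factor(iy[keep], levels = seq_len(bins)))
      counts <- matrix(as.numeric(tab), bins, bins)
    }
    freq <- counts / nrow(p)
    Fmap <- -KB_KJ * temperature * log(freq)
    Fmap[counts == 0] <- NA_real_
    structure(list(F = Fmap, xbreaks = xb, ybreaks = yb,
                   explained = pc$sdev[1:2]^2 / sum(pc$sdev^2)),
              class = "pmf_map")
  }
  list(reference = grid_pmf(proj_r), query = grid_pmf(proj_q))
}

#' Nearest-neighbor memorization search
#'
#' For each generated conformation, the minimum dRMSD to any conformation
#' in the training pool, after cropping everything to a common length
#' (first `crop_len` residues). Comparing this sample against the same
#' search run with held-out simulation frames reveals memorization.
#'
#' @param gen_ens Generated [conformational_ensemble()].
#' @param training_ensembles List of [conformational_ensemble()] objects
#'   forming the training pool.
#' @param crop_len Common crop length; all ensembles must be at least this
#'   long.
#' @return Numeric vector of nearest-neighbor dRMSD values (nm), one per
#'   generated conformation.
#' @export
memorization_search <- function(gen_ens, training_ensembles, crop_len) {
  if (length(training_ensembles) == 0L) stop("empty training pool")
  crop <- function(ens) {
    L <- dim(ens$xyz)[2L]
    if (L < crop_len) stop("ensemble shorter than the crop length")
    conformational_ensemble(
      residue_sequence(ens$sequence$letters[seq_len(crop_len)],
                       id = ens$sequence$id),
      ens$xyz[, seq_len(crop_len), , drop = FALSE],
      provenance = ens$provenance)
  }
  fg <- ensemble_distances(crop(gen_ens))
  best <- rep(Inf, nrow(fg))
  for (tr in training_ensembles) {
    ft <- ensemble_distances(crop(tr))
    cm <- drmsd_matrix(fg, ft)
    nn <- max.col(-cm)  # per-row argmin
    exact <- sqrt(rowMeans((fg - ft[nn, , drop = FALSE])^2))
    best <- pmin(best, exact)
  }
  best
}

#' Full six-score comparison record for an ensemble pair
#'
#' @inheritParams median_energy_difference
#' @param max_n,seed Passed to [emd_drmsd()].
#' @return Object of class `metric_report`: list with `MSE_c`, `MSE_d`,
#'   `aKLD_d`, `EMD_dRMSD`, `KLD_r`, `MED` and the two sample sizes.
#' @export
metric_report <- function(ref_ens, gen_ens, seq, ff = forcefield_parameters(),
                          max_n = 1000L, seed = 1L) {
  rep <- list(
    MSE_c = mse_c(contact_map(ref_ens), contact_map(gen_ens)),
    MSE_d = mse_d(ref_ens, gen_ens),
    aKLD_d = akld_d(ref_ens, gen_ens),
    EMD_dRMSD = emd_drmsd(ref_ens, gen_ens, max_n = max_n, seed = seed),
    KLD_r = as.numeric(kld_r(ref_ens, gen_ens)),
    MED = median_energy_difference(ref_ens, gen_ens, seq, ff),
    n_ref = n_frames(ref_ens), n_gen = n_frames(gen_ens), seed = seed)
  class(rep) <- "metric_report"
  rep
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(paste0("MSE_c %.4f | MSE_d %.5f nm^2 | aKLD_d %.4f | ",
                     "EMD-dRMSD %.4f nm | KLD_r %.4f | MED %.3f kJ/mol\n"),
              x$MSE_c, x$MSE_d, x$aKLD_d, x$EMD_dRMSD, x$KLD_r, x$MED))
  invisible(x)
}
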