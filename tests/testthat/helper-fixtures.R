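# Programmatic fixtures: random ensembles and synthetic chiral traces.

random_ensemble <- function(seq, n, seed, spread = 0.3) {
  rng_seed <- seed
  L <- length(seq)
  confs <- lapply(seq_len(n), function(i) {
    init_random_coordinates(seq, seed = rng_seed + i) +
      matrix(stats::rnorm(L * 3, sd = spread * 0.02), L, 3)
  })
  conformational_ensemble(seq, confs, provenance = "fixture")
}

# Build a C-alpha trace from internal coordinates (bond, angle, torsion)
# by sequential extension; used to construct chiral ensembles with a
# controlled torsion-sign distribution.
trace_from_internal <- function(bonds, angles, torsions) {
  L <- length(bonds) + 1L
  x <- matrix(0, L, 3)
  x[2, ] <- c(bonds[1], 0, 0)
  if (L >= 3) {
    th <- angles[1]
    x[3, ] <- x[2, ] + bonds[2] * c(-cos(th), sin(th), 0)
  }
  if (L >= 4) for (i in 4:L) {
    b <- bonds[i - 1]
    th <- angles[i - 2]
    ph <- torsions[i - 3]
    A <- x[i - 3, ]; B <- x[i - 2, ]; C <- x[i - 1, ]
    bc <- C - B; bc <- bc / sqrt(sum(bc^2))
    ab <- B - A
    n <- c(ab[2] * bc[3] - ab[3] * bc[2],
           ab[3] * bc[1] - ab[1] * bc[3],
           ab[1] * bc[2] - ab[2] * bc[1])
    n <- n / sqrt(sum(n^2))
    m <- c(n[2] * bc[3] - n[3] * bc[2],
           n[3] * bc[1] - n[1] * bc[3],
           n[1] * bc[2] - n[2] * bc[1])
    d2 <- b * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
    x[i, ] <- C + bc * d2[1] + m * d2[2] + n * d2[3]
  }
  x
}

# ensemble of synthetic chiral traces: torsion magnitudes ~ N(0.9, 0.3),
# sign positive with probability sign_bias
chiral_ensemble <- function(L = 20L, n = 60L, sign_bias = 0.9, seed = 1L) {
  set.seed(seed)
  seq <- residue_sequence(strrep("A", L), id = sprintf("chiral_%d", L))
  confs <- lapply(seq_len(n), function(i) {
    bonds <- rep(0.38, L - 1L)
    angles <- rnorm(L - 2L, mean = 1.9, sd = 0.15)
    mag <- abs(rnorm(L - 3L, mean = 0.9, sd = 0.3))
    sgn <- ifelse(runif(L - 3L) < sign_bias, 1, -1)
    trace_from_internal(bonds, angles, sgn * mag)
  })
  conformational_ensemble(seq, confs, provenance = "fixture")
}

# fraction of positive torsions pooled over an ensemble
torsion_sign_fraction <- function(ens) {
  vals <- unlist(lapply(seq_len(n_frames(ens)), function(i)
    as.numeric(ca_torsions(get_frame(ens, i)))))
  mean(vals > 0, na.rm = TRUE)
}
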