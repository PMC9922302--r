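# Independent oracles, written against the model definition directly and
# kept free of the package's optimized code paths.

# Naive double-loop evaluator of the four-term potential in plain R.
naive_cg_energy <- function(conf, seq, ff) {
  L <- nrow(conf)
  lets <- seq$letters
  sigma <- ff$sigma_per_residue[lets]
  eps <- ifelse(ff$polar[lets], ff$eps_polar, ff$eps_nonpolar)
  q <- ff$charge_per_residue[lets]
  A <- sign(q) * sqrt(0.75 * abs(q))
  A0 <- ifelse(ff$polar[lets], ff$A0_polar, 0)
  basic <- lets %in% c("R", "K")
  arom <- lets %in% c("F", "Y", "W")
  e_bond <- 0
  for (i in 1:(L - 1)) {
    l <- sqrt(sum((conf[i + 1, ] - conf[i, ])^2))
    e_bond <- e_bond + 0.5 * ff$k_bond * (l - ff$l0)^2
  }
  e_angle <- 0
  if (L >= 3) for (i in 1:(L - 2)) {
    u <- conf[i, ] - conf[i + 1, ]
    v <- conf[i + 2, ] - conf[i + 1, ]
    th <- acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
    e_angle <- e_angle + 0.5 * ff$k_angle * (th - ff$theta0)^2
  }
  e_short <- 0
  e_long <- 0
  mi <- function(d) d - ff$box_edge * round(d / ff$box_edge)
  for (i in 1:L) for (j in 1:L) {
    if (j <= i + 1) next  # each pair once; bonded neighbors excluded
    r <- sqrt(sum(mi(conf[j, ] - conf[i, ])^2))
    if (r > ff$cutoff) next
    epsij <- (eps[i] + eps[j]) / 2
    if ((basic[i] && arom[j]) || (arom[i] && basic[j]))
      epsij <- epsij + ff$eps_cation_pi
    sij <- sigma[i] + sigma[j]
    e_short <- e_short + 4 * epsij * ((sij / r)^10 - (sij / r)^5)
    e_long <- e_long + (A[i] * A[j] + A0[i] * A0[j]) / r * exp(-r / ff$kappa)
  }
  list(bond = e_bond, angle = e_angle, short_range = e_short,
       long_range = e_long, total = e_bond + e_angle + e_short + e_long)
}

# Exhaustive minimal-assignment mean dRMSD for tiny ensembles.
brute_force_emd <- function(ref_ens, gen_ens) {
  n <- n_frames(ref_ens)
  stopifnot(n == n_frames(gen_ens), n <= 7)
  cost <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in 1:n)
    cost[i, j] <- drmsd(get_frame(ref_ens, i), get_frame(gen_ens, j))
  perms <- all_perms(n)
  best <- Inf
  for (p in perms) best <- min(best, mean(cost[cbind(1:n, p)]))
  best
}

all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in all_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}

# Boltzmann quadrature for the dimer bond-length distribution
# p(l) ~ l^2 exp(-k (l - l0)^2 / (2 kB T))
dimer_bond_oracle <- function(ff, temperature = 298) {
  kBT <- 0.00831446261815324 * temperature
  f <- function(l) l^2 * exp(-ff$k_bond * (l - ff$l0)^2 / (2 * kBT))
  Z <- integrate(f, 0, 1)$value
  m <- integrate(function(l) l * f(l), 0, 1)$value / Z
  m2 <- integrate(function(l) l^2 * f(l), 0, 1)$value / Z
  list(mean = m, var = m2 - m^2)
}

random_test_system <- function(L, seed, spread = 0.5) {
  set.seed(seed)
  s <- residue_sequence(paste(sample(AA_ALPHABET, L, replace = TRUE),
                              collapse = ""), id = paste0("rnd", seed))
  x <- init_random_coordinates(s, seed = seed) +
    matrix(rnorm(L * 3, sd = spread * 0.05), L, 3)
  list(seq = s, conf = x)
}

random_rigid_motion <- function(conf, seed, reflect = FALSE) {
  set.seed(seed)
  q <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(q))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  if (reflect) Q[, 3] <- -Q[, 3]
  t0 <- rnorm(3, sd = 2)
  sweep(conf %*% Q, 2, t0, "+")
}
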