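# Training objectives: the non-saturated adversarial pair, the hinge
# variant with top-k generator updates, the Wasserstein critic with
# gradient penalty, and the stereochemical clash term added to every
# generator loss.

#' Stereochemical clash penalty of a conformation
#'
#' Sum of `max(x_t - x_j, 0)` over all non-bonded distances, where
#' non-bonded means residue pairs three or more positions apart. Zero iff
#' no such distance falls below the threshold.
#'
#' @param x Distance feature vector (see [distance_features()]), nm.
#' @param L Chain length consistent with `length(x) = L(L-1)/2`.
#' @param x_t Clash threshold, nm.
#' @return Non-negative scalar (nm).
#' @export
clash_penalty <- function(x, L, x_t = 0.59) {
  idx <- pair_index(L)
  if (length(x) != nrow(idx))
    stop("feature vector length inconsistent with L")
  nb <- idx[, "sep"] >= 3L
  sum(pmax(x_t - x[nb], 0))
}

# vectorized version over a feature batch + its gradient w.r.t. x
clash_penalty_batch <- function(X, L, x_t) {
  nb <- pair_index(L)[, "sep"] >= 3L
  V <- pmax(x_t - sweep(X[, nb, drop = FALSE], 2L, 0, "+"), 0)
  grad <- matrix(0, nrow(X), ncol(X))
  grad[, nb] <- -(V > 0)
  list(value = rowSums(V), grad = grad)
}

#' Fraction of clashing non-bonded distances
#'
#' Fraction of all pair distances with sequence separation of at least 3
#' that fall below the threshold, pooled over the ensemble.
#'
#' @param ens A [conformational_ensemble()].
#' @param x_t Threshold, nm.
#' @return Scalar in `[0, 1]`.
#' @export
clash_fraction <- function(ens, x_t = 0.59) {
  L <- dim(ens$xyz)[2L]
  nb <- pair_index(L)[, "sep"] >= 3L
  if (!any(nb)) return(0)
  d <- ensemble_distances(ens)[, nb, drop = FALSE]
  mean(d < x_t)
}

#' Estimate the clash threshold from training data
#'
#' The 0.1 percentile (0.001 quantile, linear interpolation) of all
#' non-bonded (separation >= 3) pair distances pooled over the supplied
#' ensembles.
#'
#' @param ensembles List of [conformational_ensemble()] objects.
#' @return Threshold `x_t`, nm.
#' @export
estimate_clash_threshold <- function(ensembles) {
  if (inherits(ensembles, "conformational_ensemble"))
    ensembles <- list(ensembles)
  pool <- unlist(lapply(ensembles, function(ens) {
    L <- dim(ens$xyz)[2L]
    nb <- pair_index(L)[, "sep"] >= 3L
    if (!any(nb)) return(numeric(0L))
    as.numeric(ensemble_distances(ens)[, nb])
  }))
  if (length(pool) == 0L) stop("no non-bonded distances in the pool")
  unname(quantile(pool, probs = 0.001, type = 7))
}

#' Discriminator / critic loss
#'
#' @param real_out,fake_out Discriminator outputs on the real and
#'   generated batch: probabilities in non-saturated mode, raw scores in
#'   hinge and Wasserstein modes.
#' @param mode `"nonsaturated"`, `"hinge_topk"` or `"wasserstein_gp"`.
#' @param gp Gradient-penalty value to add in Wasserstein mode (already
#'   scaled by lambda).
#' @return Scalar loss.
#' @export
loss_discriminator <- function(real_out, fake_out,
                               mode = c("nonsaturated", "hinge_topk",
                                        "wasserstein_gp"),
                               gp = 0) {
  mode <- match.arg(mode)
  switch(mode,
    nonsaturated = {
      if (any(real_out <= 0 | real_out >= 1 | fake_out <= 0 | fake_out >= 1))
        stop("non-saturated mode needs probabilities strictly inside (0, 1)")
      -mean(log(real_out)) - mean(log(1 - fake_out))
    },
    hinge_topk = mean(pmax(1 - real_out, 0)) + mean(pmax(1 + fake_out, 0)),
    wasserstein_gp = mean(fake_out) - mean(real_out) + gp)
}

#' Generator loss
#'
#' Adversarial term per mode plus `w_C` times the mean clash penalty of the
#' generated batch. In `hinge_topk` mode only the `ceiling(nu * batch)`
#' highest-scoring generated samples enter the adversarial term (never
#' fewer than one).
#'
#' @param fake_out Discriminator outputs on the generated batch
#'   (probabilities in non-saturated mode, scores otherwise).
#' @param clash Per-sample clash penalties `E_C` for the same batch.
#' @param mode Objective mode.
#' @param w_C Clash weight (>= 0).
#' @param nu Top-k fraction currently in effect (ignored outside
#'   `hinge_topk`).
#' @return Scalar loss with attribute `topk_idx` (indices used by the
#'   adversarial term).
#' @export
loss_generator <- function(fake_out, clash,
                           mode = c("nonsaturated", "hinge_topk",
                                    "wasserstein_gp"),
                           w_C = 0.3, nu = 1) {
  mode <- match.arg(mode)
  if (w_C < 0) stop("w_C must be non-negative")
  n <- length(fake_out)
  idx <- seq_len(n)
  if (mode == "hinge_topk") {
    k <- max(1L, ceiling(nu * n))
    idx <- order(fake_out, decreasing = TRUE)[seq_len(k)]
  }
  adv <- switch(mode,
    nonsaturated = {
      if (any(fake_out <= 0 | fake_out >= 1))
        stop("non-saturated mode needs probabilities strictly inside (0, 1)")
      -mean(log(fake_out))
    },
    hinge_topk = -mean(fake_out[idx]),
    wasserstein_gp = -mean(fake_out))
  structure(adv + w_C * mean(clash), topk_idx = idx)
}

# Wasserstein gradient penalty on interpolates: lambda * E[(||g|| - 1)^2]
# with g the critic gradient w.r.t. its input features. Returns the
# penalty value and its gradient w.r.t. the critic weights (exact almost
# everywhere for the piecewise-linear critic).
gradient_penalty <- function(weights, arch, Xr, Xf, env, lambda, rng) {
  n <- nrow(Xr)
  t <- rng$unif(n)
  Xi <- Xr * t + Xf * (1 - t)
  fw <- disc_fwd(weights, arch, Xi, env, update = FALSE)
  g <- disc_input_grad(fw$cache, arch)       # n x d_in
  gn <- sqrt(rowSums(g * g)) + 1e-12
  pen <- lambda * mean((gn - 1)^2)
  # d pen / d g = lambda * 2 (gn - 1) / (n * gn) * g  (row-wise)
  u <- g * (2 * lambda * (gn - 1) / (n * gn))
  # backprop u through g = W1sn^T D1 W2sn^T D2 w3sn (activation patterns
  # D1, D2 fixed); accumulate gradients for the three weight matrices.
  c1 <- cache_act_derivs(fw$cache, arch)
  # forward chain pieces
  W1 <- fw$cache$s1$Wsn; W2 <- fw$cache$s2$Wsn; W3 <- fw$cache$s3$Wsn
  # per-sample: g_i = W1 d1_i; with d1_i = D1_i W2 (D2_i w3)
  D1 <- c1$d1; D2 <- c1$d2                   # n x h1, n x h2 derivative masks
  w3 <- as.numeric(W3)                       # h2
  d2v <- sweep(D2, 2L, w3, "*")              # n x h2 = D2 w3
  d1v <- D1 * (d2v %*% t(W2))                # n x h1
  # grads
  r <- (u %*% W1) * D1                       # n x h1   (= D1 W1^T u)
  gW1 <- crossprod(u, d1v)                   # d_in x h1: sum_i u_i d1_i^T
  gW2 <- crossprod(r, d2v)                   # h1 x h2
  gW3 <- matrix(colSums((r %*% W2) * D2), ncol = 1L)  # h2 x 1
  grad <- list(l1 = list(W = sn_grad(gW1, fw$cache$s1),
                         b = rep(0, length(weights$l1$b))),
               l2 = list(W = sn_grad(gW2, fw$cache$s2),
                         b = rep(0, length(weights$l2$b))),
               l3 = list(W = sn_grad(gW3, fw$cache$s3),
                         b = rep(0, length(weights$l3$b))))
  list(value = pen, grad = grad)
}

cache_act_derivs <- function(cache, arch) {
  s <- arch$leaky_slope
  list(d1 = cache$a1$mask + s * (1 - cache$a1$mask),
       d2 = cache$a2$mask + s * (1 - cache$a2$mask))
}
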