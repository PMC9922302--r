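# C-alpha pseudo-torsion handedness tools. The coarse-grained potential is
# achiral, but C-alpha traces of real proteins have a chiral torsion
# distribution; generated traces can therefore come out as either mirror
# image and are post-processed with a selector network.

#' C-alpha pseudo-torsions of a conformation
#'
#' Dihedral angles over all consecutive C-alpha quadruplets
#' `(i, i+1, i+2, i+3)`, in `(-pi, pi]`. The sign convention is pinned by
#' the reference quadruplet `(0,0,0), (1,0,0), (1,1,0), (1,1,1)`, which
#' yields `+pi/2`; reflecting a conformation negates every torsion.
#' Quadruplets containing a collinear triple give `NA`, not 0.
#'
#' @param conf `L x 3` coordinate matrix with `L >= 4`.
#' @return Numeric vector of `L - 3` angles (radians), class
#'   `torsion_profile`.
#' @export
ca_torsions <- function(conf) {
  conf <- as.matrix(conf)
  L <- nrow(conf)
  if (L < 4L) stop("pseudo-torsions need at least 4 residues")
  b1 <- conf[2:(L - 2L), , drop = FALSE] - conf[1:(L - 3L), , drop = FALSE]
  b2 <- conf[3:(L - 1L), , drop = FALSE] - conf[2:(L - 2L), , drop = FALSE]
  b3 <- conf[4:L, , drop = FALSE] - conf[3:(L - 1L), , drop = FALSE]
  cross <- function(a, b)
    cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
          a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
          a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  nb2 <- sqrt(rowSums(b2^2))
  y <- rowSums(n1 * b3) * nb2
  x <- rowSums(n1 * n2)
  ang <- atan2(y, x)
  # collinear triple -> zero normal -> undefined angle
  bad <- rowSums(n1^2) < 1e-20 | rowSums(n2^2) < 1e-20
  ang[bad] <- NA_real_
  structure(ang, class = "torsion_profile")
}

#' Reflect a conformation
#'
#' Mirrors the conformation through the xy-plane (negates z). All pairwise
#' distances are preserved exactly; all pseudo-torsions change sign.
#'
#' @param conf `L x 3` coordinate matrix.
#' @return Reflected `L x 3` matrix.
#' @export
reflect_conformation <- function(conf) {
  conf <- as.matrix(conf)
  conf[, 3L] <- -conf[, 3L]
  conf
}

# torsion profile -> (sin, cos) feature rows, NA -> 0
torsion_embed <- function(tor) {
  tor <- as.numeric(tor)
  tor[is.na(tor)] <- 0
  cbind(sin(tor), cos(tor))
}

#' Train the mirror-image selector network
#'
#' A binary classifier on C-alpha pseudo-torsion profiles: each torsion is
#' embedded as its sine/cosine pair, processed by the generator-style
#' transformer trunk, mean-pooled, and mapped to a handedness probability.
#' Training pairs every conformation of the supplied (chiral) ensembles
#' with its mirror image as negative example. If the training data is
#' achiral the selector cannot beat chance and refuses to certify.
#'
#' @param chiral_ensembles List of [conformational_ensemble()] objects
#'   with a chiral torsion distribution (for tests, synthetic traces with
#'   a torsion-sign bias).
#' @param epochs,batch,lr,seed Training hyperparameters.
#' @param d_model,n_blocks,n_heads Trunk size.
#' @param verbose Print per-epoch accuracy.
#' @return Object of class `handedness_selector` with elements `weights`,
#'   `arch`, `train_accuracy` and `certified` (FALSE when accuracy stays
#'   indistinguishable from chance, with a warning).
#' @export
train_handedness_selector <- function(chiral_ensembles, epochs = 8L,
                                      batch = 32L, lr = 1e-3, seed = 1L,
                                      d_model = 16L, n_blocks = 1L,
                                      n_heads = 2L, verbose = FALSE) {
  confs <- list()
  for (ens in chiral_ensembles)
    for (i in seq_len(n_frames(ens)))
      confs[[length(confs) + 1L]] <- get_frame(ens, i)
  n <- length(confs)
  if (n < 4L) stop("need at least 4 training conformations")
  arch <- generator_architecture(n_z = 2L, n_blocks = n_blocks,
                                 d_model = d_model, n_heads = n_heads)
  rng <- local_rng(seed)
  weights <- list(trunk = init_selector_trunk(arch, rng),
                  out = init_linear(d_model, 1L, rng))
  opt <- adam_new(weights, lr, beta1 = 0.9, beta2 = 0.999)
  acc <- 0.5
  for (epoch in seq_len(epochs)) {
    ord <- rng$sample_int(n)
    correct <- 0L
    total <- 0L
    for (start in seq(1L, n, by = batch)) {
      take <- ord[start:min(start + batch - 1L, n)]
      # each conformation contributes itself (label 1) and its mirror (0)
      feats <- list()
      labels <- numeric(0L)
      for (ci in take) {
        tor <- ca_torsions(confs[[ci]])
        feats[[length(feats) + 1L]] <- torsion_embed(tor)
        labels <- c(labels, 1)
        feats[[length(feats) + 1L]] <- torsion_embed(-as.numeric(tor))
        labels <- c(labels, 0)
      }
      Lp <- nrow(feats[[1L]])
      X <- do.call(rbind, feats)
      B <- length(labels)
      fw <- selector_fwd(weights, arch, X, Lp, B, train = TRUE)
      p <- sigmoid(fw$logit)
      correct <- correct + sum((p > 0.5) == (labels > 0.5))
      total <- total + B
      dlogit <- (p - labels) / B         # BCE gradient
      gw <- selector_bwd(weights, arch, fw$cache, dlogit, Lp, B)
      weights <- adam_step(opt, weights, gw)
    }
    acc <- correct / total
    if (verbose) message(sprintf("selector epoch %d: accuracy %.3f",
                                 epoch, acc))
  }
  certified <- acc > 0.6
  if (!certified)
    warning("training data appears achiral; selector cannot certify handedness")
  structure(list(weights = weights, arch = arch, train_accuracy = acc,
                 certified = certified),
            class = "handedness_selector")
}

init_selector_trunk <- function(arch, rng) {
  d <- arch$d_model
  blocks <- vector("list", arch$n_blocks)
  for (k in seq_len(arch$n_blocks)) {
    blocks[[k]] <- list(
      q = init_linear(d, d, rng), k = init_linear(d, d, rng),
      v = init_linear(d, d, rng), o = init_linear(d, d, rng),
      ln1 = init_layernorm(d),
      ff1 = init_linear(d, 2L * d, rng), ff2 = init_linear(2L * d, d, rng),
      ln2 = init_layernorm(d))
  }
  list(embed = init_linear(2L, d, rng), blocks = blocks)
}

selector_fwd <- function(weights, arch, X, Lp, B, train = FALSE) {
  tw <- weights$trunk
  emb <- linear_fwd(tw$embed, X)
  pe <- positional_encoding(Lp, arch$d_model)
  H <- emb$out + pe[rep(seq_len(Lp), B), , drop = FALSE]
  caches <- vector("list", arch$n_blocks)
  for (k in seq_len(arch$n_blocks)) {
    bl <- block_fwd(tw$blocks[[k]], H, Lp, B, arch)
    H <- bl$out
    caches[[k]] <- bl$cache
  }
  # mean-pool per sample
  grp <- rep(seq_len(B), each = Lp)
  pooled <- rowsum(H, grp, reorder = FALSE) / Lp
  ol <- linear_fwd(weights$out, pooled)
  out <- list(logit = as.numeric(ol$out))
  if (train)
    out$cache <- list(emb = emb, blocks = caches, ol = ol, grp = grp)
  out
}

selector_bwd <- function(weights, arch, cache, dlogit, Lp, B) {
  ob <- linear_bwd(weights$out, cache$ol, matrix(dlogit, ncol = 1L))
  dH <- ob$dX[cache$grp, , drop = FALSE] / Lp
  gblocks <- vector("list", arch$n_blocks)
  for (k in rev(seq_len(arch$n_blocks))) {
    bb <- block_bwd(weights$trunk$blocks[[k]], cache$blocks[[k]], dH, arch)
    gblocks[[k]] <- bb$grad
    dH <- bb$dX
  }
  embb <- linear_bwd(weights$trunk$embed, cache$emb, dH)
  list(trunk = list(embed = embb$grad, blocks = gblocks), out = ob$grad)
}

#' Handedness probability of a conformation
#'
#' @param conf `L x 3` coordinate matrix (`L >= 4`).
#' @param selector A trained [train_handedness_selector()] object.
#' @return Probability that the conformation is correct-handed.
#' @export
predict_handedness <- function(conf, selector) {
  X <- torsion_embed(ca_torsions(as.matrix(conf)))
  sigmoid(selector_fwd(selector$weights, selector$arch, X, nrow(X), 1L)$logit)
}

#' Select the correct mirror image of a conformation
#'
#' Returns the conformation unchanged when the selector scores it at 0.5
#' or above (ties keep the input), otherwise its reflection. Idempotent,
#' and never changes any interatomic distance.
#'
#' @param conf `L x 3` coordinate matrix.
#' @param selector A trained [train_handedness_selector()] object.
#' @return `L x 3` coordinate matrix.
#' @export
select_mirror_image <- function(conf, selector) {
  conf <- as.matrix(conf)
  if (predict_handedness(conf, selector) >= 0.5) conf
  else reflect_conformation(conf)
}
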