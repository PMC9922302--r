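# Spectral-normalized MLP discriminators. Input: standardized flattened
# upper-triangle pair distances concatenated with the flattened one-hot
# sequence (optionally plus the L-3 pseudo-torsions); three affine maps
# with spectral normalization, two leaky rectifiers, and a sigmoid in
# probability mode (linear output in hinge / Wasserstein modes).

#' Discriminator architecture description
#'
#' @param mode `"mlp_per_length"` (one MLP per crop length, the default) or
#'   `"conv2d_padded"` (reserved enum value; the MLP family is the
#'   implemented discriminator).
#' @param hidden Widths of the two hidden layers.
#' @param output `"probability"` (sigmoid), `"score"` (linear; used by the
#'   hinge and Wasserstein objectives).
#' @param use_torsions Append the `L - 3` pseudo-torsions to the input
#'   features (makes the score chirality-sensitive).
#' @param leaky_slope Leaky rectifier slope.
#' @return Object of class `discriminator_architecture`.
#' @export
discriminator_architecture <- function(mode = c("mlp_per_length", "conv2d_padded"),
                                       hidden = c(256L, 256L),
                                       output = c("probability", "score"),
                                       use_torsions = FALSE,
                                       leaky_slope = 0.2) {
  mode <- match.arg(mode)
  output <- match.arg(output)
  structure(list(mode = mode, hidden = as.integer(hidden), output = output,
                 use_torsions = isTRUE(use_torsions),
                 leaky_slope = leaky_slope),
            class = "discriminator_architecture")
}

disc_input_dim <- function(L, arch) {
  L * (L - 1L) / 2L + 20L * L + if (arch$use_torsions) L - 3L else 0L
}

init_discriminator <- function(L, arch, rng) {
  d_in <- disc_input_dim(L, arch)
  list(l1 = init_linear(d_in, arch$hidden[1L], rng),
       l2 = init_linear(arch$hidden[1L], arch$hidden[2L], rng),
       l3 = init_linear(arch$hidden[2L], 1L, rng))
}

# forward over a feature batch (n x d_in). `env` holds the persistent
# power-iteration vectors; update = TRUE advances them (training step).
disc_fwd <- function(weights, arch, X, env, update = TRUE) {
  s1 <- sn_apply(weights$l1, env, "u1", update)
  s2 <- sn_apply(weights$l2, env, "u2", update)
  s3 <- sn_apply(weights$l3, env, "u3", update)
  f1 <- linear_fwd(list(W = s1$Wsn, b = weights$l1$b), X)
  a1 <- lrelu_fwd(f1$out, arch$leaky_slope)
  f2 <- linear_fwd(list(W = s2$Wsn, b = weights$l2$b), a1$out)
  a2 <- lrelu_fwd(f2$out, arch$leaky_slope)
  f3 <- linear_fwd(list(W = s3$Wsn, b = weights$l3$b), a2$out)
  score <- as.numeric(f3$out)
  out <- if (arch$output == "probability") sigmoid(score) else score
  list(out = out, score = score,
       cache = list(s1 = s1, s2 = s2, s3 = s3, f1 = f1, a1 = a1,
                    f2 = f2, a2 = a2, f3 = f3))
}

# dScore: gradient w.r.t. the pre-activation scalar score (length n).
disc_bwd <- function(weights, arch, cache, dScore) {
  dY3 <- matrix(dScore, ncol = 1L)
  b3 <- linear_bwd(list(W = cache$s3$Wsn, b = weights$l3$b), cache$f3, dY3)
  da2 <- lrelu_bwd(cache$a2, b3$dX)
  b2 <- linear_bwd(list(W = cache$s2$Wsn, b = weights$l2$b), cache$f2, da2)
  da1 <- lrelu_bwd(cache$a1, b2$dX)
  b1 <- linear_bwd(list(W = cache$s1$Wsn, b = weights$l1$b), cache$f1, da1)
  list(grad = list(l1 = list(W = sn_grad(b1$grad$W, cache$s1),
                             b = b1$grad$b),
                   l2 = list(W = sn_grad(b2$grad$W, cache$s2),
                             b = b2$grad$b),
                   l3 = list(W = sn_grad(b3$grad$W, cache$s3),
                             b = b3$grad$b)),
       dX = b1$dX)
}

# gradient of the raw score w.r.t. the input features, per sample
# (piecewise-linear network: exact almost everywhere). n x d_in matrix.
disc_input_grad <- function(cache, arch) {
  n <- nrow(cache$f1$X)
  d3 <- matrix(1, n, 1L)
  d2 <- lrelu_bwd(cache$a2, tcrossprod(d3, cache$s3$Wsn))
  d1 <- lrelu_bwd(cache$a1, tcrossprod(d2, cache$s2$Wsn))
  tcrossprod(d1, cache$s1$Wsn)
}

# assemble discriminator input features for a coordinate batch
# coords_list: list of L x 3 matrices; seq_batch: list of residue_sequence
disc_features <- function(coords_list, seq_batch, std) {
  n <- length(coords_list)
  L <- nrow(coords_list[[1L]])
  P <- L * (L - 1L) / 2L
  X <- matrix(NA_real_, n, P)
  for (i in seq_len(n)) X[i, ] <- distance_features(coords_list[[i]])
  Xs <- standardize_features(std, X, L)
  Aoh <- t(vapply(seq_batch, function(s) as.numeric(t(s$onehot)),
                  numeric(20L * L)))
  cbind(Xs, Aoh)
}

#' Discriminator forward pass
#'
#' Scores one conformation/sequence pair. In probability mode the score is
#' strictly inside (0, 1). The input pipeline uses only pair distances (and
#' optionally pseudo-torsions), so without torsion features the score is
#' invariant to rigid motions and reflections of the conformation.
#'
#' @param conf `L x 3` coordinate matrix, nm.
#' @param seq [residue_sequence()].
#' @param model GAN model holding the discriminator for this length (see
#'   [init_gan_model()]).
#' @return Scalar score.
#' @export
discriminator_forward <- function(conf, seq, model) {
  L <- length(seq)
  check_conf(as.matrix(conf), seq)
  key <- as.character(L)
  if (!key %in% names(model$D))
    stop(sprintf("no discriminator for length %d (available: %s)",
                 L, paste(names(model$D), collapse = ", ")))
  X <- disc_features(list(as.matrix(conf)), list(seq), model$std)
  if (model$arch_D$use_torsions) {
    tor <- ca_torsions(as.matrix(conf))
    tor[is.na(tor)] <- 0
    X <- cbind(X, matrix(tor, nrow = 1L))
  }
  res <- disc_fwd(model$D[[key]], model$arch_D, X, model$sn_env[[key]],
                  update = FALSE)
  res$out
}
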