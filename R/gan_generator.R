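# Sequence-conditional transformer generator. Per-residue Gaussian latents
# and one-hot residue identities are embedded, updated through
# self-attention transformer blocks, and mapped position-wise to 3D
# C-alpha coordinates. Backpropagation is manual; every forward in
# training mode returns the cache its backward needs.

#' Generator architecture description
#'
#' @param n_z Latent width per residue.
#' @param n_blocks Number of transformer blocks.
#' @param d_model Embedding width.
#' @param n_heads Attention heads (`d_model` must be divisible).
#' @param layernorm_mode `"post"` (default) or `"pre"` residual layout.
#' @param head_mode `"displacement"` (default): the position-wise head
#'   emits per-residue displacement vectors that are accumulated along the
#'   chain into coordinates, so local bond geometry is directly
#'   position-wise controllable while attention supplies the global
#'   modes; `"absolute"`: the head emits coordinates directly.
#' @return Object of class `generator_architecture`.
#' @export
generator_architecture <- function(n_z = 16L, n_blocks = 4L, d_model = 128L,
                                   n_heads = 8L,
                                   layernorm_mode = c("post", "pre"),
                                   head_mode = c("displacement", "absolute")) {
  layernorm_mode <- match.arg(layernorm_mode)
  head_mode <- match.arg(head_mode)
  if (d_model %% n_heads != 0L)
    stop("d_model must be divisible by n_heads")
  structure(list(n_z = as.integer(n_z), n_blocks = as.integer(n_blocks),
                 d_model = as.integer(d_model), n_heads = as.integer(n_heads),
                 d_head = as.integer(d_model / n_heads),
                 layernorm_mode = layernorm_mode, head_mode = head_mode),
            class = "generator_architecture")
}

init_generator <- function(arch, rng) {
  d <- arch$d_model
  blocks <- vector("list", arch$n_blocks)
  for (k in seq_len(arch$n_blocks)) {
    blocks[[k]] <- list(
      q = init_linear(d, d, rng), k = init_linear(d, d, rng),
      v = init_linear(d, d, rng), o = init_linear(d, d, rng),
      ln1 = init_layernorm(d),
      ff1 = init_linear(d, 2L * d, rng), ff2 = init_linear(2L * d, d, rng),
      ln2 = init_layernorm(d),
      zin = init_linear(2L * arch$n_z, d, rng))  # per-block latent injection
  }
  list(embed = init_linear(2L * arch$n_z + 20L, d, rng),
       blocks = blocks,
       # the head also sees the (augmented) latent directly, a short path
       # from noise to coordinates that the trunk's normalizations cannot
       # attenuate
       head1 = init_linear(d + 2L * arch$n_z, d, rng),
       head2 = init_linear(d, 3L, rng, gain = 0.5))
}

# append per-sample global latent summary channels: each position also
# sees the mean of z over the chain, giving the network a direct handle
# on global (chain-breathing) fluctuation modes
augment_latent <- function(Z, L, B) {
  grp <- rep(seq_len(B), each = L)
  means <- rowsum(Z, grp, reorder = FALSE) / L
  cbind(Z, means[grp, , drop = FALSE])
}

# fixed sinusoidal residue-index encodings
positional_encoding <- function(L, d) {
  pos <- seq_len(L) - 1L
  pe <- matrix(0, L, d)
  for (m in seq_len(ceiling(d / 2))) {
    w <- 1 / 10000^(2 * (m - 1) / d)
    pe[, 2L * m - 1L] <- sin(pos * w)
    if (2L * m <= d) pe[, 2L * m] <- cos(pos * w)
  }
  pe
}

# multi-head self-attention over B stacked blocks of L rows
mha_fwd <- function(p, X, L, B, arch) {
  Ql <- linear_fwd(p$q, X); Kl <- linear_fwd(p$k, X); Vl <- linear_fwd(p$v, X)
  dh <- arch$d_head
  H <- arch$n_heads
  scal <- 1 / sqrt(dh)
  O <- matrix(0, nrow(X), arch$d_model)
  Acache <- vector("list", B * H)
  for (b in seq_len(B)) {
    rb <- ((b - 1L) * L + 1L):(b * L)
    for (h in seq_len(H)) {
      ch <- ((h - 1L) * dh + 1L):(h * dh)
      S <- tcrossprod(Ql$out[rb, ch, drop = FALSE],
                      Kl$out[rb, ch, drop = FALSE]) * scal
      A <- softmax_rows(S)
      O[rb, ch] <- A %*% Vl$out[rb, ch, drop = FALSE]
      Acache[[(b - 1L) * H + h]] <- A
    }
  }
  Ol <- linear_fwd(p$o, O)
  list(out = Ol$out,
       cache = list(Ql = Ql, Kl = Kl, Vl = Vl, Ol = Ol, A = Acache,
                    L = L, B = B))
}

mha_bwd <- function(p, cache, dY, arch) {
  dh <- arch$d_head
  H <- arch$n_heads
  scal <- 1 / sqrt(dh)
  L <- cache$L; B <- cache$B
  ob <- linear_bwd(p$o, cache$Ol, dY)
  dO <- ob$dX
  dQ <- matrix(0, nrow(dY), arch$d_model)
  dK <- dQ; dV <- dQ
  for (b in seq_len(B)) {
    rb <- ((b - 1L) * L + 1L):(b * L)
    for (h in seq_len(H)) {
      ch <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cache$A[[(b - 1L) * H + h]]
      dOb <- dO[rb, ch, drop = FALSE]
      Vb <- cache$Vl$out[rb, ch, drop = FALSE]
      dA <- tcrossprod(dOb, Vb)
      dV[rb, ch] <- crossprod(A, dOb)
      dS <- softmax_rows_bwd(A, dA) * scal
      dQ[rb, ch] <- dS %*% cache$Kl$out[rb, ch, drop = FALSE]
      dK[rb, ch] <- crossprod(dS, cache$Ql$out[rb, ch, drop = FALSE])
    }
  }
  qb <- linear_bwd(p$q, cache$Ql, dQ)
  kb <- linear_bwd(p$k, cache$Kl, dK)
  vb <- linear_bwd(p$v, cache$Vl, dV)
  list(grad = list(q = qb$grad, k = kb$grad, v = vb$grad, o = ob$grad),
       dX = qb$dX + kb$dX + vb$dX)
}

block_fwd <- function(p, X, L, B, arch, Z = NULL) {
  zl <- NULL
  if (!is.null(p$zin) && !is.null(Z)) {
    zl <- linear_fwd(p$zin, Z)
    X <- X + zl$out
  }
  out <- block_fwd_core(p, X, L, B, arch)
  out$cache$zl <- zl
  out
}

block_fwd_core <- function(p, X, L, B, arch) {
  if (arch$layernorm_mode == "post") {
    att <- mha_fwd(p, X, L, B, arch)
    ln1 <- layernorm_fwd(p$ln1, X + att$out)
    f1 <- linear_fwd(p$ff1, ln1$out)
    a1 <- lrelu_fwd(f1$out)
    f2 <- linear_fwd(p$ff2, a1$out)
    ln2 <- layernorm_fwd(p$ln2, ln1$out + f2$out)
    list(out = ln2$out,
         cache = list(att = att, ln1 = ln1, f1 = f1, a1 = a1, f2 = f2,
                      ln2 = ln2))
  } else {
    ln1 <- layernorm_fwd(p$ln1, X)
    att <- mha_fwd(p, ln1$out, L, B, arch)
    X1 <- X + att$out
    ln2 <- layernorm_fwd(p$ln2, X1)
    f1 <- linear_fwd(p$ff1, ln2$out)
    a1 <- lrelu_fwd(f1$out)
    f2 <- linear_fwd(p$ff2, a1$out)
    list(out = X1 + f2$out,
         cache = list(att = att, ln1 = ln1, f1 = f1, a1 = a1, f2 = f2,
                      ln2 = ln2))
  }
}

block_bwd <- function(p, cache, dY, arch) {
  core <- block_bwd_core(p, cache, dY, arch)
  if (!is.null(p$zin)) {
    gz <- if (!is.null(cache$zl))
      linear_bwd(p$zin, cache$zl, core$dX)$grad
    else
      list(W = p$zin$W * 0, b = p$zin$b * 0)
    core$grad <- c(core$grad, list(zin = gz))
  }
  core
}

block_bwd_core <- function(p, cache, dY, arch) {
  if (arch$layernorm_mode == "post") {
    l2 <- layernorm_bwd(p$ln2, cache$ln2, dY)
    f2b <- linear_bwd(p$ff2, cache$f2, l2$dX)
    da1 <- lrelu_bwd(cache$a1, f2b$dX)
    f1b <- linear_bwd(p$ff1, cache$f1, da1)
    dln1 <- l2$dX + f1b$dX
    l1 <- layernorm_bwd(p$ln1, cache$ln1, dln1)
    attb <- mha_bwd(p, cache$att$cache, l1$dX, arch)
    list(grad = c(attb$grad,
                  list(ln1 = l1$grad, ff1 = f1b$grad, ff2 = f2b$grad,
                       ln2 = l2$grad)),
         dX = l1$dX + attb$dX)
  } else {
    f2b <- linear_bwd(p$ff2, cache$f2, dY)
    da1 <- lrelu_bwd(cache$a1, f2b$dX)
    f1b <- linear_bwd(p$ff1, cache$f1, da1)
    l2 <- layernorm_bwd(p$ln2, cache$ln2, f1b$dX)
    dX1 <- dY + l2$dX
    attb <- mha_bwd(p, cache$att$cache, dX1, arch)
    l1 <- layernorm_bwd(p$ln1, cache$ln1, attb$dX)
    list(grad = c(attb$grad,
                  list(ln1 = l1$grad, ff1 = f1b$grad, ff2 = f2b$grad,
                       ln2 = l2$grad)),
         dX = dX1 + l1$dX)
  }
}

# Z: (B*L) x n_z latents; Aoh: (B*L) x 20 one-hot rows. Returns coordinates
# (B*L) x 3 and, if train = TRUE, the cache for gen_bwd().
gen_fwd <- function(weights, arch, Z, Aoh, L, B, train = FALSE) {
  Za <- augment_latent(Z, L, B)
  emb <- linear_fwd(weights$embed, cbind(Za, Aoh))
  pe <- positional_encoding(L, arch$d_model)
  X <- emb$out + pe[rep(seq_len(L), B), , drop = FALSE]
  caches <- vector("list", arch$n_blocks)
  for (k in seq_len(arch$n_blocks)) {
    bl <- block_fwd(weights$blocks[[k]], X, L, B, arch, Z = Za)
    X <- bl$out
    caches[[k]] <- bl$cache
  }
  h1 <- linear_fwd(weights$head1, cbind(X, Za))
  a1 <- lrelu_fwd(h1$out)
  h2 <- linear_fwd(weights$head2, a1$out)
  coords <- h2$out
  if (is.null(arch$head_mode) || arch$head_mode == "displacement") {
    # per-sample cumulative sums via whole-column cumsum minus the running
    # total at each block start (no per-sample loop)
    ends <- seq_len(B) * L
    for (k in 1:3) {
      cs <- cumsum(h2$out[, k])
      base <- c(0, cs[ends[-B]])
      coords[, k] <- cs - rep(base, each = L)
    }
  }
  out <- list(coords = coords)
  if (train)
    out$cache <- list(emb = emb, blocks = caches, h1 = h1, a1 = a1, h2 = h2)
  out
}

# dCoords: (B*L) x 3 upstream gradient; returns weight-shaped gradient tree
gen_bwd <- function(weights, arch, cache, dCoords) {
  if (is.null(arch$head_mode) || arch$head_mode == "displacement") {
    # d(cumsum)/d(displacement): within-block suffix sums, computed from
    # whole-column reversed cumsums minus the suffix total past each block
    Lb <- cache$blocks[[1L]]$att$cache$L
    B <- cache$blocks[[1L]]$att$cache$B
    n <- Lb * B
    dD <- dCoords
    for (k in 1:3) {
      r <- rev(cumsum(rev(dCoords[, k])))
      past <- c(r[seq_len(B - 1L) * Lb + 1L], 0)  # suffix beyond each block
      dD[, k] <- r - rep(past, each = Lb)
    }
    dCoords <- dD
  }
  h2b <- linear_bwd(weights$head2, cache$h2, dCoords)
  da1 <- lrelu_bwd(cache$a1, h2b$dX)
  h1b <- linear_bwd(weights$head1, cache$h1, da1)
  dX <- h1b$dX[, seq_len(arch$d_model), drop = FALSE]  # latent part: no params upstream
  gblocks <- vector("list", arch$n_blocks)
  for (k in rev(seq_len(arch$n_blocks))) {
    bb <- block_bwd(weights$blocks[[k]], cache$blocks[[k]], dX, arch)
    gblocks[[k]] <- bb$grad
    dX <- bb$dX
  }
  embb <- linear_bwd(weights$embed, cache$emb, dX)
  list(embed = embb$grad, blocks = gblocks,
       head1 = h1b$grad, head2 = h2b$grad)
}

#' Draw a latent sequence
#'
#' Per-residue standard-normal latents, the random input of the generator.
#'
#' @param L Number of residues.
#' @param n_z Latent width.
#' @param seed Integer seed.
#' @return `L x n_z` matrix.
#' @export
latent_sequence <- function(L, n_z, seed = 1L) {
  rng <- local_rng(seed)
  matrix(rng$norm(L * n_z), L, n_z)
}

#' Generator forward pass
#'
#' Maps one latent sequence and one residue sequence to a C-alpha
#' conformation. Deterministic given `z` and the model weights; the same
#' weights accept any sequence length.
#'
#' @param z `L x n_z` latent matrix (see [latent_sequence()]).
#' @param seq [residue_sequence()] with matching length.
#' @param model A GAN model (see [init_gan_model()] or [train_gan()]).
#' @return `L x 3` coordinate matrix, nm.
#' @export
generator_forward <- function(z, seq, model) {
  L <- length(seq)
  if (!is.matrix(z) || nrow(z) != L || ncol(z) != model$arch_G$n_z)
    stop(sprintf("z must be a %d x %d matrix", L, model$arch_G$n_z))
  res <- gen_fwd(model$G, model$arch_G, z, seq$onehot, L, 1L)
  res$coords
}
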