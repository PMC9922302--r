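# Minimal neural-network toolkit: dense layers, layer normalization,
# softmax attention pieces, spectral normalization and Adam, with manual
# backpropagation. Weights live in plain nested lists; gradients and
# optimizer moments are parallel trees of the same shape.

# ---- weight-tree utilities -------------------------------------------------

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(x) tree_map(f, x)) else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (k in seq_along(a)) out[[k]] <- tree_map2(f, a[[k]], b[[k]])
    out
  } else f(a, b)
}

zeros_like <- function(tree) tree_map(function(x) x * 0, tree)

tree_add <- function(a, b) tree_map2(`+`, a, b)

# Adam with configurable betas (the adversarial training uses beta1 = 0).
# Moments are kept as flat vectors; gradients are flattened with unlist()
# (depth-first, matching the tree walk used to re-apply the update).
adam_new <- function(params, lr, beta1 = 0.0, beta2 = 0.9, eps = 1e-8) {
  env <- new.env(parent = emptyenv())
  n <- length(unlist(params, use.names = FALSE))
  env$m <- numeric(n)
  env$v <- numeric(n)
  env$t <- 0L
  env$lr <- lr; env$b1 <- beta1; env$b2 <- beta2; env$eps <- eps
  env
}

# subtract a flat update vector from a weight tree, depth-first
tree_sub_flat <- function(tree, vec, cursor) {
  if (is.list(tree)) {
    for (k in seq_along(tree)) tree[[k]] <- tree_sub_flat(tree[[k]], vec,
                                                          cursor)
    tree
  } else {
    n <- length(tree)
    out <- tree - vec[cursor$at + seq_len(n) - 1L]
    cursor$at <- cursor$at + n
    out
  }
}

# refill a weight tree from a flat vector (inverse of unlist), keeping dims
tree_refill <- function(tree, vec, cursor) {
  if (is.list(tree)) {
    for (k in seq_along(tree)) tree[[k]] <- tree_refill(tree[[k]], vec,
                                                        cursor)
    tree
  } else {
    n <- length(tree)
    tree[] <- vec[cursor$at + seq_len(n) - 1L]
    cursor$at <- cursor$at + n
    tree
  }
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  g <- unlist(grads, use.names = FALSE)
  opt$m <- opt$b1 * opt$m + (1 - opt$b1) * g
  opt$v <- opt$b2 * opt$v + (1 - opt$b2) * g * g
  bc1 <- 1 - opt$b1^opt$t
  bc2 <- 1 - opt$b2^opt$t
  upd <- opt$lr * (opt$m / bc1) / (sqrt(opt$v / bc2) + opt$eps)
  cursor <- new.env(parent = emptyenv())
  cursor$at <- 1L
  tree_sub_flat(params, upd, cursor)
}

# ---- initializers ----------------------------------------------------------

init_linear <- function(n_in, n_out, rng, gain = 1) {
  sd <- gain * sqrt(2 / (n_in + n_out))
  list(W = matrix(rng$norm(n_in * n_out, sd = sd), n_in, n_out),
       b = rep(0, n_out))
}

# ---- dense layer -----------------------------------------------------------

linear_fwd <- function(p, X) {
  list(out = X %*% p$W + rep(p$b, each = nrow(X)), X = X)
}

linear_bwd <- function(p, cache, dY) {
  list(grad = list(W = crossprod(cache$X, dY), b = colSums(dY)),
       dX = tcrossprod(dY, p$W))
}

# ---- activations -----------------------------------------------------------

lrelu_fwd <- function(X, slope = 0.2) {
  mask <- X > 0
  list(out = X * (mask + slope * (1 - mask)), X = X, mask = mask,
       slope = slope)
}

lrelu_bwd <- function(cache, dY) {
  dY * (cache$mask + cache$slope * (1 - cache$mask))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)  # m recycles down columns: per-row max subtraction
  E / rowSums(E)
}

softmax_rows_bwd <- function(A, dA) {
  A * (dA - rowSums(dA * A))
}

# ---- layer normalization ---------------------------------------------------

layernorm_fwd <- function(p, X, eps = 1e-5) {
  n <- nrow(X)
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- xhat * rep(p$g, each = n) + rep(p$b, each = n)
  list(out = out, xhat = xhat, inv = inv, xc = xc)
}

layernorm_bwd <- function(p, cache, dY) {
  dxhat <- dY * rep(p$g, each = nrow(dY))
  xhat <- cache$xhat
  inv <- cache$inv
  # dX = inv * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)) per row
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- inv * (dxhat - m1 - xhat * m2)
  list(grad = list(g = colSums(dY * xhat), b = colSums(dY)), dX = dX)
}

init_layernorm <- function(d) list(g = rep(1, d), b = rep(0, d))

# ---- spectral normalization ------------------------------------------------

# One power iteration per call (training mode), persistent u kept in the
# layer's environment slot. W is n_in x n_out; u has length n_out.
sn_apply <- function(p, env, key, update = TRUE) {
  W <- p$W
  u <- env[[key]]
  if (is.null(u)) {
    u <- rep(1, ncol(W)) / sqrt(ncol(W))  # deterministic start
  }
  if (update) {
    v <- as.numeric(W %*% u)
    v <- v / max(sqrt(sum(v^2)), 1e-12)
    u <- as.numeric(crossprod(W, v))
    u <- u / max(sqrt(sum(u^2)), 1e-12)
    env[[key]] <- u
  } else {
    v <- as.numeric(W %*% u)
    v <- v / max(sqrt(sum(v^2)), 1e-12)
  }
  sig <- max(as.numeric(crossprod(v, W %*% u)), 1e-12)
  list(Wsn = W / sig, sig = sig, u = u, v = v)
}

# gradient through W/sigma given dL/dWsn (treating u, v as constants):
# dW = dWsn/sig - (sum(dWsn * Wsn)/sig) * v u^T
sn_grad <- function(dWsn, sn) {
  dW <- dWsn / sn$sig
  coef <- sum(dWsn * sn$Wsn) / sn$sig
  dW - coef * outer(sn$v, sn$u)
}
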