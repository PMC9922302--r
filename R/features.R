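# Pair bookkeeping shared by the metric suite and the adversarial model.

# row-major upper-triangle pair index table for a chain of length L:
# (1,2),(1,3),...,(1,L),(2,3),... Column `sep` is the sequence separation.
# Memoized: the table is requested for every conformation batch.
.pair_index_cache <- new.env(parent = emptyenv())

pair_index <- function(L) {
  stopifnot(L >= 2L)
  key <- as.character(L)
  hit <- .pair_index_cache[[key]]
  if (!is.null(hit)) return(hit)
  i <- rep.int(seq_len(L - 1L), times = (L - 1L):1L)
  j <- unlist(lapply(seq_len(L - 1L), function(a) (a + 1L):L), use.names = FALSE)
  out <- cbind(i = i, j = j, sep = j - i)
  .pair_index_cache[[key]] <- out
  out
}

# distance features for B stacked conformations ((B*L) x 3) -> B x P matrix
batch_distance_features <- function(coords, L, B) {
  idx <- pair_index(L)
  P <- nrow(idx)
  off <- rep((seq_len(B) - 1L) * L, each = P)
  I <- off + idx[, "i"]
  J <- off + idx[, "j"]
  d <- coords[I, , drop = FALSE] - coords[J, , drop = FALSE]
  matrix(sqrt(d[, 1L]^2 + d[, 2L]^2 + d[, 3L]^2), B, P, byrow = TRUE)
}

# gradient of a per-distance loss back to stacked coordinates:
# dists, ddist are B x P; returns (B*L) x 3
batch_dist_to_coord_grad <- function(coords, dists, ddist, L, B) {
  idx <- pair_index(L)
  P <- nrow(idx)
  off <- rep((seq_len(B) - 1L) * L, each = P)
  I <- off + idx[, "i"]
  J <- off + idx[, "j"]
  dvec <- as.vector(t(dists))
  gvec <- as.vector(t(ddist))
  u <- (coords[I, , drop = FALSE] - coords[J, , drop = FALSE]) /
    pmax(dvec, 1e-9)
  contrib <- u * gvec
  g <- matrix(0, B * L, 3L)
  gi <- rowsum(contrib, I)
  gj <- rowsum(contrib, J)
  ri <- as.integer(rownames(gi))
  rj <- as.integer(rownames(gj))
  g[ri, ] <- g[ri, ] + gi
  g[rj, ] <- g[rj, ] - gj
  g
}

#' Flattened pairwise distance features of a conformation
#'
#' The upper triangle of the distance matrix in row-major order
#' (`(1,2), (1,3), ..., (1,L), (2,3), ...`), the representation consumed by
#' the discriminators. Invariant to rigid motions and reflections.
#'
#' @param conf `L x 3` coordinate matrix, nm.
#' @return Numeric vector of length `L(L-1)/2` (nm).
#' @export
distance_features <- function(conf) {
  conf <- as.matrix(conf)
  stopifnot(ncol(conf) == 3L, nrow(conf) >= 2L)
  idx <- pair_index(nrow(conf))
  d <- conf[idx[, "i"], , drop = FALSE] - conf[idx[, "j"], , drop = FALSE]
  sqrt(rowSums(d * d))
}

# n x P matrix of pair distances over all frames of an ensemble
ensemble_distances <- function(ens) {
  xyz <- ens$xyz
  L <- dim(xyz)[2L]
  idx <- pair_index(L)
  n <- dim(xyz)[1L]
  out <- matrix(NA_real_, nrow = n, ncol = nrow(idx))
  for (p in seq_len(nrow(idx))) {
    d <- xyz[, idx[p, "i"], , drop = FALSE] - xyz[, idx[p, "j"], , drop = FALSE]
    out[, p] <- sqrt(rowSums(matrix(d, nrow = n)^2))
  }
  out
}
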