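#' Fit the per-separation distance standardizer
#'
#' For every sequence separation `k` the mean `m_k` and standard deviation
#' `s_k` of C-alpha pair distances are pooled over all frames of all
#' supplied ensembles. The discriminators use these as a non-trainable
#' standardization layer.
#'
#' @param ensembles List of [conformational_ensemble()] objects; the
#'   longest one defines the separation range `k = 1 .. L_max - 1`.
#' @param s_floor Lower bound applied to every `s_k` (guards near-rigid
#'   separations), nm.
#' @return Object of class `feature_standardizer` with vectors `m` and `s`
#'   indexed by separation.
#' @export
fit_standardizer <- function(ensembles, s_floor = 1e-4) {
  if (length(ensembles) == 0L) stop("no ensembles supplied")
  Lmax <- max(vapply(ensembles, function(e) dim(e$xyz)[2L], integer(1L)))
  # accumulate sufficient statistics per separation
  n <- numeric(Lmax - 1L)
  s1 <- numeric(Lmax - 1L)
  s2 <- numeric(Lmax - 1L)
  for (ens in ensembles) {
    L <- dim(ens$xyz)[2L]
    idx <- pair_index(L)
    d <- ensemble_distances(ens)
    for (k in unique(idx[, "sep"])) {
      cols <- which(idx[, "sep"] == k)
      vals <- d[, cols]
      n[k] <- n[k] + length(vals)
      s1[k] <- s1[k] + sum(vals)
      s2[k] <- s2[k] + sum(vals^2)
    }
  }
  if (any(n < 2))
    stop(sprintf("separation %d has fewer than 2 observations",
                 which(n < 2)[1L]))
  m <- s1 / n
  varv <- pmax(s2 / n - m^2, 0)  # population variance of the pool
  s <- pmax(sqrt(varv), s_floor)
  structure(list(m = m, s = s, L_max = Lmax), class = "feature_standardizer")
}

#' Standardize a distance-feature matrix
#'
#' Applies `(x - m_k) / s_k` per feature, `k` being the sequence
#' separation of the pair behind each feature column.
#'
#' @param std A [fit_standardizer()] result.
#' @param X `n x L(L-1)/2` matrix of distance features (or a single
#'   feature vector).
#' @param L Chain length the features belong to.
#' @return Matrix (or vector) of standardized features.
#' @export
standardize_features <- function(std, X, L) {
  vec <- is.null(dim(X))
  if (vec) X <- matrix(X, nrow = 1L)
  if (L - 1L > std$L_max - 1L)
    stop("chain longer than the standardizer's fitted range")
  sep <- pair_index(L)[, "sep"]
  n <- nrow(X)
  Xs <- (X - rep(std$m[sep], each = n)) / rep(std$s[sep], each = n)
  if (vec) Xs[1L, ] else Xs
}
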