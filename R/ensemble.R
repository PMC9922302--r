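#' Construct a conformational ensemble
#'
#' A `conformational_ensemble` is the unit all comparison metrics operate
#' on: an ordered collection of C-alpha conformations sharing one residue
#' sequence. Coordinates are stored in nanometres as an `n x L x 3` array.
#'
#' @param sequence A [residue_sequence()].
#' @param coords Either an `n x L x 3` numeric array, a single `L x 3`
#'   matrix (one conformation), or a list of `L x 3` matrices.
#' @param provenance One of `"simulated"`, `"generated"`, `"fixture"`.
#' @return Object of class `conformational_ensemble` with elements
#'   `sequence`, `xyz` (n x L x 3 array, nm) and `provenance`.
#' @export
conformational_ensemble <- function(sequence, coords,
                                    provenance = c("simulated", "generated", "fixture")) {
  provenance <- match.arg(provenance)
  stopifnot(inherits(sequence, "residue_sequence"))
  L <- length(sequence)
  if (is.matrix(coords)) coords <- list(coords)
  if (is.list(coords)) {
    n <- length(coords)
    if (n == 0L) stop("an ensemble must contain at least one conformation")
    xyz <- array(NA_real_, dim = c(n, L, 3L))
    for (i in seq_len(n)) {
      m <- coords[[i]]
      if (!is.matrix(m) || nrow(m) != L || ncol(m) != 3L)
        stop(sprintf("conformation %d is not an %d x 3 matrix", i, L))
      xyz[i, , ] <- m
    }
  } else if (is.array(coords) && length(dim(coords)) == 3L) {
    if (dim(coords)[2L] != L || dim(coords)[3L] != 3L)
      stop(sprintf("coordinate array must be n x %d x 3", L))
    if (dim(coords)[1L] == 0L)
      stop("an ensemble must contain at least one conformation")
    xyz <- coords
  } else {
    stop("coords must be a matrix, a list of matrices, or an n x L x 3 array")
  }
  if (any(!is.finite(xyz))) stop("non-finite coordinates in ensemble")
  structure(list(sequence = sequence, xyz = xyz, provenance = provenance),
            class = "conformational_ensemble")
}

#' @export
print.conformational_ensemble <- function(x, ...) {
  cat(sprintf("<conformational_ensemble> %s: %d frames x %d residues (%s)\n",
              x$sequence$id, n_frames(x), dim(x$xyz)[2L], x$provenance))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ens A [conformational_ensemble()].
#' @return Integer frame count.
#' @export
n_frames <- function(ens) dim(ens$xyz)[1L]

#' Extract one conformation from an ensemble
#' @param ens A [conformational_ensemble()].
#' @param i Frame index.
#' @return `L x 3` coordinate matrix (nm).
#' @export
get_frame <- function(ens, i) {
  n <- n_frames(ens)
  if (i < 1L || i > n) stop("frame index out of range")
  matrix(ens$xyz[i, , ], ncol = 3L)
}

#' Subset an ensemble by frame indices
#' @param ens A [conformational_ensemble()].
#' @param idx Integer vector of frame indices.
#' @return A [conformational_ensemble()] with the selected frames.
#' @export
subset_frames <- function(ens, idx) {
  idx <- as.integer(idx)
  if (any(idx < 1L | idx > n_frames(ens))) stop("frame index out of range")
  conformational_ensemble(ens$sequence,
                          ens$xyz[idx, , , drop = FALSE],
                          provenance = ens$provenance)
}

#' Concatenate ensembles sharing one sequence
#' @param ... [conformational_ensemble()] objects with identical sequence
#'   length.
#' @param provenance Provenance tag for the result.
#' @return A single [conformational_ensemble()].
#' @export
bind_ensembles <- function(..., provenance = "simulated") {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) &&
      !inherits(parts[[1L]], "conformational_ensemble"))
    parts <- parts[[1L]]
  stopifnot(length(parts) >= 1L)
  L <- dim(parts[[1L]]$xyz)[2L]
  for (p in parts) {
    if (dim(p$xyz)[2L] != L) stop("all ensembles must share the sequence length")
  }
  xyz <- do.call(abind3, lapply(parts, function(p) p$xyz))
  conformational_ensemble(parts[[1L]]$sequence, xyz, provenance = provenance)
}

# bind n x L x 3 arrays along the frame dimension (no abind dependency)
abind3 <- function(...) {
  parts <- list(...)
  ns <- vapply(parts, function(a) dim(a)[1L], integer(1L))
  L <- dim(parts[[1L]])[2L]
  out <- array(NA_real_, dim = c(sum(ns), L, 3L))
  at <- 0L
  for (a in parts) {
    out[at + seq_len(dim(a)[1L]), , ] <- a
    at <- at + dim(a)[1L]
  }
  out
}
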