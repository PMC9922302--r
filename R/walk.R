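#' Self-avoiding random-walk starting coordinates
#'
#' Builds initial chain coordinates as a random walk with fixed
#' successive-bead distance equal to the equilibrium bond length and all
#' pairwise distances at least that long (self-avoidance), using rejection
#' sampling with a bounded number of retries per bead. Deterministic for a
#' fixed seed.
#'
#' @param sequence [residue_sequence()] (only its length is used).
#' @param seed Integer seed.
#' @param bond Bond length / exclusion distance, nm.
#' @param max_retries Retries per bead before giving up.
#' @return `L x 3` coordinate matrix, nm.
#' @export
init_random_coordinates <- function(sequence, seed = 1L, bond = 0.38,
                                    max_retries = 1000L) {
  L <- length(sequence)
  rng <- local_rng(seed)
  coords <- matrix(NA_real_, nrow = L, ncol = 3L)
  coords[1L, ] <- 0
  for (i in seq_len(L - 1L) + 1L) {
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      u <- rng$norm(3L)
      u <- u / sqrt(sum(u^2))
      cand <- coords[i - 1L, ] + bond * u
      prev <- coords[seq_len(i - 1L), , drop = FALSE]
      d2 <- rowSums((prev - matrix(cand, nrow = i - 1L, ncol = 3L,
                                   byrow = TRUE))^2)
      # bonded neighbor sits exactly at `bond`; tolerate rounding there
      if (all(d2 >= bond^2 * (1 - 1e-12))) {
        coords[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf(
        "could not place bead %d after %d retries; try a different seed",
        i, max_retries))
  }
  coords
}
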