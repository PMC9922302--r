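#' Crop plan for multi-length adversarial training
#'
#' One MLP discriminator is kept per crop length; at each epoch every
#' training sequence is assigned to a crop length and contributes
#' `n_frames` randomly sampled frames, randomly cropped to that length.
#'
#' @param L_train Crop lengths (one discriminator each).
#' @param c_max Per-length sequence quota after balancing.
#' @param n_frames Frames sampled per assigned sequence per epoch.
#' @return Object of class `crop_plan`.
#' @export
crop_plan <- function(L_train = c(20L, 50L, 80L, 110L), c_max = 1070L,
                      n_frames = 1750L) {
  structure(list(L_train = sort(as.integer(L_train)),
                 c_max = as.integer(c_max), n_frames = as.integer(n_frames)),
            class = "crop_plan")
}

# nearest crop length; ties broken toward the smaller length
nearest_crop <- function(L, L_train) {
  d <- abs(L_train - L)
  L_train[which(d == min(d))[1L]]  # L_train sorted ascending -> smaller wins
}

#' Assign sequences to crop lengths for one epoch
#'
#' Sequences whose length is in the plan keep it; all others map to the
#' nearest crop length (ties toward the smaller). Random re-sampling of
#' the training sequences then tops every crop length up to exactly
#' `c_max` assignments.
#'
#' @param sequences List of [residue_sequence()] objects.
#' @param plan A [crop_plan()].
#' @param seed Integer seed.
#' @return `data.frame` with columns `seq` (sequence index) and `crop`
#'   (assigned crop length); exactly `c_max` rows per crop length.
#' @export
assign_crops <- function(sequences, plan, seed = 1L) {
  lens <- vapply(sequences, length, integer(1L))
  if (any(lens < min(plan$L_train)))
    stop("all sequences must be at least as long as the smallest crop length")
  crop <- vapply(lens, nearest_crop, integer(1L), L_train = plan$L_train)
  counts <- table(factor(crop, levels = plan$L_train))
  if (any(counts > plan$c_max))
    stop(sprintf("crop length %s has %d sequences but c_max is only %d",
                 names(counts)[which(counts > plan$c_max)[1L]],
                 max(counts), plan$c_max))
  out <- data.frame(seq = seq_along(sequences), crop = crop)
  rng <- local_rng(seed)
  for (Lt in plan$L_train) {
    deficit <- plan$c_max - sum(out$crop == Lt)
    if (deficit > 0L) {
      extra <- rng$sample_int(length(sequences), deficit, replace = TRUE)
      out <- rbind(out, data.frame(seq = extra, crop = Lt))
    }
  }
  out[order(out$crop, out$seq), , drop = FALSE]
}

# uniform random start offset for cropping a length-L frame to crop_len
crop_start <- function(L, crop_len, rng) {
  if (L < crop_len)
    stop(sprintf("cannot crop a length-%d chain to %d residues", L, crop_len))
  if (L == crop_len) return(1L)
  rng$sample_int(L - crop_len + 1L, 1L)
}
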