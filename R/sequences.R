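#' The 20 standard amino acids, one-letter codes
#'
#' Column order used for every one-hot encoding in the package.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# one-letter -> three-letter, for PDB residue names
AA_THREE <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
              G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
              M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
              S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

#' Construct a residue sequence
#'
#' A `residue_sequence` is the conditional input of the generative model: an
#' ordered run of one-letter codes over the 20 standard amino acids together
#' with its L x 20 one-hot encoding.
#'
#' @param letters Character scalar (e.g. `"AAAA"`) or character vector of
#'   one-letter codes. Upper-cased on input.
#' @param id Text label for the sequence.
#' @return An object of class `residue_sequence` with elements `id`,
#'   `letters` (character vector of length L) and `onehot` (L x 20 binary
#'   matrix, columns ordered as [AA_ALPHABET]).
#' @examples
#' s <- residue_sequence("ACDE", id = "toy")
#' s$onehot[1, "A"]
#' @export
residue_sequence <- function(letters, id = "seq") {
  if (length(letters) == 1L && nchar(letters[1L]) > 1L)
    letters <- strsplit(letters, "")[[1L]]
  letters <- toupper(as.character(letters))
  L <- length(letters)
  if (L < 2L)
    stop("a residue sequence needs at least 2 residues, got ", L)
  bad <- which(!(letters %in% AA_ALPHABET))
  if (length(bad) > 0L)
    stop(sprintf("sequence '%s': non-standard residue letter '%s' at position %d",
                 id, letters[bad[1L]], bad[1L]))
  onehot <- matrix(0L, nrow = L, ncol = 20L,
                   dimnames = list(NULL, AA_ALPHABET))
  onehot[cbind(seq_len(L), match(letters, AA_ALPHABET))] <- 1L
  structure(list(id = as.character(id), letters = letters, onehot = onehot),
            class = "residue_sequence")
}

#' @export
print.residue_sequence <- function(x, ...) {
  cat(sprintf("<residue_sequence> %s (L = %d)\n", x$id, length(x$letters)))
  cat(paste(x$letters, collapse = ""), "\n")
  invisible(x)
}

#' @export
length.residue_sequence <- function(x) length(x$letters)

#' Recover the letters of a one-hot encoding
#'
#' Inverse of the encoding built by [residue_sequence()].
#'
#' @param onehot L x 20 binary matrix with columns ordered as [AA_ALPHABET].
#' @return Character vector of one-letter codes.
#' @export
onehot_to_letters <- function(onehot) {
  stopifnot(is.matrix(onehot), ncol(onehot) == 20L)
  if (any(rowSums(onehot) != 1L))
    stop("every one-hot row must sum to exactly 1")
  AA_ALPHABET[max.col(onehot)]
}

#' Read amino acid sequences from a FASTA file
#'
#' @param path Path to an existing FASTA file.
#' @return List of [residue_sequence()] objects, record order preserved.
#'   Letters are upper-cased. Records containing letters outside the
#'   20-standard alphabet (including B, J, O, U, X, Z) are rejected with an
#'   error naming the record and the offending position.
#' @export
read_sequences_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(set))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    out[[i]] <- residue_sequence(toupper(as.character(set[[i]])), id = ids[i])
  }
  out
}

#' Write sequences to a FASTA file
#'
#' @param sequences A `residue_sequence` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sequences_fasta <- function(sequences, path) {
  if (inherits(sequences, "residue_sequence")) sequences <- list(sequences)
  lines <- unlist(lapply(sequences, function(s)
    c(paste0(">", s$id), paste(s$letters, collapse = ""))))
  writeLines(lines, path)
  invisible(path)
}

#' Generate fixture peptide sequences
#'
#' Deterministic sequence families used throughout the package for testing
#' and benchmarking without any external data:
#' \describe{
#'   \item{polyAla}{all-alanine chains; a random linear polymer without
#'     sequence-specific interactions under the coarse-grained potential.}
#'   \item{charge_blocks}{alternating 5-residue blocks of glutamate and
#'     lysine (acidic block first), emulating charge-segregated IDPs;
#'     e.g. L = 20 gives `EEEEEKKKKKEEEEEKKKKK`.}
#'   \item{random_mix}{uniform draws over the 20 standard letters, seeded.}
#' }
#'
#' @param preset One of `"polyAla"`, `"charge_blocks"`, `"random_mix"`.
#' @param lengths Integer vector of chain lengths, each within \[20, 200\].
#' @param seed Integer seed (used by `random_mix` only).
#' @return List of [residue_sequence()] objects, one per requested length.
#' @examples
#' make_fixture_sequences("charge_blocks", 20)[[1]]
#' @export
make_fixture_sequences <- function(preset = c("polyAla", "charge_blocks", "random_mix"),
                                   lengths, seed = 1L) {
  preset <- match.arg(preset)
  lengths <- as.integer(lengths)
  if (any(lengths < 20L | lengths > 200L))
    stop("fixture lengths must lie within [20, 200]")
  out <- vector("list", length(lengths))
  for (i in seq_along(lengths)) {
    L <- lengths[i]
    letters <- switch(preset,
      polyAla = rep("A", L),
      charge_blocks = {
        # 0-based block index: even -> E block, odd -> K block
        b <- (seq_len(L) - 1L) %/% 5L
        ifelse(b %% 2L == 0L, "E", "K")
      },
      random_mix = {
        rng <- local_rng(seed + 7L * i)
        AA_ALPHABET[floor(rng$unif(L) * 20) + 1L]
      })
    out[[i]] <- residue_sequence(letters,
                                 id = sprintf("%s_%d", preset, L))
  }
  out
}
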