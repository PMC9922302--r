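# Multi-model C-alpha PDB and CHARMM-style DCD trajectory I/O.
#
# Internal coordinates are always nm; both formats store Angstrom on disk
# (PDB by convention and fixed-width precision, DCD following the CHARMM /
# OpenMM convention), so values are scaled by 10 at the boundary.

NM_PER_ANGSTROM <- 0.1

#' Write a C-alpha ensemble to a trajectory file
#'
#' Writes either a multi-model PDB (one `MODEL`/`ENDMDL` block per frame,
#' C-alpha-only `ATOM` records, chain A, residue names taken from the
#' sequence) or a CHARMM-style binary DCD plus a single-model template PDB
#' carrying the topology.
#'
#' @param ensemble A [conformational_ensemble()].
#' @param path Output file path.
#' @param format `"pdb"` (multi-model PDB) or `"dcd"` (DCD + template PDB).
#' @param template_pdb For `format = "dcd"`: path of the template PDB;
#'   default replaces the `.dcd` extension with `.pdb`.
#' @return `path`, invisibly.
#' @export
write_ca_trajectory <- function(ensemble, path, format = c("pdb", "dcd"),
                                template_pdb = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(ensemble, "conformational_ensemble"))
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) stop("cannot write trajectory: directory does not exist: ",
                    dirname(path))
  if (format == "pdb") {
    write_pdb_models(ensemble, path)
  } else {
    if (is.null(template_pdb))
      template_pdb <- sub("\\.dcd$", ".pdb", path, ignore.case = TRUE)
    if (identical(template_pdb, path)) template_pdb <- paste0(path, ".pdb")
    write_pdb_models(subset_frames(ensemble, 1L), template_pdb)
    write_dcd(ensemble, path)
  }
  invisible(path)
}

write_pdb_models <- function(ensemble, path) {
  seq <- ensemble$sequence
  L <- length(seq)
  n <- n_frames(ensemble)
  res3 <- AA_THREE[seq$letters]
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("REMARK   1 CA TRACE %s NFRAMES %d", seq$id, n), con)
  for (f in seq_len(n)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- ensemble$xyz[f, , , drop = TRUE] / NM_PER_ANGSTROM  # nm -> A
    if (L == 1L) xyz <- matrix(xyz, ncol = 3L)
    lines <- sprintf(
      "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(L), res3, seq_len(L), xyz[, 1L], xyz[, 2L], xyz[, 3L])
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

read_pdb_models <- function(path, sequence) {
  lines <- readLines(path)
  frames <- list()
  cur <- NULL
  cur_lines <- integer(0L)
  flush_model <- function() {
    if (is.null(cur) || length(cur) == 0L) return(NULL)
    do.call(rbind, cur)
  }
  in_model <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[i]
    tag <- substr(ln, 1L, 6L)
    if (startsWith(tag, "MODEL")) {
      in_model <- TRUE
      cur <- list()
    } else if (startsWith(tag, "ENDMDL")) {
      m <- flush_model()
      if (!is.null(m)) frames[[length(frames) + 1L]] <- m
      cur <- NULL
      in_model <- FALSE
    } else if (tag == "ATOM  " || tag == "HETATM") {
      if (is.null(cur)) cur <- list()  # headerless single-model file
      x <- suppressWarnings(as.numeric(substr(ln, 31L, 38L)))
      y <- suppressWarnings(as.numeric(substr(ln, 39L, 46L)))
      z <- suppressWarnings(as.numeric(substr(ln, 47L, 54L)))
      if (any(is.na(c(x, y, z))))
        stop(sprintf("malformed ATOM record at line %d of %s", i, path))
      cur[[length(cur) + 1L]] <- c(x, y, z)
    }
  }
  m <- flush_model()
  if (!is.null(m)) frames[[length(frames) + 1L]] <- m
  if (length(frames) == 0L) stop("no ATOM records found in ", path)
  L <- length(sequence)
  for (f in seq_along(frames)) {
    if (nrow(frames[[f]]) != L)
      stop(sprintf("frame %d of %s has %d atoms but the sequence has %d residues",
                   f, path, nrow(frames[[f]]), L))
  }
  lapply(frames, function(m) m * NM_PER_ANGSTROM)  # A -> nm
}

write_dcd <- function(ensemble, path) {
  n <- n_frames(ensemble)
  L <- dim(ensemble$xyz)[2L]
  con <- file(path, open = "wb")
  on.exit(close(con))
  wrec <- function(writer) {
    # Fortran unformatted record: payload length before and after
    raw_con <- rawConnection(raw(0L), open = "wb")
    writer(raw_con)
    payload <- rawConnectionValue(raw_con)
    close(raw_con)
    writeBin(length(payload), con, size = 4L, endian = "little")
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4L, endian = "little")
  }
  wrec(function(c0) {
    writeBin(charToRaw("CORD"), c0)
    icntrl <- integer(20L)
    icntrl[1L] <- n       # frames
    icntrl[2L] <- 1L      # first step
    icntrl[3L] <- 1L      # save interval
    icntrl[4L] <- n       # total steps
    icntrl[20L] <- 24L    # format version
    writeBin(icntrl, c0, size = 4L, endian = "little")
  })
  wrec(function(c0) {
    writeBin(1L, c0, size = 4L, endian = "little")
    title <- sprintf("%-80s", paste("CA trace", ensemble$sequence$id))
    writeBin(charToRaw(substr(title, 1L, 80L)), c0)
  })
  wrec(function(c0) writeBin(L, c0, size = 4L, endian = "little"))
  for (f in seq_len(n)) {
    xyz <- ensemble$xyz[f, , , drop = TRUE] / NM_PER_ANGSTROM
    if (L == 1L) xyz <- matrix(xyz, ncol = 3L)
    for (d in 1:3)
      wrec(function(c0) writeBin(as.numeric(xyz[, d]), c0, size = 4L,
                                 endian = "little"))
  }
  invisible(path)
}

read_dcd <- function(path, sequence) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  rrec <- function() {
    len <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (length(len) == 0L) return(NULL)
    payload <- readBin(con, "raw", n = len)
    tail_len <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (length(tail_len) == 0L || tail_len != len)
      stop("corrupt DCD record in ", path)
    payload
  }
  hdr <- rrec()
  if (is.null(hdr) || rawToChar(hdr[1:4]) != "CORD")
    stop("not a DCD file: ", path)
  icntrl <- readBin(hdr[-(1:4)], "integer", n = 20L, size = 4L,
                    endian = "little")
  nframes <- icntrl[1L]
  rrec()  # title block
  nat_rec <- rrec()
  natoms <- readBin(nat_rec, "integer", n = 1L, size = 4L, endian = "little")
  L <- length(sequence)
  if (natoms != L)
    stop(sprintf("DCD has %d atoms but the sequence has %d residues",
                 natoms, L))
  frames <- vector("list", nframes)
  for (f in seq_len(nframes)) {
    m <- matrix(NA_real_, nrow = natoms, ncol = 3L)
    for (d in 1:3) {
      rec <- rrec()
      if (is.null(rec)) stop(sprintf("DCD truncated at frame %d", f))
      m[, d] <- readBin(rec, "numeric", n = natoms, size = 4L,
                        endian = "little")
    }
    frames[[f]] <- m * NM_PER_ANGSTROM
  }
  frames
}

#' Read a C-alpha trajectory
#'
#' Reads a multi-model PDB or a DCD file written by [write_ca_trajectory()]
#' (or by any tool following the same conventions) into a
#' [conformational_ensemble()]. Coordinates are converted from Angstrom to
#' nm.
#'
#' @param path Trajectory file. Format is detected from the extension
#'   (`.dcd` = DCD, anything else = PDB).
#' @param sequence The owning [residue_sequence()]; the file's atom count
#'   must equal its length.
#' @param provenance Provenance tag for the resulting ensemble.
#' @return A [conformational_ensemble()], one conformation per frame.
#' @export
read_ca_trajectory <- function(path, sequence, provenance = "simulated") {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  frames <- if (grepl("\\.dcd$", path, ignore.case = TRUE))
    read_dcd(path, sequence)
  else
    read_pdb_models(path, sequence)
  conformational_ensemble(sequence, frames, provenance = provenance)
}
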