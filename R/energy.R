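#' Coarse-grained potential energy of a conformation
#'
#' Evaluates the four-term residue-level potential: harmonic bonds over
#' successive beads, harmonic angles over consecutive triples, a 10-5
#' contact term `4(eps + eps_cation_pi)((sigma/r)^10 - (sigma/r)^5)` over
#' non-bonded pairs (`|i - j| >= 2`, within the cutoff, minimum-image), and
#' the screened long-range term `(A_i A_j + A0_i A0_j)/r exp(-r/kappa)`.
#'
#' @param conf `L x 3` coordinate matrix, nm.
#' @param seq The [residue_sequence()] of the chain.
#' @param ff [forcefield_parameters()].
#' @return An `energy_breakdown`: list with `bond`, `angle`, `short_range`,
#'   `long_range` and `total` (kJ/mol).
#' @export
cg_energy <- function(conf, seq, ff = forcefield_parameters()) {
  conf <- as.matrix(conf)
  check_conf(conf, seq)
  p <- ff_params_for_sequence(seq, ff)
  e <- cpp_cg_energy(conf, p)
  structure(list(bond = e[["bond"]], angle = e[["angle"]],
                 short_range = e[["short_range"]],
                 long_range = e[["long_range"]],
                 total = sum(e)),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("bond %.4f + angle %.4f + short %.4f + long %.4f = %.4f kJ/mol\n",
              x$bond, x$angle, x$short_range, x$long_range, x$total))
  invisible(x)
}

#' Analytic forces of the coarse-grained potential
#'
#' @inheritParams cg_energy
#' @return `L x 3` matrix of forces, kJ/(mol nm); equals the negative
#'   gradient of [cg_energy()] with the same cutoff convention.
#' @export
cg_forces <- function(conf, seq, ff = forcefield_parameters()) {
  conf <- as.matrix(conf)
  check_conf(conf, seq)
  p <- ff_params_for_sequence(seq, ff)
  cpp_cg_forces(conf, p)
}

#' Total energies over an ensemble
#'
#' @param ens A [conformational_ensemble()].
#' @param ff [forcefield_parameters()].
#' @return Numeric vector of total potential energies (kJ/mol), one per
#'   frame.
#' @export
ensemble_energies <- function(ens, ff = forcefield_parameters()) {
  p <- ff_params_for_sequence(ens$sequence, ff)
  vapply(seq_len(n_frames(ens)),
         function(i) sum(cpp_cg_energy(get_frame(ens, i), p)),
         numeric(1L))
}

check_conf <- function(conf, seq) {
  L <- length(seq)
  if (!is.matrix(conf) || ncol(conf) != 3L)
    stop("a conformation must be an L x 3 matrix")
  if (nrow(conf) != L)
    stop(sprintf("conformation has %d beads but the sequence has %d residues",
                 nrow(conf), L))
  if (any(!is.finite(conf))) stop("non-finite coordinates in conformation")
  invisible(TRUE)
}
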