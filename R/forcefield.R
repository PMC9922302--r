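# Residue-level force field parameterization.
#
# The potential has four terms: harmonic bonds, harmonic angles, a 10-5
# contact term with cation-pi augmentation, and a screened long-range term
# combining Debye-Hueckel electrostatics with a polar-solvation repulsion.

KB_KJ <- 0.00831446261815324  # Boltzmann constant, kJ mol^-1 K^-1

# default polar / non-polar split (overridable via forcefield_parameters)
POLAR_RESIDUES    <- c("R", "K", "D", "E", "N", "Q", "H", "S", "T", "Y", "C", "W")
NONPOLAR_RESIDUES <- c("A", "V", "L", "I", "P", "F", "M", "G")

# mean residue volumes (Zamyatnin-type table) -> equal-volume sphere radii
default_sigma_table <- function() {
  path <- system.file("extdata", "residue_volumes.csv", package = "idpgem")
  vols <- utils::read.csv(path, stringsAsFactors = FALSE)
  sigma <- (3 * vols$volume_A3 / (4 * pi))^(1 / 3) / 10  # Angstrom^3 -> nm
  setNames(sigma, vols$residue)[AA_ALPHABET]
}

#' Coarse-grained force field parameters
#'
#' All energies in kJ/mol, lengths in nm. Per-residue radii default to the
#' radii of spheres with the mean amino-acid residue volumes; the
#' polar/non-polar split and every constant are overridable.
#'
#' @param k_bond Bond spring constant, kJ/(mol nm^2).
#' @param l0 Equilibrium bond length, nm.
#' @param k_angle Angle spring constant, kJ/(mol rad^2).
#' @param theta0 Equilibrium angle, rad.
#' @param eps_polar,eps_nonpolar Per-residue contact well depths, kJ/mol;
#'   a pair uses the arithmetic mean of its two per-residue values.
#' @param eps_cation_pi Extra well depth for basic (R/K) x aromatic (F/Y/W)
#'   pairs, kJ/mol.
#' @param kappa Debye screening length, nm.
#' @param cutoff Non-bonded cutoff, nm.
#' @param box_edge Cubic box edge for the minimum-image convention, nm.
#' @param A0_polar Solvation-repulsion coefficient for polar residues.
#' @param sigma_per_residue Named numeric vector of per-residue radii (nm)
#'   over [AA_ALPHABET].
#' @param polar_residues Character vector naming the polar residues.
#' @return Object of class `forcefield_parameters`.
#' @export
forcefield_parameters <- function(k_bond = 4184, l0 = 0.38,
                                  k_angle = 4.184, theta0 = pi,
                                  eps_polar = 0.40, eps_nonpolar = 0.41,
                                  eps_cation_pi = 0.3,
                                  kappa = 1.0, cutoff = 3.0, box_edge = 300,
                                  A0_polar = 0.05,
                                  sigma_per_residue = default_sigma_table(),
                                  polar_residues = POLAR_RESIDUES) {
  if (any(sigma_per_residue <= 0)) stop("all residue radii must be positive")
  if (!all(AA_ALPHABET %in% names(sigma_per_residue)))
    stop("sigma_per_residue must cover all 20 standard residues")
  charge <- setNames(rep(0, 20), AA_ALPHABET)
  charge[c("R", "K")] <- +1
  charge[c("D", "E")] <- -1
  polar <- AA_ALPHABET %in% polar_residues
  names(polar) <- AA_ALPHABET
  structure(list(
    k_bond = k_bond, l0 = l0, k_angle = k_angle, theta0 = theta0,
    eps_polar = eps_polar, eps_nonpolar = eps_nonpolar,
    eps_cation_pi = eps_cation_pi, kappa = kappa, cutoff = cutoff,
    box_edge = box_edge, A0_polar = A0_polar,
    sigma_per_residue = sigma_per_residue[AA_ALPHABET],
    charge_per_residue = charge, polar = polar
  ), class = "forcefield_parameters")
}

#' @export
print.forcefield_parameters <- function(x, ...) {
  cat("<forcefield_parameters>\n")
  cat(sprintf("  bonds: k = %g kJ/(mol nm^2), l0 = %g nm\n", x$k_bond, x$l0))
  cat(sprintf("  angles: k = %g kJ/(mol rad^2), theta0 = %g rad\n",
              x$k_angle, x$theta0))
  cat(sprintf("  eps polar/nonpolar = %g/%g, cation-pi = %g kJ/mol\n",
              x$eps_polar, x$eps_nonpolar, x$eps_cation_pi))
  cat(sprintf("  kappa = %g nm, cutoff = %g nm, box = %g nm\n",
              x$kappa, x$cutoff, x$box_edge))
  invisible(x)
}

# Per-residue parameter vectors for a concrete sequence, in the layout the
# compiled kernels expect. A_i = sign(q_i) sqrt(0.75 |q_i|) is derived here,
# never stored.
ff_params_for_sequence <- function(seq, ff) {
  stopifnot(inherits(seq, "residue_sequence"),
            inherits(ff, "forcefield_parameters"))
  lets <- seq$letters
  q <- ff$charge_per_residue[lets]
  polar <- ff$polar[lets]
  list(
    sigma = unname(ff$sigma_per_residue[lets]),
    eps = unname(ifelse(polar, ff$eps_polar, ff$eps_nonpolar)),
    A = unname(sign(q) * sqrt(0.75 * abs(q))),
    A0 = unname(ifelse(polar, ff$A0_polar, 0)),
    is_cationic = as.integer(lets %in% c("R", "K")),
    is_aromatic = as.integer(lets %in% c("F", "Y", "W")),
    k_bond = ff$k_bond, l0 = ff$l0, k_angle = ff$k_angle,
    theta0 = ff$theta0, eps_cation_pi = ff$eps_cation_pi,
    kappa = ff$kappa, cutoff = ff$cutoff, box_edge = ff$box_edge
  )
}

#' Read force field parameters from a YAML config
#'
#' @param path YAML file; keys match the arguments of
#'   [forcefield_parameters()] (scalar constants plus optional
#'   `sigma_per_residue` and `polar_residues`).
#' @return A [forcefield_parameters()] object.
#' @export
read_forcefield_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$sigma_per_residue))
    cfg$sigma_per_residue <- unlist(cfg$sigma_per_residue)
  if (!is.null(cfg$polar_residues))
    cfg$polar_residues <- unlist(cfg$polar_residues)
  do.call(forcefield_parameters, cfg)
}

#' Write force field parameters to a YAML config
#'
#' @param ff A [forcefield_parameters()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_forcefield_yaml <- function(ff, path) {
  out <- list(
    k_bond = ff$k_bond, l0 = ff$l0, k_angle = ff$k_angle, theta0 = ff$theta0,
    eps_polar = ff$eps_polar, eps_nonpolar = ff$eps_nonpolar,
    eps_cation_pi = ff$eps_cation_pi, kappa = ff$kappa, cutoff = ff$cutoff,
    box_edge = ff$box_edge, A0_polar = ff$A0_polar,
    sigma_per_residue = as.list(ff$sigma_per_residue),
    polar_residues = names(ff$polar)[ff$polar]
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
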