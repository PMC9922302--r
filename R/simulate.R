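#' Simulation protocol settings
#'
#' Defaults mirror the reference Langevin protocol: friction 0.01/ps,
#' production timestep 0.02 ps, 298 K, cubic 300 nm box, frames every
#' 200 ps, 5000 steepest-descent minimization steps and 20,000
#' equilibration steps at a 0.01 ps timestep.
#'
#' @param timestep Production timestep, ps.
#' @param friction Langevin friction coefficient, 1/ps.
#' @param temperature Temperature, K.
#' @param n_steps Production steps.
#' @param save_interval_ps Interval between saved frames, ps.
#' @param seed Integer seed.
#' @param minimize_steps Steepest-descent steps before equilibration.
#' @param equil_steps Equilibration MD steps.
#' @param equil_timestep Equilibration timestep, ps.
#' @param mass Uniform bead mass, g/mol (average residue mass).
#' @return Object of class `simulation_protocol`.
#' @export
simulation_protocol <- function(timestep = 0.02, friction = 0.01,
                                temperature = 298, n_steps = 50000L,
                                save_interval_ps = 200, seed = 1L,
                                minimize_steps = 5000L, equil_steps = 20000L,
                                equil_timestep = 0.01, mass = 110) {
  stopifnot(timestep > 0, equil_timestep > 0, friction >= 0,
            temperature > 0, n_steps >= 1, save_interval_ps > 0)
  save_interval_steps <- as.integer(round(save_interval_ps / timestep))
  if (save_interval_steps < 1L) stop("save interval below one timestep")
  structure(list(timestep = timestep, friction = friction,
                 temperature = temperature, n_steps = as.integer(n_steps),
                 save_interval_ps = save_interval_ps,
                 save_interval_steps = save_interval_steps,
                 seed = as.integer(seed),
                 minimize_steps = as.integer(minimize_steps),
                 equil_steps = as.integer(equil_steps),
                 equil_timestep = equil_timestep, mass = mass),
            class = "simulation_protocol")
}

#' Steepest-descent energy minimization
#'
#' Adaptive-step steepest descent on the coarse-grained potential; the
#' energy is non-increasing across accepted steps and the run stops at
#' `max_steps` or when the largest force component falls below `gtol`.
#'
#' @param conf `L x 3` starting coordinates, nm.
#' @param seq [residue_sequence()].
#' @param ff [forcefield_parameters()].
#' @param max_steps Maximum accepted steps.
#' @param step_nm Initial trial displacement of the largest-force bead, nm.
#' @param gtol Convergence threshold on the max force component,
#'   kJ/(mol nm).
#' @return The minimized `L x 3` coordinate matrix with attributes
#'   `energy` (kJ/mol) and `steps`.
#' @export
minimize_steepest_descent <- function(conf, seq, ff = forcefield_parameters(),
                                      max_steps = 5000L, step_nm = 0.01,
                                      gtol = 1e-4) {
  conf <- as.matrix(conf)
  check_conf(conf, seq)
  p <- ff_params_for_sequence(seq, ff)
  res <- cpp_minimize(conf, p, as.integer(max_steps), step_nm, gtol)
  structure(res$coords, energy = res$energy, steps = res$steps)
}

#' Langevin dynamics simulation
#'
#' BAOAB-discretized Langevin dynamics of the coarse-grained chain with
#' uniform bead masses. Coordinates are saved every
#' `protocol$save_interval_steps` steps; trajectories are deterministic for
#' a fixed protocol seed. Velocities are drawn from the Maxwell-Boltzmann
#' distribution at the target temperature unless supplied.
#'
#' @param conf Starting `L x 3` coordinates, nm (a minimized or
#'   equilibrated structure is recommended).
#' @param seq [residue_sequence()].
#' @param ff [forcefield_parameters()].
#' @param protocol A [simulation_protocol()].
#' @param velocities Optional starting `L x 3` velocity matrix, nm/ps.
#' @return A [conformational_ensemble()] of the saved frames, with
#'   attributes `ke_mean` (mean kinetic energy per integration step,
#'   kJ/mol), `final_coords` and `final_velocities`.
#' @export
langevin_simulate <- function(conf, seq, ff = forcefield_parameters(),
                              protocol = simulation_protocol(),
                              velocities = NULL) {
  conf <- as.matrix(conf)
  check_conf(conf, seq)
  p <- ff_params_for_sequence(seq, ff)
  res <- cpp_langevin(conf, p, protocol$n_steps, protocol$timestep,
                      protocol$friction, protocol$temperature,
                      protocol$save_interval_steps, protocol$seed,
                      protocol$mass, velocities)
  ens <- conformational_ensemble(seq, res$frames, provenance = "simulated")
  attr(ens, "ke_mean") <- res$ke_mean
  attr(ens, "final_coords") <- res$coords
  attr(ens, "final_velocities") <- res$velocities
  ens
}

# minimize + short equilibration, returning coordinates and velocities
equilibrate_chain <- function(seq, ff, protocol, seed) {
  start <- init_random_coordinates(seq, seed = seed)
  mini <- minimize_steepest_descent(start, seq, ff,
                                    max_steps = protocol$minimize_steps)
  eq_protocol <- simulation_protocol(
    timestep = protocol$equil_timestep, friction = protocol$friction,
    temperature = protocol$temperature, n_steps = protocol$equil_steps,
    save_interval_ps = protocol$equil_steps * protocol$equil_timestep,
    seed = seed, mass = protocol$mass)
  eq <- langevin_simulate(mini, seq, ff, eq_protocol)
  list(coords = attr(eq, "final_coords"),
       velocities = attr(eq, "final_velocities"))
}

#' Reference ensemble generation protocol
#'
#' Runs independent Langevin trajectories (each minimized and equilibrated
#' from fresh self-avoiding-walk coordinates) and concatenates their saved
#' frames. At `scale = 1` this reproduces the full reference protocol:
#' 5 runs of 1000 ns production with frames every 200 ps, i.e. 25,000
#' frames. Smaller scales shrink each run proportionally while preserving
#' the frame spacing.
#'
#' @param seq [residue_sequence()].
#' @param ff [forcefield_parameters()].
#' @param scale Fraction of the full protocol in (0, 1].
#' @param seed Integer seed; per-run seeds are derived from it.
#' @param n_runs Number of independent trajectories.
#' @param protocol Base [simulation_protocol()]; its `n_steps` is ignored
#'   and set from `scale`.
#' @return A [conformational_ensemble()] with `n_runs` x `5000 * scale`
#'   frames, with attribute `run_id` giving each frame's trajectory index.
#' @export
reference_protocol <- function(seq, ff = forcefield_parameters(),
                               scale = 1, seed = 1L, n_runs = 5L,
                               protocol = simulation_protocol()) {
  stopifnot(scale > 0, scale <= 1)
  full_steps_per_run <- 1000e3 / protocol$timestep  # 1000 ns production
  n_steps <- as.integer(round(full_steps_per_run * scale))
  n_steps <- max(n_steps, protocol$save_interval_steps)
  rng <- local_rng(seed)
  run_seeds <- rng$child(2L * n_runs)
  parts <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    state <- equilibrate_chain(seq, ff, protocol, seed = run_seeds[2L * r - 1L])
    run_protocol <- simulation_protocol(
      timestep = protocol$timestep, friction = protocol$friction,
      temperature = protocol$temperature, n_steps = n_steps,
      save_interval_ps = protocol$save_interval_ps,
      seed = run_seeds[2L * r], mass = protocol$mass)
    parts[[r]] <- langevin_simulate(state$coords, seq, ff, run_protocol,
                                    velocities = state$velocities)
  }
  out <- bind_ensembles(parts, provenance = "simulated")
  attr(out, "run_id") <- rep(seq_len(n_runs),
                             vapply(parts, n_frames, integer(1L)))
  out
}
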