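## Langevin dynamics in reduced units (kB = 1, unit atom masses by default).
##
## The integrator is the BAOAB splitting of Langevin dynamics: half kick,
## half drift, Ornstein-Uhlenbeck velocity refresh, half drift, half kick.
## With friction = 0 the O step is the identity and the scheme reduces to
## symplectic velocity Verlet (NVE).  All randomness is consumed from a
## counter-based generator seeded per run, so trajectories are reproducible
## bit-for-bit on one build.

#' Langevin run parameters
#'
#' @param reduced_temperature dimensionless temperature (production default
#'   0.582; the disordered-tail protocol uses 1.0).
#' @param timestep integration step in reduced time (default 0.002).
#' @param friction Langevin friction, inverse reduced time (default 1.0;
#'   0 gives NVE velocity Verlet).
#' @param n_steps number of steps.
#' @param seed integer RNG seed for the thermostat noise.
#' @param save_interval save a frame every this many steps.
#' @export
langevin_params <- function(reduced_temperature = 0.582, timestep = 0.002,
                            friction = 1.0, n_steps = 10000L, seed = 1L,
                            save_interval = 500L) {
  if (reduced_temperature < 0) stop("parameter error: negative temperature")
  if (timestep <= 0) stop("parameter error: timestep must be > 0")
  if (friction < 0) stop("parameter error: friction must be >= 0")
  if (n_steps < 0) stop("parameter error: n_steps must be >= 0")
  if (save_interval < 1) stop("parameter error: save_interval must be >= 1")
  structure(list(reduced_temperature = reduced_temperature,
                 timestep = timestep, friction = friction,
                 n_steps = as.integer(n_steps), seed = as.integer(seed),
                 save_interval = as.integer(save_interval)),
            class = "langevin_params")
}

#' Simulation state
#'
#' @param positions `n x 3` matrix, nm.
#' @param velocities `n x 3` matrix (zeros if omitted).
#' @param time reduced time of the state.
#' @export
simulation_state <- function(positions, velocities = NULL, time = 0) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be n x 3")
  if (!all(is.finite(positions))) stop("non-finite positions")
  if (is.null(velocities)) {
    velocities <- matrix(0, nrow(positions), 3)
  } else {
    velocities <- as.matrix(velocities)
    if (!all(dim(velocities) == dim(positions))) {
      stop("velocity shape does not match positions")
    }
    if (!all(is.finite(velocities))) stop("non-finite velocities")
  }
  structure(list(positions = positions, velocities = velocities, time = time),
            class = "simulation_state")
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Each velocity component is drawn from `N(0, sqrt(T/m))`; at `T = 0` all
#' velocities are zero.  Deterministic given the seed.
#'
#' @param state a [simulation_state()], [mol_structure()] or atom count.
#' @param temperature reduced temperature.
#' @param seed integer seed.
#' @param masses per-atom masses (default unit masses).
#' @return a [simulation_state()] with fresh velocities (positions preserved
#'   when a state/structure was given; a bare count returns the velocity
#'   matrix).
#' @export
initialize_velocities <- function(state, temperature, seed, masses = NULL) {
  if (temperature < 0) stop("parameter error: negative temperature")
  n <- if (inherits(state, "simulation_state")) nrow(state$positions)
       else if (inherits(state, "mol_structure")) n_atoms(state)
       else as.integer(state)
  if (is.null(masses)) masses <- rep(1, n)
  stopifnot(length(masses) == n)
  set.seed(seed)
  vel <- matrix(rnorm(3 * n), n, 3) * sqrt(temperature / masses)
  if (temperature == 0) vel[] <- 0
  if (inherits(state, "simulation_state")) {
    simulation_state(state$positions, vel, state$time)
  } else if (inherits(state, "mol_structure")) {
    simulation_state(coords(state), vel)
  } else {
    vel
  }
}

#' Run Langevin dynamics
#'
#' @param topology an `ff_topology`.
#' @param state0 initial [simulation_state()] (or a [mol_structure()], taken
#'   with zero velocities).
#' @param params a [langevin_params()].
#' @param restraints optional [restraint_spec()].
#' @param masses per-atom masses (default unit).
#' @return a [cg_trajectory()]; the final [simulation_state()], the
#'   potential/kinetic energy at each saved frame and the run manifest are
#'   attached as attributes `final_state`, `epot`, `ekin`, `manifest`.
#' @export
run_langevin <- function(topology, state0, params, restraints = NULL,
                         masses = NULL, wall = NULL) {
  stopifnot(inherits(topology, "ff_topology"),
            inherits(params, "langevin_params"))
  if (inherits(state0, "mol_structure")) state0 <- simulation_state(coords(state0))
  stopifnot(inherits(state0, "simulation_state"))
  n <- topology$n_atoms
  if (nrow(state0$positions) != n) {
    stop("state does not match topology atom count")
  }
  if (is.null(masses)) masses <- rep(1, n)
  res <- .cg_langevin_cpp(state0$positions, state0$velocities,
                          topo_cpp_list(topology, restraints, wall),
                          as.numeric(masses),
                          params$timestep, params$friction,
                          params$reduced_temperature, params$n_steps,
                          params$save_interval, params$seed)
  if (res$blow_step >= 0) {
    stop("dynamics blow-up: non-finite coordinates at step ", res$blow_step)
  }
  ns <- res$n_saved
  fr <- aperm(array(res$frames, dim = dim(res$frames)), c(3, 2, 1))
  fr <- fr[seq_len(ns), , , drop = FALSE]
  traj <- cg_trajectory(fr, res$times[seq_len(ns)],
                        elements = topology$atoms$element,
                        metadata = list(seed = params$seed,
                                        temperature = params$reduced_temperature,
                                        timestep = params$timestep,
                                        friction = params$friction,
                                        n_steps = params$n_steps,
                                        save_interval = params$save_interval))
  attr(traj, "final_state") <- simulation_state(res$pos, res$vel,
                                                params$n_steps * params$timestep)
  attr(traj, "epot") <- res$epot[seq_len(ns)]
  attr(traj, "ekin") <- res$ekin[seq_len(ns)]
  traj
}

#' Kinetic temperature of saved frames
#'
#' `T_kin = 2 KE / (3 N)` per saved frame (unit masses, kB = 1).
#'
#' @param trajectory a trajectory returned by [run_langevin()].
#' @export
kinetic_temperature <- function(trajectory) {
  ekin <- attr(trajectory, "ekin")
  if (is.null(ekin)) stop("trajectory carries no kinetic-energy record")
  2 * ekin / (3 * dim(trajectory$frames)[2])
}

## integrated autocorrelation time (in sampling intervals) of a series
integrated_act <- function(x, max_lag = min(length(x) - 2, 200)) {
  x <- x - mean(x)
  v <- mean(x^2)
  if (v <= 0) return(1)
  tau <- 1
  for (lag in seq_len(max_lag)) {
    rho <- mean(x[seq_len(length(x) - lag)] * x[-seq_len(lag)]) / v
    if (rho < 0.05) break
    tau <- tau + 2 * rho
  }
  tau
}

#' Generate disordered terminal-tail conformations
#'
#' Runs a restrained high-temperature simulation from the compact
#' conformation: all non-tail atoms are held near their compact positions by
#' harmonic restraints while the tails sample freely at the elevated
#' temperature, erasing any force-field bias.  Conformations are sampled at
#' a fixed stride after an equilibration stride.
#'
#' @param compact compact-state [mol_structure()] with tail annotations.
#' @param topology the (mature-reference) `ff_topology`.
#' @param tail_ranges optional named list `chain_id -> c(first, last)`
#'   residue range treated as disordered; defaults to each chain's annotated
#'   tail range.
#' @param n_samples number of conformations to return (>= 1).
#' @param high_T reduced temperature of the sampling run (default 1.0).
#' @param restraint_k spring constant for non-tail atoms (reduced units/nm^2).
#' @param seed integer seed.
#' @param stride steps between samples (default 2000).
#' @param equilibration_strides strides discarded before sampling.
#' @param interior_only keep only samples whose tail beads all lie inside the
#'   outer shell surface; extra candidates are drawn automatically.
#' @param containment if `TRUE` (default) a half-harmonic radial wall just
#'   outside the compact shell surface confines the tails during the
#'   high-temperature run, emulating the sealed cavities of a procapsid
#'   (whose tails cannot pre-translocate); the wall exists only in this
#'   stage, never in production runs.
#' @return list of `n_samples` [mol_structure()]s; a manifest (stride,
#'   measured tail-Rg autocorrelation time, any warnings) is attached as an
#'   attribute.
#' @export
generate_disordered_tails <- function(compact, topology, tail_ranges = NULL,
                                      n_samples = 4, high_T = 1.0,
                                      restraint_k = 1000, seed = 1L,
                                      stride = 4500L,
                                      equilibration_strides = 2L,
                                      interior_only = FALSE,
                                      containment = TRUE) {
  stopifnot(inherits(compact, "mol_structure"), n_samples >= 1)
  tail_idx <- integer()
  if (is.null(tail_ranges)) {
    ch <- compact$chains
    for (k in seq_len(nrow(ch))) {
      if (!is.na(ch$tail_start[k])) {
        tail_idx <- c(tail_idx, atom_indices(compact, ch$chain_id[k],
                                             c(ch$tail_start[k], ch$tail_end[k])))
      }
    }
  } else {
    for (cid in names(tail_ranges)) {
      tail_idx <- c(tail_idx, atom_indices(compact, cid, tail_ranges[[cid]]))
    }
  }
  if (length(tail_idx) == 0) stop("no tail residues to disorder")
  body_idx <- setdiff(seq_len(n_atoms(compact)), tail_idx)
  if (length(body_idx) == 0) stop("no non-tail atoms to restrain")
  xyz0 <- coords(compact)
  restr <- restraint_spec(body_idx, xyz0[body_idx, , drop = FALSE], restraint_k)

  n_cand <- if (interior_only) max(3L * n_samples, n_samples + 4L) else n_samples
  fine <- max(10L, as.integer(stride / 10))
  n_steps <- as.integer(stride * (equilibration_strides + n_cand))
  st0 <- initialize_velocities(simulation_state(xyz0), high_T, seed)
  ## a slightly smaller step than production: high-temperature collisions
  ## of the unstructured tails are the stiffest events the model produces
  pars <- langevin_params(reduced_temperature = high_T, timestep = 0.0015,
                          friction = 1.0, n_steps = n_steps, seed = seed,
                          save_interval = fine)
  ## the wall sits at the shell mid-surface: tails may enter pore mouths
  ## but cannot pass through to the exterior during tail generation
  shell_surface <- stats::median(sqrt(rowSums(xyz0[body_idx, , drop = FALSE]^2)))
  wall <- if (containment) list(radius = shell_surface + 0.03, k = 200) else NULL
  traj <- run_langevin(topology, st0, pars, restraints = restr, wall = wall)

  ## tail-Rg decorrelation diagnostic on the finely saved series
  tail_rg <- vapply(seq_len(n_frames(traj)), function(i) {
    radius_of_gyration(frame_coords(traj, i)[tail_idx, , drop = FALSE])
  }, numeric(1))
  tau_frames <- integrated_act(tail_rg)
  tau_steps <- tau_frames * fine
  warn <- NULL
  if (stride < tau_steps) {
    warn <- sprintf(paste0("sampling stride (%d steps) is shorter than the ",
                           "measured tail-Rg autocorrelation time (%.0f steps)"),
                    stride, tau_steps)
    warning(warn)
  }

  ## a tail bead counts as escaped only when it lies clearly beyond the
  ## containment turnaround: transient thermal excursions against the wall
  ## (or part-way into a pore mouth) are interior
  body_radius <- shell_surface + 0.40
  steps <- round(traj$times / pars$timestep)
  sample_frames <- match((equilibration_strides + seq_len(n_cand)) * stride,
                         steps)
  sample_frames <- sample_frames[!is.na(sample_frames)]
  out <- list(); kept <- 0
  for (fi in sample_frames) {
    if (kept >= n_samples) break
    xyz <- frame_coords(traj, fi)
    if (interior_only) {
      rr <- sqrt(rowSums(xyz[tail_idx, , drop = FALSE]^2))
      if (any(rr > body_radius)) next
    }
    kept <- kept + 1
    out[[kept]] <- set_coords(compact, xyz)
    out[[kept]]$source <- sprintf("%s + disordered tails (sample %d, seed %d)",
                                  compact$source, kept, seed)
  }
  if (kept == 0) {
    stop("no sampled tail conformation satisfied the interior criterion; ",
         "increase the stride or check the containment settings")
  }
  if (kept < n_samples) {
    warning("only ", kept, " of ", n_samples,
            " requested tail conformations satisfied the interior criterion")
  }
  attr(out, "manifest") <- list(seed = seed, high_T = high_T,
                                restraint_k = restraint_k, stride = stride,
                                tail_rg_act_steps = tau_steps,
                                stride_warning = warn,
                                n_candidates = n_cand, n_kept = kept)
  out
}
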