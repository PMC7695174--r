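test_that("velocity initialisation is Maxwell-Boltzmann, deterministic, zero at T=0", {
  v0 <- initialize_velocities(100, 0, seed = 1)
  expect_true(all(v0 == 0))

  v1 <- initialize_velocities(10000, 0.582, seed = 2)
  v2 <- initialize_velocities(10000, 0.582, seed = 2)
  expect_identical(v1, v2)
  ## equipartition: mean kinetic energy per degree of freedom = T/2
  expect_lt(abs(mean(v1^2) / 2 - 0.582 / 2) / (0.582 / 2), 0.02)

  expect_error(initialize_velocities(10, -1, seed = 1), "negative temperature")
})

test_that("friction zero reduces to energy-conserving velocity Verlet", {
  topo <- build_topology(fx$harmonic_dimer, param_table = NULL)
  x0 <- coords(fx$harmonic_dimer)
  x0[2, 1] <- x0[2, 1] + 0.03
  tr <- run_langevin(topo, simulation_state(x0),
                     langevin_params(friction = 0, timestep = 5e-4,
                                     n_steps = 10000, save_interval = 100,
                                     seed = 1))
  E <- attr(tr, "epot") + attr(tr, "ekin")
  expect_lt((max(E) - min(E)) / abs(mean(E)), 1e-4)
})

test_that("zero steps returns only the initial frame; runs are reproducible", {
  topo <- build_topology(fx$harmonic_dimer, param_table = NULL)
  st <- simulation_state(coords(fx$harmonic_dimer))
  tr0 <- run_langevin(topo, st, langevin_params(n_steps = 0, seed = 1))
  expect_equal(n_frames(tr0), 1)

  p <- langevin_params(n_steps = 2000, save_interval = 200, seed = 42)
  st1 <- initialize_velocities(st, 0.582, 42)
  a <- run_langevin(topo, st1, p)
  b <- run_langevin(topo, st1, p)
  expect_identical(a$frames, b$frames)
})

test_that("a thermostatted particle in a harmonic well samples variance T/k", {
  topo <- bare_topology(1)
  restr <- restraint_spec(1L, matrix(0, 1, 3), k = 2)
  tr <- run_langevin(topo, simulation_state(matrix(0, 1, 3)),
                     langevin_params(reduced_temperature = 0.5,
                                     timestep = 0.01, friction = 1,
                                     n_steps = 400000, save_interval = 20,
                                     seed = 7),
                     restraints = restr)
  xs <- tr$frames[, 1, ]
  expect_lt(abs(mean(apply(xs, 2, var)) - 0.25) / 0.25, 0.05)
})

test_that("double-well occupancies match the Boltzmann ratio", {
  ## free particle between two anchored partners with unequal contact
  ## depths: basins around each anchor, partitioned at the mid-plane
  topo <- bare_topology(3)
  topo$contacts <- data.frame(i = c(1L, 2L), j = c(3L, 3L),
                              r_native = 0.45, chain_i = c("A", "B"),
                              chain_j = "C", intermolecular = TRUE,
                              sigma = 0.45, eps = c(0.8, 0.55))
  topo$exclusions <- matrix(c(1L, 2L), 1, 2)
  anchors <- matrix(c(-0.7, 0, 0, 0.7, 0, 0), 2, 3, byrow = TRUE)
  ## anchors held rigid; a weak isotropic restraint confines the particle
  ## (the wells have finite range) and is part of the reference integral
  restr <- restraint_spec(1:3, rbind(anchors, c(0, 0, 0)),
                          k = c(1e4, 1e4, 1))
  x0 <- rbind(anchors, c(-0.25, 0, 0))
  Tred <- 0.35
  tr <- run_langevin(topo, simulation_state(x0),
                     langevin_params(reduced_temperature = Tred,
                                     timestep = 0.005, friction = 1,
                                     n_steps = 4e6, save_interval = 50,
                                     seed = 3),
                     restraints = restr)
  xpart <- tr$frames[-(1:400), 3, 1]   # x of the free particle, equilibrated
  ratio_sim <- mean(xpart < 0) / mean(xpart > 0)

  ## independent oracle: numerical Boltzmann integral in cylindrical
  ## coordinates about the anchor axis (anchors treated as fixed)
  lj <- function(r, eps) eps * ((0.45 / r)^12 - 2 * (0.45 / r)^6)
  xs <- seq(-1.6, 1.6, length.out = 641)
  rs <- seq(1e-3, 1.2, length.out = 241)
  w <- outer(xs, rs, function(x, rho) {
    r1 <- sqrt((x + 0.7)^2 + rho^2)
    r2 <- sqrt((x - 0.7)^2 + rho^2)
    conf <- 0.5 * 1 * (x^2 + rho^2)
    exp(-(lj(r1, 0.8) + lj(r2, 0.55) + conf) / Tred) * rho
  })
  ratio_ref <- sum(w[xs < 0, ]) / sum(w[xs > 0, ])
  expect_lt(abs(ratio_sim / ratio_ref - 1), 0.05)
})

test_that("kinetic temperature of the toy shell stays within 2% of the set point", {
  st <- initialize_velocities(
    simulation_state(coords(ts_shell$expanded_reference)), 0.582, 5)
  tr <- run_langevin(ts_topo, st,
                     langevin_params(n_steps = 30000, save_interval = 500,
                                     seed = 5))
  tk <- mean(kinetic_temperature(tr)[-(1:20)])
  expect_lt(abs(tk - 0.582) / 0.582, 0.02)
})

test_that("dynamics blow-ups are reported with the step number", {
  ## two overlapping non-excluded beads inside the r^-12 core
  topo <- bare_topology(2,
    atoms = data.frame(chain_id = c("A", "B"), residue_index = 1L,
                       residue_name = "GLY", atom_name = "CA", element = "C"))
  x0 <- matrix(c(0, 0, 0, 0.02, 0, 0), 2, 3, byrow = TRUE)
  expect_error(
    run_langevin(topo, simulation_state(x0),
                 langevin_params(timestep = 0.02, n_steps = 1000, seed = 1)),
    "blow-up.*step")
})

test_that("disordered-tail generation restrains the body and decorrelates tails", {
  starts <- suppressWarnings(
    generate_disordered_tails(ts_shell$compact, ts_topo, n_samples = 4,
                              seed = 11, interior_only = TRUE))
  expect_length(starts, 4)
  ann <- ts_shell$annotations
  caps <- capsomer_chains(ts_shell)
  tail_idx <- unlist(lapply(caps, function(cid)
    atom_indices(ts_shell$compact, cid, c(1L, 8L))))
  body_idx <- setdiff(seq_len(n_atoms(ts_shell$compact)), tail_idx)
  x0 <- coords(ts_shell$compact)
  ## restrained-atom displacements obey the harmonic fluctuation bound:
  ## the typical atom within 3 sqrt(T/k); the maximum additionally carries
  ## the small static offset from intra-shell forces
  for (s in starts) {
    disp <- sqrt(rowSums((coords(s)[body_idx, ] - x0[body_idx, ])^2))
    expect_lt(median(disp), 3 * sqrt(1.0 / 1000))
    expect_lt(max(disp), 3 * sqrt(1.0 / 1000) + 0.12)
  }
  ## tails decorrelate between samples: inter-sample tail RMSD well above
  ## the short-stride thermal fluctuation scale
  short <- suppressWarnings(
    generate_disordered_tails(ts_shell$compact, ts_topo, n_samples = 2,
                              seed = 11, stride = 200,
                              equilibration_strides = 10L))
  rmsd_pair <- function(a, b) rmsd_coords(coords(a)[tail_idx, ],
                                          coords(b)[tail_idx, ])
  long_r <- mean(c(rmsd_pair(starts[[1]], starts[[2]]),
                   rmsd_pair(starts[[2]], starts[[3]]),
                   rmsd_pair(starts[[3]], starts[[4]])))
  short_r <- rmsd_pair(short[[1]], short[[2]])
  expect_gt(long_r, 2 * short_r)

  ## the stride diagnostic is recorded in the manifest and the warning
  ## fires exactly when the stride undercuts the measured autocorrelation
  ## time
  m <- attr(starts, "manifest")
  expect_true(is.numeric(m$tail_rg_act_steps))
  expect_equal(!is.null(m$stride_warning), m$stride < m$tail_rg_act_steps)
})
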