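# Shared fixtures and independent oracles, built once per test run.

fx <- make_unit_fixtures()

## small toy shell (two chains per class) and its production topology,
## reused across test files
ts_shell <- make_toy_shell(toy_shell_spec(chains_per_class = 2L), seed = 1L)
ts_topo <- build_topology(ts_shell$expanded_reference, param_table = NULL,
                          dihedral_contact_ratio = 0)

capsomer_chains <- function(shell) {
  shell$annotations$chain_id[!is.na(shell$annotations$position_label)]
}

## ---------------------------------------------------------------------------
## independent brute-force Shadow oracle: tests every candidate pair against
## every possible occluder using its own geometry and its own bonded-graph
## bookkeeping (graph powers for 1-2/1-3/1-4 exclusions)

shadow_oracle <- function(structure, params, bonds = NULL) {
  xyz <- coords(structure)
  n <- nrow(xyz)
  at <- structure$atoms
  if (is.null(bonds)) bonds <- attr(structure, "bonds")
  A <- matrix(0, n, n)
  if (!is.null(bonds) && nrow(bonds) > 0) {
    for (m in seq_len(nrow(bonds))) {
      A[bonds[m, 1], bonds[m, 2]] <- 1
      A[bonds[m, 2], bonds[m, 1]] <- 1
    }
  }
  A2 <- A %*% A; A3 <- A2 %*% A
  excluded <- (A + A2 + A3) > 0
  diag(excluded) <- TRUE
  seg_dist <- function(p, a, b) {
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab^2)
    t <- min(1, max(0, t))
    sqrt(sum((p - (a + t * ab))^2))
  }
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      rij <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (rij > params$contact_cutoff) next
      if (at$chain_id[i] == at$chain_id[j] &&
          abs(at$residue_index[i] - at$residue_index[j]) <
            params$min_residue_separation) next
      if (excluded[i, j]) next
      occluded <- FALSE
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        if (sqrt(sum((xyz[k, ] - xyz[i, ])^2)) >= rij) next
        radk <- if (A[k, i] > 0 || A[k, j] > 0) params$bonded_radius
                else params$shadow_radius
        if (radk <= 0) next
        if (seg_dist(xyz[k, ], xyz[i, ], xyz[j, ]) < radk) {
          occluded <- TRUE
          break
        }
      }
      if (!occluded) out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(integer(), 0, 2) else out
}

## random mixed-chain cloud for contact-map oracles: one multi-residue chain
## (exercising the sequence-separation filter and bonded shrinkage) plus
## single-bead chains
random_cloud <- function(seed, n = 30, box = 1.5) {
  set.seed(seed)
  xyz <- matrix(runif(3 * n, 0, box), n, 3)
  n_chain_a <- min(10L, n %/% 2L)
  at <- data.frame(
    element = "C", atom_name = "CA",
    residue_index = c(seq_len(n_chain_a), rep(1L, n - n_chain_a)),
    residue_name = "GLY",
    chain_id = c(rep("A", n_chain_a),
                 c(LETTERS[-1], letters, 0:9)[seq_len(n - n_chain_a)]),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE)
  bonds <- cbind(seq_len(n_chain_a - 1L), 2:n_chain_a)
  mol_structure(at, source = sprintf("cloud seed %d", seed), bonds = bonds)
}

## finite-difference force check
max_force_error <- function(topo, x, h = 1e-6) {
  f <- forces(topo, x)
  num <- matrix(0, nrow(x), 3)
  for (i in seq_len(nrow(x))) {
    for (c in 1:3) {
      xp <- x; xp[i, c] <- xp[i, c] + h
      xm <- x; xm[i, c] <- xm[i, c] - h
      num[i, c] <- -(potential_energy(topo, xp)$total -
                       potential_energy(topo, xm)$total) / (2 * h)
    }
  }
  max(abs(f - num))
}

## minimal single-particle topology (restraint-driven wells etc.)
bare_topology <- function(n, atoms = NULL) {
  structure(list(
    n_atoms = as.integer(n),
    bonds = data.frame(i = integer(), j = integer(), r0 = numeric(),
                       k = numeric()),
    angles = data.frame(i = integer(), j = integer(), k = integer(),
                        theta0 = numeric(), ka = numeric()),
    dihedrals = data.frame(i = integer(), j = integer(), k = integer(),
                           l = integer(), class = character(),
                           native_angle = numeric(), kd = numeric()),
    contacts = data.frame(i = integer(), j = integer(), r_native = numeric(),
                          chain_i = character(), chain_j = character(),
                          intermolecular = logical(), sigma = numeric(),
                          eps = numeric()),
    exclusions = matrix(integer(), 0, 2),
    excluded_volume = list(radius = 0.25, strength = 1, cutoff = 0.6),
    energy_scale = 1, contact_form = "lj", gaussian_width = 0.05,
    atoms = if (is.null(atoms)) {
      data.frame(chain_id = "A", residue_index = seq_len(n),
                 residue_name = "GLY", atom_name = "CA", element = "C")
    } else atoms,
    reference = "", notes = character()), class = "ff_topology")
}

mk_trace <- function(q, times = seq_along(q) - 1, chain = "A", label = "A") {
  structure(list(chain_id = chain, position_label = label,
                 times = times, q = q), class = "q_trace")
}
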