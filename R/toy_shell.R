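## Synthetic miniature shells.
##
## The generator builds a closed spherical shell of coarse (one-bead-per-
## residue) chains with a trans-shell pore per chain, in two reference
## conformations: a compact state with the terminal tails on the interior
## surface, and an expanded state (the "mature" reference) in which every
## tail has threaded its pore and lies on the exterior surface, draped
## toward the neighbouring chain so that its distal beads form
## intermolecular contacts.  Pore half-widths are set per position class, so
## steric hindrance to translocation is a controlled, ordered property --
## the desk-scale analogue of position-dependent cavity sterics in a real
## capsid.  Beads are emitted as GLY CA pseudo-atoms so every downstream
## module runs unmodified.

.chain_id_pool <- c(LETTERS, letters, as.character(0:9))

#' Toy-shell generative parameters
#'
#' @param n_position_classes number of position classes (default 7, labelled
#'   A-G).
#' @param chains_per_class chains per class (default 3).
#' @param residues_per_chain residues (beads) per chain, tail included
#'   (default 40).
#' @param tail_length terminal-tail length in residues (default 8).
#' @param compact_radius,expanded_radius shell radii in nm; the default pair
#'   keeps the ~25:28.5 ratio of a maturing capsid.
#' @param cavity_half_widths named per-class pore half-widths, nm.  The
#'   default follows a strict steric ordering E > D > C ~ F ~ G ~ B > A.
#' @param bond_length bead spacing, nm.
#' @param tail_height height of the exterior native tail path above the
#'   shell surface, nm.
#' @param kinked_cavity if `TRUE`, a five-bead obstacle "doorway" is placed
#'   across each exterior tail path, mid-way through the intermolecular
#'   contact zone, creating a long-lived partially-translocated
#'   intermediate.
#' @param seed integer seed (compact-tail placement jitter).
#' @export
toy_shell_spec <- function(n_position_classes = 7L, chains_per_class = 3L,
                           residues_per_chain = NULL, tail_length = 8L,
                           compact_radius = NULL, expanded_radius = NULL,
                           cavity_half_widths = c(A = 0.34, B = 0.385,
                                                  C = 0.40, D = 0.44,
                                                  E = 0.48, F = 0.395,
                                                  G = 0.39),
                           bond_length = 0.33, tail_height = 0.30,
                           kinked_cavity = FALSE, seed = 1L) {
  labels <- LETTERS[seq_len(n_position_classes)]
  if (length(cavity_half_widths) != n_position_classes) {
    stop("cavity_half_widths must have one entry per position class")
  }
  if (is.null(names(cavity_half_widths))) names(cavity_half_widths) <- labels
  if (any(cavity_half_widths <= 0)) stop("cavity widths must be positive")
  if (any(cavity_half_widths < 0.29)) {
    stop("infeasible spec: cavity half-width leaves no aperture beyond the ",
         "bead steric radius; no tail can pass")
  }
  n_chain <- as.integer(n_position_classes) * as.integer(chains_per_class)
  ## auto-sizing: the sphere must give every chain room for its pore, its
  ## exterior tail spiral and a clearance band so no two tails share body
  ## beads; the bead budget must keep the lattice sealed (spacing <= 0.4 nm)
  if (is.null(expanded_radius)) {
    s_req <- 2 * (max(cavity_half_widths) + 0.16) + 1.30
    expanded_radius <- 1.08 * s_req * sqrt(n_chain / 14.51)
  }
  if (is.null(compact_radius)) compact_radius <- expanded_radius * 25 / 28.5
  if (is.null(residues_per_chain)) {
    patch_per <- ceiling(4 * pi * expanded_radius^2 * 1.1547 / 0.16 / n_chain)
    residues_per_chain <- as.integer(tail_length + 6L + patch_per)
  }
  if (expanded_radius <= compact_radius) {
    stop("expanded_radius must exceed compact_radius")
  }
  if (tail_length >= residues_per_chain) {
    stop("tail_length must be smaller than residues_per_chain")
  }
  if (tail_length < 3) stop("infeasible spec: tail_length must be >= 3")
  ## the tail spiral must fit around its pore: path length bounded by the
  ## pore circumference minus a clearance gap
  if ((tail_length - 1) * bond_length / (min(cavity_half_widths) + 0.10) >
        2 * pi - 0.6) {
    stop("infeasible spec: tail longer than its trans-shell cavity path")
  }
  structure(list(n_position_classes = as.integer(n_position_classes),
                 labels = labels,
                 chains_per_class = as.integer(chains_per_class),
                 residues_per_chain = as.integer(residues_per_chain),
                 tail_length = as.integer(tail_length),
                 compact_radius = compact_radius,
                 expanded_radius = expanded_radius,
                 cavity_half_widths = cavity_half_widths[labels],
                 bond_length = bond_length,
                 tail_height = tail_height,
                 kinked_cavity = isTRUE(kinked_cavity),
                 seed = as.integer(seed)),
            class = "toy_shell_spec")
}

## quasi-uniform points on the unit sphere (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n)
  ga <- pi * (3 - sqrt(5))
  z <- 1 - (2 * i - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- ga * i
  cbind(r * cos(th), r * sin(th), z)
}

normalize <- function(v) v / sqrt(sum(v^2))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## tangent frame at unit vector u
tangent_frame <- function(u) {
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- normalize(cross3(u, ref))
  t2 <- cross3(u, t1)
  list(t1 = t1, t2 = t2)
}

## rotate tangent vector e about axis u by angle a
rotate_about <- function(e, u, a) {
  e * cos(a) + cross3(u, e) * sin(a) + u * sum(u * e) * (1 - cos(a))
}

## native exterior tail path of one chain: residue tail_length just outside
## the pore exit, the rest wrapping the pore at lateral radius 0.55 nm
tail_native_path <- function(u, e, spec, R, w) {
  fr <- tangent_frame(u)
  az0 <- atan2(sum(e * fr$t2), sum(e * fr$t1))
  tl <- spec$tail_length
  s_t <- w + 0.10          # tight spiral just outside the pore rim
  zig <- 0.06
  dpsi <- spec$bond_length / s_t
  h <- spec$tail_height
  t(vapply(seq_len(tl), function(r) {
    psi <- az0 + (tl - r) * dpsi
    lat <- s_t + ifelse(r %% 2 == 0, zig, -zig)
    d <- cos(psi) * fr$t1 + sin(psi) * fr$t2
    alpha <- lat / R
    (R + h) * (cos(alpha) * u + sin(alpha) * d)
  }, numeric(3)))
}

#' Generate a toy-shell pair
#'
#' Deterministic given the seed.  Returns compact and expanded reference
#' conformations as [mol_structure()]s sharing one chain topology (explicit
#' bonds attached), per-chain annotations and a cavity map.
#'
#' @param spec a [toy_shell_spec()].
#' @param seed optional seed override.
#' @return object of class `toy_shell_pair`: list with elements `compact`,
#'   `expanded_reference`, `annotations`, `cavity_map` and `spec`.
#' @export
make_toy_shell <- function(spec = toy_shell_spec(), seed = NULL) {
  stopifnot(inherits(spec, "toy_shell_spec"))
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  n_chain <- spec$n_position_classes * spec$chains_per_class
  if (n_chain > length(.chain_id_pool)) {
    stop("too many chains for single-character chain ids (max ",
         length(.chain_id_pool), ")")
  }
  Re_ <- spec$expanded_radius; Rc_ <- spec$compact_radius
  bl <- spec$bond_length; h <- spec$tail_height
  n_rim <- 6L
  n_patch <- spec$residues_per_chain - spec$tail_length - n_rim
  if (n_patch < 6) {
    stop("infeasible spec: residues_per_chain leaves fewer than 6 body ",
         "beads per chain beyond the tail and pore rim")
  }
  gap <- 0.28                        # punched annulus width outside the rim
  sites <- fibonacci_sphere(n_chain) # unit vectors
  class_idx <- ((seq_len(n_chain) - 1L) %% spec$n_position_classes) + 1L
  labels <- spec$labels[class_idx]
  widths <- spec$cavity_half_widths[labels]
  chain_ids <- .chain_id_pool[seq_len(n_chain)]

  ## nearest-neighbour site and (rotated) exterior path direction per chain
  site_d <- as.matrix(stats::dist(sites))
  diag(site_d) <- Inf
  nn <- apply(site_d, 1, which.min)
  dirs <- t(vapply(seq_len(n_chain), function(c0) {
    u <- sites[c0, ]
    e <- normalize(sites[nn[c0], ] - sum(sites[nn[c0], ] * u) * u)
    rotate_about(e, u, 20 * pi / 180)
  }, numeric(3)))

  ## ------------------------------------------------------------------
  ## body lattice: a quasi-uniform Fibonacci lattice on the expanded sphere,
  ## opened at every pore by a smooth geodesic push-out map
  ## s -> sqrt(s^2 + a^2) away from each pore centre (a = pore half-width +
  ## annulus).  The map is continuous, so the lattice keeps its neighbour
  ## structure -- no ragged holes -- while every pore gets a clean circular
  ## edge at geodesic radius a.
  target_patch <- n_chain * n_patch
  lattice <- fibonacci_sphere(target_patch) * Re_
  annulus <- 0.26
  for (c0 in seq_len(n_chain)) {
    u <- sites[c0, ]
    a <- widths[c0] + annulus
    for (b in seq_len(nrow(lattice))) {
      v <- normalize(lattice[b, ])
      ca <- sum(v * u)
      alpha <- acos(min(1, max(-1, ca)))
      tang <- v - ca * u
      tn <- sqrt(sum(tang^2))
      tang <- if (tn < 1e-9) tangent_frame(u)$t1 else tang / tn
      s_new <- sqrt((Re_ * alpha)^2 + a^2)
      alpha2 <- min(pi, s_new / Re_)
      lattice[b, ] <- Re_ * (cos(alpha2) * u + sin(alpha2) * tang)
    }
  }
  survivors <- lattice

  ## balanced assignment of lattice beads to chains.  Beads lying under a
  ## chain's native tail spiral (within the contact cutoff of any of its
  ## tail beads) are pre-assigned to that chain so that every tail-body
  ## contact is intramolecular; the remainder go to the nearest site with
  ## free capacity.
  cap <- rep(n_patch, n_chain)
  D <- matrix(0, nrow(survivors), n_chain)
  for (c0 in seq_len(n_chain)) {
    ctr <- Re_ * sites[c0, ]
    D[, c0] <- sqrt((survivors[, 1] - ctr[1])^2 + (survivors[, 2] - ctr[2])^2 +
                      (survivors[, 3] - ctr[3])^2)
  }
  owner <- integer(nrow(survivors))
  tail_d <- matrix(Inf, nrow(survivors), n_chain)
  for (c0 in seq_len(n_chain)) {
    tn <- tail_native_path(sites[c0, ], dirs[c0, ], spec, Re_, widths[c0])
    for (tb in seq_len(nrow(tn))) {
      d <- sqrt((survivors[, 1] - tn[tb, 1])^2 +
                  (survivors[, 2] - tn[tb, 2])^2 +
                  (survivors[, 3] - tn[tb, 3])^2)
      tail_d[, c0] <- pmin(tail_d[, c0], d)
    }
  }
  for (b in seq_len(nrow(survivors))) {
    c0 <- which.min(tail_d[b, ])
    if (tail_d[b, c0] < 0.62) {
      owner[b] <- c0; cap[c0] <- cap[c0] - 1L
    }
  }
  if (any(cap < 0)) {
    stop("infeasible spec: overlapping tail paths claim the same body beads")
  }
  for (b in order(apply(D, 1, min))) {
    if (owner[b] > 0) next
    for (c0 in order(D[b, ])) {
      if (cap[c0] > 0) { owner[b] <- c0; cap[c0] <- cap[c0] - 1L; break }
    }
  }

  ## ------------------------------------------------------------------
  ## per-chain bead construction (expanded reference).
  ##
  ## The native tail path is an exterior spiral around the chain's own pore
  ## at lateral radius s_t and height h above the surface.  Intermolecular
  ## contacts come from a per-chain "cage" chain: pad beads bridged between
  ## two pillar columns, hovering at h_pad above the surface directly over
  ## the spiral.  Because 1.5 x (pad-tail native distance) is smaller than
  ## the pad's height above the shell, no pad contact can register from the
  ## shell interior: Q can only grow by genuine trans-shell displacement.
  set.seed(spec$seed)
  atom_rows <- list(); bond_rows <- list(); expanded <- list(); compact <- list()
  rho <- Rc_ / Re_
  cavity_map <- list()
  h_pad <- h + 0.55   # pad height; pad-tail gap 0.55 => formed radius 0.825
  zig <- 0.06         # lateral zigzag amplitude of tail paths
  tl <- spec$tail_length
  n_pads <- tl - 3L     # pads cover the distal residues 1 .. tl-3
  ## additional pads at half-integer positions refine the Q resolution:
  ## each contacts both flanking tail beads
  n_half <- n_pads - 1L
  n_cage <- n_pads + n_half + (if (spec$kinked_cavity) 3L else 0L)
  ## surface point helper: lateral geodesic distance s, azimuth psi in the
  ## local frame, height hh above the sphere
  spt <- function(u, fr, s, psi, hh) {
    d <- cos(psi) * fr$t1 + sin(psi) * fr$t2
    alpha <- s / Re_
    (Re_ + hh) * (cos(alpha) * u + sin(alpha) * d)
  }
  cage_exp <- list(); cage_cmp <- list(); cage_atoms <- list()
  cage_bonds <- list(); cage_ids <- character(0)
  n_body_atoms <- n_chain * spec$residues_per_chain
  for (c0 in seq_len(n_chain)) {
    u <- sites[c0, ]; fr <- tangent_frame(u)
    e <- dirs[c0, ]
    w <- widths[c0]
    az0 <- atan2(sum(e * fr$t2), sum(e * fr$t1))
    ## rim ring (residues tail+1 .. tail+6), first bead facing the spiral
    rim <- t(vapply(seq_len(n_rim), function(k) {
      th <- az0 + 2 * pi * (k - 1) / n_rim
      Re_ * u + w * (cos(th) * fr$t1 + sin(th) * fr$t2)
    }, numeric(3)))
    ## lattice patch beads of this chain, ordered rim-outward in a
    ## boustrophedon spiral so consecutive beads stay close
    patch <- survivors[owner == c0, , drop = FALSE]
    if (nrow(patch) != n_patch) {
      stop("internal error: patch bead budget mismatch for chain ", c0)
    }
    ctr <- Re_ * u
    latd <- sqrt((patch[, 1] - ctr[1])^2 + (patch[, 2] - ctr[2])^2 +
                   (patch[, 3] - ctr[3])^2)
    az <- vapply(seq_len(nrow(patch)), function(k) {
      v <- patch[k, ] - ctr
      atan2(sum(v * fr$t2), sum(v * fr$t1))
    }, numeric(1))
    band <- floor((latd - w) / (1.2 * bl))
    ord <- order(band, ifelse(band %% 2 == 0, az, -az))
    patch <- patch[ord, , drop = FALSE]
    body_exp <- rbind(rim, patch)

    ## expanded native tail: residue tail_length just outside the pore exit,
    ## residues tail_length-1 .. 1 wrapping the pore on the exterior surface
    tail_exp <- tail_native_path(u, e, spec, Re_, w)

    ## compact state: body scaled radially; tail hugs the interior wall,
    ## heading away from its native direction, with seeded jitter
    body_cmp <- body_exp * rho
    r_in <- Rc_ - 0.35
    tail_cmp <- t(vapply(seq_len(tl), function(r) {
      steps <- tl - r + 1
      phi <- steps * bl / r_in
      radial <- cos(phi) * u - sin(phi) * e
      side <- cross3(radial, normalize(-cos(phi) * e - sin(phi) * u))
      p <- r_in * radial + ifelse(r %% 2 == 0, zig, -zig) * side
      p + rnorm(3, 0, 0.02)
    }, numeric(3)))

    expanded[[c0]] <- rbind(tail_exp, body_exp)
    compact[[c0]] <- rbind(tail_cmp, body_cmp)
    nres <- spec$residues_per_chain
    atom_rows[[c0]] <- data.frame(
      element = "C", atom_name = "CA",
      residue_index = seq_len(nres), residue_name = "GLY",
      chain_id = chain_ids[c0], x = 0, y = 0, z = 0,
      stringsAsFactors = FALSE)
    off <- (c0 - 1L) * nres
    ## chain backbone plus rim-ring chords and diameters: the chords make
    ## the pore a stiff hexagon, so the cavity half-width is a controlled
    ## parameter rather than a soft degree of freedom
    rim_res <- tl + seq_len(n_rim)
    chord <- cbind(off + rim_res, off + rim_res[(seq_len(n_rim)) %% n_rim + 1L])
    chord2 <- cbind(off + rim_res, off + rim_res[(seq_len(n_rim) + 1L) %% n_rim + 1L])
    diam <- cbind(off + rim_res[1:3], off + rim_res[4:6])
    bond_rows[[c0]] <- rbind(cbind(off + seq_len(nres - 1L), off + 2:nres),
                             chord, chord2, diam)
    cavity_map[[chain_ids[c0]]] <- list(site = Re_ * u, axis = u,
                                        half_width = unname(w),
                                        class = labels[c0],
                                        exit_direction = e)

    ## cage chain: pillar column (heights 0.12, 0.40 at lateral 0.85 nm,
    ## azimuth before the spiral start), pads over residues tl-1 .. 1,
    ## second pillar column past the spiral end
    ## cage chain: pad beads hovering directly above the native positions of
    ## tail residues tl-1 .. 1.  Pads have no structural support of their own
    ## (they are scaffolding, harmonically restrained during simulations);
    ## their 0.55 nm vertical native distance keeps the formed radius
    ## (0.825 nm) smaller than their height, so pad contacts cannot register
    ## from the shell interior.
    s_t <- w + 0.10
    dpsi <- bl / s_t
    cage <- NULL
    for (rr in rev(seq(1, n_pads, by = 0.5))) {   # pads over residues
      psi <- az0 + (tl - rr) * dpsi               # n_pads .. 1 in half steps
      cage <- rbind(cage, spt(u, fr, s_t, psi, h_pad))
    }
    if (spec$kinked_cavity) {
      ## low lintel directly over residue 3 of the native path: a strong
      ## steric squeeze early in the zipper, stalling it at Q ~ 0.4 --
      ## well separated from the high-Q states of natural threading traps.
      ## Its native distances to nearby tail beads are small, so 1.5x those
      ## distances stays below the lintel height: no interior registration.
      psi_k <- az0 + (tl - 3) * dpsi
      cage <- rbind(cage,
                    spt(u, fr, s_t - 0.12, psi_k, 0.45),
                    spt(u, fr, s_t, psi_k, 0.45),
                    spt(u, fr, s_t + 0.12, psi_k, 0.45))
    }
    cid <- .chain_id_pool[n_chain + c0]
    cage_ids <- c(cage_ids, cid)
    cage_exp[[cid]] <- cage
    cage_cmp[[cid]] <- cage * rho
    cage_atoms[[cid]] <- data.frame(
      element = "C", atom_name = "CA", residue_index = seq_len(n_cage),
      residue_name = "GLY", chain_id = cid, x = 0, y = 0, z = 0,
      stringsAsFactors = FALSE)
    coff <- n_body_atoms + (c0 - 1L) * n_cage
    cage_bonds[[cid]] <- cbind(coff + seq_len(n_cage - 1L), coff + 2:n_cage)
  }
  obst_atoms <- cage_atoms; obst_bonds <- cage_bonds
  obst_exp <- cage_exp; obst_cmp <- cage_cmp; obst_ids <- cage_ids

  atoms <- do.call(rbind, c(atom_rows, obst_atoms))
  bonds <- do.call(rbind, c(bond_rows, obst_bonds))
  xyz_exp <- do.call(rbind, c(expanded, obst_exp))
  xyz_cmp <- do.call(rbind, c(compact, obst_cmp))

  ## resolve residual steric overlaps in the compact tails (deterministic
  ## push-apart; initial configurations must not start inside the r^-12 core)
  xyz_cmp <- push_apart(xyz_cmp, min_dist = 0.22, max_iter = 60, bonds = bonds)
  xyz_exp <- push_apart(xyz_exp, min_dist = 0.12, max_iter = 60, bonds = bonds)

  ann <- data.frame(chain_id = c(chain_ids, obst_ids),
                    position_label = c(labels, rep(NA_character_,
                                                   length(obst_ids))),
                    tail_start = c(rep(1L, n_chain),
                                   rep(NA_integer_, length(obst_ids))),
                    tail_end = c(rep(spec$tail_length, n_chain),
                                 rep(NA_integer_, length(obst_ids))),
                    stringsAsFactors = FALSE)

  mk <- function(xyz, what) {
    at <- atoms; at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    mol_structure(at, chains = ann,
                  source = sprintf("toy shell (%s, seed %d)", what, spec$seed),
                  bonds = bonds)
  }
  exp_s <- mk(xyz_exp, "expanded reference")
  cmp_s <- mk(xyz_cmp, "compact")

  if (spec$kinked_cavity) {
    ## lintel beads at mid-range native distances from tail beads must not
    ## become contacts (they remain purely steric); only their short-range
    ## pairs (< 0.44 nm, whose formed radius stays under the lintel height)
    ## are allowed as contacts
    lintel_res <- (n_cage - 2L):n_cage
    bl <- NULL
    for (c0 in seq_len(n_chain)) {
      ti <- atom_indices(exp_s, chain_ids[c0], c(1L, spec$tail_length))
      li <- atom_indices(exp_s, obst_ids[c0], range(lintel_res))
      for (a in ti) for (b in li) {
        dn <- sqrt(sum((xyz_exp[a, ] - xyz_exp[b, ])^2))
        if (dn >= 0.44 && dn < 0.70) bl <- rbind(bl, c(a, b))
      }
    }
    if (!is.null(bl)) {
      exp_s <- blacklist_contacts(exp_s, bl)
      cmp_s <- blacklist_contacts(cmp_s, bl)
    }
  }

  ## generator contract checks
  rg_ratio <- radius_of_gyration(exp_s) / radius_of_gyration(cmp_s)
  if (abs(rg_ratio / (Re_ / Rc_) - 1) > 0.10) {
    stop("internal error: Rg ratio of the generated pair deviates from the ",
         "radius ratio by more than 10%")
  }
  ## purity of the intermolecular tail environment: any other-chain atom
  ## within contact range of a native tail bead must be a cage bead hovering
  ## at least 0.7 nm above the shell surface (so no tail contact can form
  ## from the shell interior)
  at_all <- exp_s$atoms
  heights <- sqrt(xyz_exp[, 1]^2 + xyz_exp[, 2]^2 + xyz_exp[, 3]^2) - Re_
  for (c0 in seq_len(n_chain)) {
    ti <- atom_indices(exp_s, chain_ids[c0], c(1L, spec$tail_length))
    own <- atom_indices(exp_s, chain_ids[c0])
    for (a in ti) {
      d <- sqrt(rowSums((xyz_exp - matrix(xyz_exp[a, ], nrow(xyz_exp), 3,
                                          byrow = TRUE))^2))
      near <- setdiff(which(d < 0.6), own)
      bl <- attr(exp_s, "contact_blacklist")
      if (!is.null(bl)) {
        blk <- c(bl[bl[, 1] == a, 2], bl[bl[, 2] == a, 1])
        near <- setdiff(near, blk)
      }
      ok <- at_all$chain_id[near] %in% obst_ids &
        1.5 * d[near] < heights[near] + 0.28
      bad <- near[!ok]
      if (length(bad) > 0) {
        stop("internal error: non-cage atoms of another chain lie within ",
             "contact range of the native tail of chain ", chain_ids[c0])
      }
    }
  }
  tail_reach_ok <- vapply(seq_len(n_chain), function(c0) {
    ti <- atom_indices(exp_s, chain_ids[c0], c(1L, spec$tail_length))
    others <- setdiff(seq_len(nrow(xyz_exp)),
                      atom_indices(exp_s, chain_ids[c0]))
    dmin <- min(vapply(ti, function(a) {
      min(sqrt(rowSums((xyz_exp[others, , drop = FALSE] -
                          matrix(xyz_exp[a, ], length(others), 3,
                                 byrow = TRUE))^2)))
    }, numeric(1)))
    dmin < 0.6
  }, logical(1))
  if (!all(tail_reach_ok)) {
    stop("infeasible spec: some expanded tails reach no other chain ",
         "(no intermolecular contact possible)")
  }

  structure(list(compact = cmp_s, expanded_reference = exp_s,
                 annotations = ann, cavity_map = cavity_map, spec = spec),
            class = "toy_shell_pair")
}

#' @export
print.toy_shell_pair <- function(x, ...) {
  cat("toy_shell_pair:", nrow(x$annotations), "chains (",
      sum(!is.na(x$annotations$position_label)), "capsomer ),",
      n_atoms(x$expanded_reference), "beads; Rg",
      sprintf("%.2f -> %.2f nm\n", radius_of_gyration(x$compact),
              radius_of_gyration(x$expanded_reference)))
  invisible(x)
}

## deterministic overlap resolution: repeatedly separate all pairs closer
## than min_dist along their joining vector
push_apart <- function(xyz, min_dist = 0.2, max_iter = 50, bonds = NULL) {
  for (it in seq_len(max_iter)) {
    d <- as.matrix(stats::dist(xyz))
    diag(d) <- Inf
    if (!is.null(bonds)) {
      d[cbind(bonds[, 1], bonds[, 2])] <- Inf
      d[cbind(bonds[, 2], bonds[, 1])] <- Inf
    }
    bad <- which(d < min_dist, arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    if (nrow(bad) == 0) return(xyz)
    for (q in seq_len(nrow(bad))) {
      i <- bad[q, 1]; j <- bad[q, 2]
      v <- xyz[j, ] - xyz[i, ]
      dn <- sqrt(sum(v^2))
      v <- if (dn < 1e-9) c(1, 0, 0) else v / dn
      shift <- (min_dist - dn) / 2 + 0.005
      xyz[i, ] <- xyz[i, ] - shift * v
      xyz[j, ] <- xyz[j, ] + shift * v
    }
  }
  xyz
}

#' Export a toy shell to disk
#'
#' Writes `compact.pdb`, `expanded.pdb` and an `annotations.json` sidecar
#' (chain annotations, cavity map, generative parameters) to a directory.
#'
#' @param pair a `toy_shell_pair`.
#' @param dir output directory (created if needed).
#' @export
export_toy_shell <- function(pair, dir) {
  stopifnot(inherits(pair, "toy_shell_pair"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_structure(pair$compact, file.path(dir, "compact.pdb"))
  write_structure(pair$expanded_reference, file.path(dir, "expanded.pdb"))
  jsonlite::write_json(
    list(annotations = pair$annotations,
         cavity_map = lapply(pair$cavity_map, function(cv)
           list(class = cv$class, half_width = cv$half_width,
                site = cv$site, axis = cv$axis)),
         spec = unclass(pair$spec)),
    file.path(dir, "annotations.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# ---------------------------------------------------------------------------
# small deterministic fixtures

## internal-coordinate atom placement (NeRF): returns the position of the
## atom bonded to c, given bond length, angle at c (with b) and dihedral
## a-b-c-new
place_atom <- function(a, b, c, bond, angle_deg, dihedral_deg) {
  ang <- angle_deg * pi / 180; dih <- dihedral_deg * pi / 180
  bc <- normalize(c - b)
  n <- normalize(cross3(b - a, bc))
  m <- cross3(n, bc)
  c + bond * (-cos(ang) * bc + sin(ang) * (cos(dih) * m + sin(dih) * n))
}

#' Deterministic unit-test fixtures
#'
#' * `harmonic_dimer`: two bonded pseudo-atoms 0.38 nm apart.
#' * `dipeptide`: an all-atom (heavy) ALA-ALA peptide in an extended
#'   conformation with ideal bonded geometry -- its dihedral classification
#'   (omega rigid; phi, psi, chi flexible) can be enumerated by hand.
#' * `random_cloud`: 30 single-bead chains placed uniformly in a 1.5 nm box
#'   with a fixed seed (for contact-map oracles).
#'
#' @param cloud_seed seed of the random cloud (default 42).
#' @param cloud_n number of cloud atoms (default 30).
#' @param cloud_box box edge, nm (default 1.5).
#' @return named list of [mol_structure()]s.
#' @export
make_unit_fixtures <- function(cloud_seed = 42L, cloud_n = 30L,
                               cloud_box = 1.5) {
  dimer <- mol_structure(
    data.frame(element = "C", atom_name = "CA", residue_index = 1:2,
               residue_name = "GLY", chain_id = "A",
               x = c(0, 0.38), y = 0, z = 0, stringsAsFactors = FALSE),
    source = "harmonic dimer fixture", bonds = cbind(1L, 2L))

  ## ALA-ALA, heavy atoms, idealised extended geometry
  N1 <- c(0, 0, 0); CA1 <- c(0.1449, 0, 0)
  ang <- 110.1 * pi / 180
  C1 <- CA1 + 0.1522 * c(-cos(ang), sin(ang), 0)
  O1 <- place_atom(N1, CA1, C1, 0.1229, 120.4, 0)
  CB1 <- place_atom(C1, N1, CA1, 0.1526, 109.7, -122)
  N2 <- place_atom(N1, CA1, C1, 0.1335, 116.6, 180)
  CA2 <- place_atom(CA1, C1, N2, 0.1449, 121.9, 180)
  C2 <- place_atom(C1, N2, CA2, 0.1522, 110.1, -120)
  CB2 <- place_atom(C1, N2, CA2, 0.1526, 109.7, 120)
  O2 <- place_atom(N2, CA2, C2, 0.1229, 120.4, 140)
  OXT <- place_atom(N2, CA2, C2, 0.1250, 117.0, -40)
  xyz <- rbind(N1, CA1, C1, O1, CB1, N2, CA2, C2, O2, CB2, OXT)
  dipep <- mol_structure(
    data.frame(element = c("N", "C", "C", "O", "C",
                           "N", "C", "C", "O", "C", "O"),
               atom_name = c("N", "CA", "C", "O", "CB",
                             "N", "CA", "C", "O", "CB", "OXT"),
               residue_index = c(rep(1L, 5), rep(2L, 6)),
               residue_name = "ALA", chain_id = "A",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE),
    source = "ALA-ALA dipeptide fixture")

  set.seed(cloud_seed)
  cl_xyz <- matrix(stats::runif(3 * cloud_n, 0, cloud_box), cloud_n, 3)
  cloud <- mol_structure(
    data.frame(element = "C", atom_name = "CA", residue_index = 1L,
               residue_name = "GLY",
               chain_id = .chain_id_pool[seq_len(cloud_n)],
               x = cl_xyz[, 1], y = cl_xyz[, 2], z = cl_xyz[, 3],
               stringsAsFactors = FALSE),
    source = sprintf("random cloud fixture (seed %d)", cloud_seed))

  list(harmonic_dimer = dimer, dipeptide = dipep, random_cloud = cloud)
}
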