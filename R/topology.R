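## Single-basin structure-based force-field construction.
##
## The stabilizing interactions (contacts, flexible dihedrals) are defined
## from one reference conformation -- the expanded/mature shell -- making it
## the potential-energy minimum.  Contacts come from the Shadow screening
## construction; their minima are scaled (default 0.95) so the free-energy
## minimum in Rg coincides with the mature structure rather than beyond it.

#' Shadow contact-map parameters
#'
#' @param contact_cutoff pair-distance cutoff, nm.
#' @param shadow_radius screening-sphere radius, nm.
#' @param min_residue_separation minimum sequence separation for intra-chain
#'   pairs (inter-chain pairs have no separation filter).
#' @param bonded_radius shrunken screening radius for atoms directly bonded
#'   to either endpoint, nm.
#' @export
shadow_params <- function(contact_cutoff = 0.6, shadow_radius = 0.1,
                          min_residue_separation = 3, bonded_radius = 0.05) {
  if (contact_cutoff <= 0) stop("contact_cutoff must be positive")
  if (shadow_radius < 0) stop("shadow_radius must be >= 0")
  if (contact_cutoff < shadow_radius) {
    stop("parameter error: contact_cutoff < shadow_radius")
  }
  if (min_residue_separation < 1) stop("min_residue_separation must be >= 1")
  structure(list(contact_cutoff = contact_cutoff,
                 shadow_radius = shadow_radius,
                 min_residue_separation = as.integer(min_residue_separation),
                 bonded_radius = bonded_radius),
            class = "shadow_params")
}

#' Shadow contact map of a reference conformation
#'
#' A pair within the cutoff is a contact unless a third atom occludes the
#' line of sight between them: a screening sphere (radius
#' `params$shadow_radius`, shrunk to `params$bonded_radius` for atoms bonded
#' to either endpoint), centred within the pair distance of the first atom,
#' intersecting the segment removes the pair.  Bonded exclusions (1-2, 1-3,
#' 1-4) and intra-chain pairs closer than the minimum sequence separation
#' are excluded.
#'
#' @param structure reference [mol_structure()] (the expanded conformation).
#' @param params a [shadow_params()].
#' @param bonds optional explicit bond matrix; defaults to the structure's
#'   bond attribute or distance-based inference.
#' @return a `contact_map`: data.frame with columns `i`, `j` (atom indices),
#'   `r_native` (nm), `chain_i`, `chain_j`, `intermolecular`; the Shadow
#'   parameters and provenance are kept as attributes.
#' @export
shadow_contact_map <- function(structure, params = shadow_params(),
                               bonds = NULL) {
  stopifnot(inherits(structure, "mol_structure"))
  if (n_atoms(structure) < 2) stop("structure must have >= 2 atoms")
  if (!inherits(params, "shadow_params")) {
    params <- do.call(shadow_params, params)
  }
  if (is.null(bonds)) bonds <- structure_bonds(structure)
  excl <- bonded_exclusions(bonds, n_atoms(structure))
  chain_code <- as.integer(factor(structure$atoms$chain_id,
                                  levels = unique(structure$atoms$chain_id)))
  res <- .cg_shadow_cpp(coords(structure),
                        as.integer(structure$atoms$residue_index),
                        chain_code,
                        params$contact_cutoff, params$shadow_radius,
                        params$bonded_radius, params$min_residue_separation,
                        as_pair_matrix(bonds), as_pair_matrix(excl))
  cm <- data.frame(i = res$i, j = res$j, r_native = res$r_native)
  bl <- attr(structure, "contact_blacklist")
  if (!is.null(bl) && nrow(cm) > 0) {
    bl <- as_pair_matrix(bl)
    key <- paste(pmin(cm$i, cm$j), pmax(cm$i, cm$j))
    cm <- cm[!(key %in% paste(bl[, 1], bl[, 2])), , drop = FALSE]
    rownames(cm) <- NULL
  }
  cm$chain_i <- structure$atoms$chain_id[cm$i]
  cm$chain_j <- structure$atoms$chain_id[cm$j]
  cm$intermolecular <- cm$chain_i != cm$chain_j
  attr(cm, "params") <- params
  attr(cm, "reference") <- structure$source
  class(cm) <- c("contact_map", "data.frame")
  cm
}

#' Scale contact minima
#'
#' Sets each contact's interaction minimum `sigma` to `scale_factor` times
#' its current minimum (initially the native distance).  Repeated application
#' composes multiplicatively; `r_native` is never modified.
#'
#' @param map a `contact_map`.
#' @param scale_factor dimensionless factor in (0, 1].
#' @export
scale_contact_minima <- function(map, scale_factor = 0.95) {
  if (!is.numeric(scale_factor) || scale_factor <= 0) {
    stop("parameter error: scale_factor must be positive")
  }
  if (is.null(map$sigma)) map$sigma <- map$r_native
  map$sigma <- scale_factor * map$sigma
  map
}

# ---------------------------------------------------------------------------
# covalent bond graph

## distance-based covalent bond inference for all-atom structures: heavy-atom
## pairs within the same or sequence-adjacent residues of one chain, under an
## element-aware length cutoff.
infer_bonds <- function(structure) {
  at <- structure$atoms
  xyz <- coords(structure)
  out_i <- integer(); out_j <- integer()
  for (cid in unique(at$chain_id)) {
    idx <- which(at$chain_id == cid)
    res <- at$residue_index[idx]
    for (a in seq_along(idx)) {
      cand <- idx[res >= res[a] & res <= res[a] + 1]
      cand <- cand[cand > idx[a]]
      if (length(cand) == 0) next
      d <- sqrt(rowSums((xyz[cand, , drop = FALSE] -
                           matrix(xyz[idx[a], ], length(cand), 3,
                                  byrow = TRUE))^2))
      lim <- ifelse(at$element[cand] == "S" | at$element[idx[a]] == "S",
                    0.21, 0.185)
      hit <- cand[d < lim]
      out_i <- c(out_i, rep(idx[a], length(hit)))
      out_j <- c(out_j, hit)
    }
  }
  cbind(out_i, out_j)
}

structure_bonds <- function(structure) {
  b <- attr(structure, "bonds")
  if (is.null(b)) b <- infer_bonds(structure)
  as_pair_matrix(b)
}

as_pair_matrix <- function(b) {
  if (is.null(b) || length(b) == 0) return(matrix(integer(), 0, 2))
  b <- matrix(as.integer(b), ncol = 2)
  sw <- b[, 1] > b[, 2]
  b[sw, ] <- b[sw, c(2, 1)]
  unique(b)
}

adjacency_list <- function(bonds, n) {
  adj <- vector("list", n)
  for (m in seq_len(nrow(bonds))) {
    i <- bonds[m, 1]; j <- bonds[m, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, sort)
}

## 1-2, 1-3 and 1-4 pairs of the bond graph
bonded_exclusions <- function(bonds, n) {
  adj <- adjacency_list(bonds, n)
  pairs <- list(bonds)
  ## 1-3
  p13_i <- integer(); p13_j <- integer()
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(nb, 2)
      p13_i <- c(p13_i, cmb[1, ]); p13_j <- c(p13_j, cmb[2, ])
    }
  }
  pairs[[2]] <- cbind(p13_i, p13_j)
  ## 1-4: neighbours across each bond
  p14_i <- integer(); p14_j <- integer()
  for (m in seq_len(nrow(bonds))) {
    j <- bonds[m, 1]; k <- bonds[m, 2]
    a <- setdiff(adj[[j]], k); d <- setdiff(adj[[k]], j)
    if (length(a) && length(d)) {
      g <- expand.grid(a, d)
      keep <- g[, 1] != g[, 2]
      p14_i <- c(p14_i, g[keep, 1]); p14_j <- c(p14_j, g[keep, 2])
    }
  }
  pairs[[3]] <- cbind(p14_i, p14_j)
  as_pair_matrix(do.call(rbind, pairs))
}

# ---------------------------------------------------------------------------
# dihedral classification

## sp2/planar heavy atoms by residue; the backbone carbonyl carbon, carbonyl
## oxygen(s) and amide nitrogen are planar in every residue.
.sp2_backbone <- c("C", "O", "OXT", "N")
.sp2_sidechain <- list(
  ALA = character(), ARG = c("NE", "CZ", "NH1", "NH2"),
  ASN = c("CG", "OD1", "ND2"), ASP = c("CG", "OD1", "OD2"),
  CYS = character(), GLN = c("CD", "OE1", "NE2"),
  GLU = c("CD", "OE1", "OE2"), GLY = character(),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = character(), LEU = character(), LYS = character(),
  MET = character(),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = character(), SER = character(), THR = character(),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  VAL = character())

is_sp2_atom <- function(residue_name, atom_name) {
  residue_name <- toupper(residue_name)
  unknown <- setdiff(unique(residue_name), names(.sp2_sidechain))
  if (length(unknown) > 0) {
    stop("unknown residue(s) for dihedral classification: ",
         paste(unknown, collapse = ", "))
  }
  atom_name %in% .sp2_backbone |
    mapply(function(r, a) a %in% .sp2_sidechain[[r]], residue_name, atom_name,
           USE.NAMES = FALSE)
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  m <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
         b1[1] * b2[2] - b1[2] * b2[1])
  n <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
         b2[1] * b3[2] - b2[2] * b3[1])
  cx <- c(m[2] * n[3] - m[3] * n[2], m[3] * n[1] - m[1] * n[3],
          m[1] * n[2] - m[2] * n[1])
  atan2(sum(cx * b2) / sqrt(sum(b2^2)), sum(m * n))
}

#' Classify proper dihedrals of a structure
#'
#' One representative proper dihedral is assigned per rotatable central bond
#' (the lowest-index flanking atoms are used).  A dihedral whose central bond
#' joins two planar/sp2-hybridised atoms (peptide omega, rings, side-chain
#' carboxyl/amide planes) is `rigid` -- a periodicity-2 cosine with minima at
#' 0 and 180 degrees; every other dihedral (phi, psi, chi) is `flexible`,
#' with its minimum at the reference conformation's value.
#'
#' @param structure a [mol_structure()] with standard residue/atom naming.
#' @param bonds optional explicit bond matrix.
#' @return data.frame with columns `i`, `j`, `k`, `l`, `class`
#'   (`"rigid"`/`"flexible"`) and `native_angle` (radians).
#' @export
classify_dihedrals <- function(structure, bonds = NULL) {
  if (is.null(bonds)) bonds <- structure_bonds(structure)
  n <- n_atoms(structure)
  adj <- adjacency_list(bonds, n)
  at <- structure$atoms
  xyz <- coords(structure)
  sp2 <- is_sp2_atom(at$residue_name, at$atom_name)
  rows <- list(); nr <- 0
  for (m in seq_len(nrow(bonds))) {
    j <- bonds[m, 1]; k <- bonds[m, 2]
    a <- setdiff(adj[[j]], k); d <- setdiff(adj[[k]], j)
    if (length(a) == 0 || length(d) == 0) next
    i <- min(a); l <- min(d)
    if (i == l) next
    cls <- if (sp2[j] && sp2[k]) "rigid" else "flexible"
    phi <- dihedral_angle(xyz[i, ], xyz[j, ], xyz[k, ], xyz[l, ])
    nr <- nr + 1
    rows[[nr]] <- data.frame(i = i, j = j, k = k, l = l, class = cls,
                             native_angle = phi)
  }
  if (nr == 0) {
    return(data.frame(i = integer(), j = integer(), k = integer(),
                      l = integer(), class = character(),
                      native_angle = numeric()))
  }
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# bonded parameter table

#' Equilibrium bond/angle parameter table
#'
#' Loads the bundled table of equilibrium bond lengths (nm) and angles
#' (degrees) transcribed from the Amber ff03 parameter set: the
#' residue-independent backbone terms plus generic heavy-atom side-chain
#' classes.  Entries with residue `*` apply to any residue; a residue-specific
#' row takes precedence.
#'
#' @return data.frame with columns `kind`, `residue`, `atoms`, `value`.
#' @export
default_parameter_table <- function() {
  path <- system.file("extdata", "ff03_bonded.tsv", package = "capsidgo")
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  class(tab) <- c("parameter_table", "data.frame")
  tab
}

lookup_bonded <- function(table, kind, residue, atom_names) {
  key <- paste(atom_names, collapse = "-")
  keyr <- paste(rev(atom_names), collapse = "-")
  sub <- table[table$kind == kind & table$atoms %in% c(key, keyr), , drop = FALSE]
  if (nrow(sub) == 0) return(NA_real_)
  exact <- sub[sub$residue == residue, , drop = FALSE]
  if (nrow(exact) > 0) return(exact$value[1])
  wild <- sub[sub$residue == "*", , drop = FALSE]
  if (nrow(wild) > 0) return(wild$value[1])
  NA_real_
}

# ---------------------------------------------------------------------------
# topology assembly

#' Build a single-basin structure-based topology
#'
#' Constructs the full force field from the expanded reference conformation:
#' covalent bonds and angles (equilibrium values from the parameter table,
#' falling back to the reference geometry with a logged note), classified
#' dihedrals, a Shadow contact map with scaled minima, bonded exclusions and
#' excluded-volume parameters.  Every contact at its scaled minimum
#' contributes exactly `-epsilon`; flexible-dihedral strengths are set so the
#' total flexible-dihedral stabilising energy is `dihedral_contact_ratio`
#' times the total contact energy.
#'
#' @param reference expanded/mature [mol_structure()].
#' @param shadow a [shadow_params()].
#' @param scale_factor contact-minimum scaling (default 0.95).
#' @param param_table a parameter table ([default_parameter_table()]), or
#'   `NULL` to take all bonded equilibria from the reference geometry.
#' @param allow_fallback if `FALSE`, a missing bonded parameter is an error
#'   instead of a logged fallback to reference geometry.
#' @param epsilon contact energy scale (reduced units).
#' @param bond_k,angle_k bonded force constants (reduced units / nm^2,
#'   / rad^2).
#' @param rigid_dihedral_k force constant of rigid (periodicity-2) dihedrals.
#' @param dihedral_contact_ratio total flexible-dihedral : total contact
#'   stabilising-energy ratio.
#' @param excluded_volume_radius,excluded_volume_strength r^-12 repulsion
#'   parameters for non-excluded, non-contact pairs (nm; reduced units).
#' @param contact_form `"lj"` (6-12, default) or `"gaussian"`.
#' @param gaussian_width width of the gaussian contact well, nm.
#' @return an object of class `ff_topology`.
#' @export
build_topology <- function(reference, shadow = shadow_params(),
                           scale_factor = 0.95,
                           param_table = default_parameter_table(),
                           allow_fallback = TRUE,
                           epsilon = 1,
                           bond_k = 500, angle_k = 40,
                           rigid_dihedral_k = 10,
                           dihedral_contact_ratio = 0.5,
                           excluded_volume_radius = 0.25,
                           excluded_volume_strength = 1,
                           contact_form = c("lj", "gaussian"),
                           gaussian_width = 0.05) {
  stopifnot(inherits(reference, "mol_structure"))
  contact_form <- match.arg(contact_form)
  at <- reference$atoms
  xyz <- coords(reference)
  bonds <- structure_bonds(reference)
  notes <- character()

  dist_ij <- function(p) sqrt(rowSums((xyz[p[, 1], , drop = FALSE] -
                                         xyz[p[, 2], , drop = FALSE])^2))
  ## bonds
  b_r0 <- numeric(nrow(bonds)); n_fb <- 0
  ref_b <- dist_ij(bonds)
  for (m in seq_len(nrow(bonds))) {
    v <- if (is.null(param_table)) NA_real_ else
      lookup_bonded(param_table, "bond", at$residue_name[bonds[m, 1]],
                    at$atom_name[bonds[m, c(1, 2)]])
    if (is.na(v)) {
      if (!is.null(param_table) && !allow_fallback) {
        stop("missing bond parameter for ",
             paste(at$atom_name[bonds[m, c(1, 2)]], collapse = "-"),
             " in ", at$residue_name[bonds[m, 1]])
      }
      v <- ref_b[m]; n_fb <- n_fb + 1
    }
    b_r0[m] <- v
  }
  if (n_fb > 0 && !is.null(param_table)) {
    notes <- c(notes, sprintf(
      "%d/%d bond equilibria taken from reference geometry (no table entry)",
      n_fb, nrow(bonds)))
  }

  ## angles
  n <- nrow(at)
  adj <- adjacency_list(bonds, n)
  ang <- list(); na_ <- 0
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(nb, 2)
      for (q in seq_len(ncol(cmb))) {
        na_ <- na_ + 1
        ang[[na_]] <- c(cmb[1, q], j, cmb[2, q])
      }
    }
  }
  angles <- if (na_ > 0) do.call(rbind, ang) else matrix(integer(), 0, 3)
  a_th0 <- numeric(nrow(angles)); n_fa <- 0
  for (m in seq_len(nrow(angles))) {
    tri <- angles[m, ]
    v <- if (is.null(param_table)) NA_real_ else
      lookup_bonded(param_table, "angle", at$residue_name[tri[2]],
                    at$atom_name[tri])
    if (is.na(v)) {
      if (!is.null(param_table) && !allow_fallback) {
        stop("missing angle parameter for ",
             paste(at$atom_name[tri], collapse = "-"),
             " in ", at$residue_name[tri[2]])
      }
      v1 <- xyz[tri[1], ] - xyz[tri[2], ]; v2 <- xyz[tri[3], ] - xyz[tri[2], ]
      v <- acos(min(1, max(-1, sum(v1 * v2) /
                             sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      n_fa <- n_fa + 1
    }
    a_th0[m] <- v * pi / 180
  }
  if (n_fa > 0 && !is.null(param_table)) {
    notes <- c(notes, sprintf(
      "%d/%d angle equilibria taken from reference geometry (no table entry)",
      n_fa, nrow(angles)))
  }

  ## dihedrals
  dih <- classify_dihedrals(reference, bonds = bonds)

  ## contacts
  cmap <- shadow_contact_map(reference, params = shadow, bonds = bonds)
  cmap <- scale_contact_minima(cmap, scale_factor)
  cmap$eps <- rep(epsilon, nrow(cmap))

  n_flex <- sum(dih$class == "flexible")
  k_flex <- if (n_flex > 0) {
    dihedral_contact_ratio * epsilon * nrow(cmap) / n_flex
  } else 0
  dih$kd <- ifelse(dih$class == "rigid", rigid_dihedral_k, k_flex)

  excl <- bonded_exclusions(bonds, n)
  topo <- structure(list(
    n_atoms = n,
    bonds = data.frame(i = bonds[, 1], j = bonds[, 2], r0 = b_r0,
                       k = rep(bond_k, nrow(bonds))),
    angles = data.frame(i = angles[, 1], j = angles[, 2], k = angles[, 3],
                        theta0 = a_th0, ka = rep(angle_k, nrow(angles))),
    dihedrals = dih,
    contacts = cmap,
    exclusions = as_pair_matrix(rbind(excl, cbind(cmap$i, cmap$j))),
    excluded_volume = list(radius = excluded_volume_radius,
                           strength = excluded_volume_strength,
                           cutoff = max(2.4 * excluded_volume_radius, 0.6)),
    energy_scale = epsilon,
    contact_form = contact_form,
    gaussian_width = gaussian_width,
    atoms = at[c("chain_id", "residue_index", "residue_name", "atom_name",
                 "element")],
    reference = reference$source,
    notes = notes), class = "ff_topology")
  topo
}

#' @export
print.ff_topology <- function(x, ...) {
  cat("ff_topology:", x$n_atoms, "atoms |", nrow(x$bonds), "bonds |",
      nrow(x$angles), "angles |", nrow(x$dihedrals), "dihedrals (",
      sum(x$dihedrals$class == "rigid"), "rigid ) |", nrow(x$contacts),
      "contacts (", sum(x$contacts$intermolecular), "intermolecular )\n")
  if (length(x$notes)) cat(paste(" note:", x$notes, collapse = "\n"), "\n")
  invisible(x)
}

#' Position restraint specification
#'
#' @param indices atom indices to restrain.
#' @param reference `length(indices) x 3` matrix of reference positions, nm.
#' @param k spring constant(s), reduced energy / nm^2 (scalar or one per
#'   restrained atom).
#' @export
restraint_spec <- function(indices, reference, k) {
  indices <- as.integer(indices)
  reference <- as.matrix(reference)
  if (length(indices) == 0) stop("restraint selection is empty")
  if (!is.numeric(k) || any(k <= 0)) stop("restraint spring constant must be > 0")
  if (!(length(k) %in% c(1L, length(indices)))) {
    stop("k must be scalar or one value per restrained atom")
  }
  if (nrow(reference) != length(indices) || ncol(reference) != 3) {
    stop("restraint reference must be length(indices) x 3")
  }
  structure(list(indices = indices, reference = reference,
                 k = as.numeric(k)), class = "restraint_spec")
}

## assemble the argument list consumed by the C++ kernels; wall is an
## optional half-harmonic radial containment list(radius, k)
topo_cpp_list <- function(topology, restraints = NULL, wall = NULL) {
  stopifnot(inherits(topology, "ff_topology"))
  cm <- topology$contacts
  sigma <- if (is.null(cm$sigma)) cm$r_native else cm$sigma
  eps <- if (is.null(cm$eps)) rep(topology$energy_scale, nrow(cm)) else cm$eps
  if (is.null(restraints)) {
    ridx <- integer(0); rref <- matrix(0, 0, 3); rk <- 0
  } else {
    stopifnot(inherits(restraints, "restraint_spec"))
    ridx <- restraints$indices; rref <- restraints$reference
    rk <- restraints$k
  }
  list(n_atoms = topology$n_atoms,
       bonds = as_pair_matrix(cbind(topology$bonds$i, topology$bonds$j)),
       bond_r0 = topology$bonds$r0, bond_k = topology$bonds$k,
       angles = matrix(as.integer(c(topology$angles$i, topology$angles$j,
                                    topology$angles$k)), ncol = 3),
       angle_theta0 = topology$angles$theta0, angle_k = topology$angles$ka,
       dihedrals = matrix(as.integer(c(topology$dihedrals$i,
                                       topology$dihedrals$j,
                                       topology$dihedrals$k,
                                       topology$dihedrals$l)), ncol = 4),
       dih_phi0 = as.numeric(topology$dihedrals$native_angle),
       dih_k = as.numeric(topology$dihedrals$kd),
       dih_class = ifelse(topology$dihedrals$class == "rigid", 1L, 2L),
       contacts = matrix(as.integer(c(cm$i, cm$j)), ncol = 2),
       contact_sigma = sigma, contact_eps = eps,
       contact_form = if (topology$contact_form == "lj") 0L else 1L,
       gaussian_width = topology$gaussian_width,
       ev_sigma = topology$excluded_volume$radius,
       ev_eps = topology$excluded_volume$strength,
       ev_cutoff = topology$excluded_volume$cutoff,
       exclusions = topology$exclusions,
       restraint_idx = ridx, restraint_ref = rref, restraint_k = rk,
       wall_radius = if (is.null(wall)) 0 else wall$radius,
       wall_k = if (is.null(wall)) 0 else wall$k)
}

#' Potential energy of a configuration
#'
#' @param topology an `ff_topology`.
#' @param positions `n_atoms x 3` matrix (nm) or a [mol_structure()].
#' @param restraints optional [restraint_spec()].
#' @return list with `total` and per-term energies (`bond`, `angle`,
#'   `dihedral`, `contact`, `excluded_volume`, `restraint`), reduced units.
#' @export
potential_energy <- function(topology, positions, restraints = NULL) {
  if (inherits(positions, "mol_structure")) positions <- coords(positions)
  positions <- as.matrix(positions)
  if (nrow(positions) != topology$n_atoms || ncol(positions) != 3) {
    stop("shape error: positions must be n_atoms x 3 (got ",
         nrow(positions), " x ", ncol(positions), ")")
  }
  res <- .cg_energy_cpp(positions, topo_cpp_list(topology, restraints))
  res[c("total", "bond", "angle", "dihedral", "contact", "excluded_volume",
        "restraint")]
}

#' Forces on every atom
#'
#' @inheritParams potential_energy
#' @return `n_atoms x 3` matrix of forces, reduced energy / nm.
#' @export
forces <- function(topology, positions, restraints = NULL) {
  if (inherits(positions, "mol_structure")) positions <- coords(positions)
  positions <- as.matrix(positions)
  if (nrow(positions) != topology$n_atoms || ncol(positions) != 3) {
    stop("shape error: positions must be n_atoms x 3")
  }
  .cg_energy_cpp(positions, topo_cpp_list(topology, restraints))$forces
}

# ---------------------------------------------------------------------------
# topology export

#' Export a topology as JSON
#'
#' Serialises the complete force field (bonds, angles, dihedrals, contacts
#' with native distances and scaled minima, exclusions, excluded volume,
#' energy scale) into a documented JSON schema.
#'
#' @param topology an `ff_topology`.
#' @param path output path.
#' @export
export_topology_json <- function(topology, path) {
  cm <- topology$contacts
  obj <- list(
    schema = "capsidgo-topology-1",
    n_atoms = topology$n_atoms,
    energy_scale = topology$energy_scale,
    contact_form = topology$contact_form,
    excluded_volume = topology$excluded_volume,
    bonds = topology$bonds,
    angles = topology$angles,
    dihedrals = topology$dihedrals,
    contacts = as.data.frame(cm[names(cm)]),
    exclusions = as.data.frame(topology$exclusions),
    notes = topology$notes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Write a GROMACS-dialect topology file
#'
#' Interoperability export: emits `[ atoms ]`, `[ bonds ]` (function 1),
#' `[ angles ]` (function 1), `[ dihedrals ]` (function 1) and `[ pairs ]`
#' (function 1, 6-12 coefficients with the minimum at the scaled contact
#' distance) sections with unit conventions (nm, kJ/mol as reduced energy)
#' listed in the header comment.  Not intended to round-trip.
#'
#' @param topology an `ff_topology`.
#' @param path output path.
#' @export
write_topology_gromacs <- function(topology, path) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("; capsidgo structure-based topology export (GROMACS dialect)")
  w("; units: nm, reduced energy as kJ/mol; bonds/angles harmonic (funct 1),")
  w("; dihedrals periodic cosine (funct 1), contacts as [ pairs ] funct 1")
  w("; with C6 = 2 eps sigma^6, C12 = eps sigma^12")
  w("[ atoms ]")
  for (i in seq_len(topology$n_atoms)) {
    w("%6d %4s %6d %4s %4s %6d %8.3f %8.3f", i,
      topology$atoms$element[i], topology$atoms$residue_index[i],
      topology$atoms$residue_name[i], topology$atoms$atom_name[i], i, 0, 1)
  }
  w("[ bonds ]")
  b <- topology$bonds
  for (m in seq_len(nrow(b))) {
    w("%6d %6d 1 %10.6f %10.3f", b$i[m], b$j[m], b$r0[m], b$k[m])
  }
  w("[ angles ]")
  a <- topology$angles
  for (m in seq_len(nrow(a))) {
    w("%6d %6d %6d 1 %10.4f %10.3f", a$i[m], a$j[m], a$k[m],
      a$theta0[m] * 180 / pi, a$ka[m])
  }
  w("[ dihedrals ]")
  d <- topology$dihedrals
  for (m in seq_len(nrow(d))) {
    if (d$class[m] == "rigid") {
      w("%6d %6d %6d %6d 1 %10.4f %10.4f 2", d$i[m], d$j[m], d$k[m], d$l[m],
        180, d$kd[m])
    } else {
      w("%6d %6d %6d %6d 1 %10.4f %10.4f 1", d$i[m], d$j[m], d$k[m], d$l[m],
        d$native_angle[m] * 180 / pi, d$kd[m])
    }
  }
  w("[ pairs ]")
  cm <- topology$contacts
  sig <- if (is.null(cm$sigma)) cm$r_native else cm$sigma
  eps <- if (is.null(cm$eps)) rep(topology$energy_scale, nrow(cm)) else cm$eps
  for (m in seq_len(nrow(cm))) {
    w("%6d %6d 1 %14.6e %14.6e", cm$i[m], cm$j[m],
      2 * eps[m] * sig[m]^6, eps[m] * sig[m]^12)
  }
  w("[ exclusions ]")
  ex <- topology$exclusions
  for (m in seq_len(nrow(ex))) w("%6d %6d", ex[m, 1], ex[m, 2])
  invisible(path)
}
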