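## Structure containers and I/O.
##
## Coordinates are stored in nanometres throughout the package; PDB files
## (Angstrom) are converted on read/write.  A structure is a light S3 object:
## an atom table plus per-chain annotations (capsomer position label and the
## residue interval of the terminal tail).

#' Atomic structure container
#'
#' Builds a `mol_structure`: an ordered atom table with per-chain annotations.
#' Atoms must be grouped by chain, with non-decreasing residue indices within
#' each chain.  Positions are in nm.
#'
#' @param atoms data.frame with columns `element`, `atom_name`,
#'   `residue_index`, `residue_name`, `chain_id`, `x`, `y`, `z` (nm).
#' @param chains optional data.frame with columns `chain_id`,
#'   `position_label`, `tail_start`, `tail_end`.  Defaults to one row per
#'   chain with `NA` annotations.
#' @param source provenance string.
#' @param bonds optional integer matrix (two columns, global atom indices) of
#'   explicit covalent bonds; when present, topology construction uses it
#'   instead of distance-based inference.
#' @return object of class `mol_structure`.
#' @export
mol_structure <- function(atoms, chains = NULL, source = "", bonds = NULL) {
  req <- c("element", "atom_name", "residue_index", "residue_name",
           "chain_id", "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  atoms <- as.data.frame(atoms[req], stringsAsFactors = FALSE)
  atoms$residue_index <- as.integer(atoms$residue_index)
  if (nrow(atoms) == 0) stop("empty structure: no atoms")
  if (!all(is.finite(as.matrix(atoms[c("x", "y", "z")])))) {
    stop("non-finite coordinates in atom table")
  }
  ## atoms must group by chain: each chain id forms one contiguous block
  blocks <- rle(atoms$chain_id)$values
  if (anyDuplicated(blocks)) {
    stop("atoms are not grouped by chain: chain id(s) ",
         paste(unique(blocks[duplicated(blocks)]), collapse = ", "),
         " appear in more than one block")
  }
  for (cid in blocks) {
    ri <- atoms$residue_index[atoms$chain_id == cid]
    if (is.unsorted(ri)) {
      stop("residue indices not non-decreasing within chain ", cid)
    }
  }
  if (is.null(chains)) {
    chains <- data.frame(chain_id = blocks, position_label = NA_character_,
                         tail_start = NA_integer_, tail_end = NA_integer_,
                         stringsAsFactors = FALSE)
  } else {
    chains <- as.data.frame(chains, stringsAsFactors = FALSE)
    if (anyDuplicated(chains$chain_id)) stop("duplicate chain ids in annotations")
    if (!setequal(chains$chain_id, blocks)) {
      stop("chain annotations do not match the chains present in the atom table")
    }
    for (k in seq_len(nrow(chains))) {
      ts <- chains$tail_start[k]; te <- chains$tail_end[k]
      if (!is.na(ts) && !is.na(te)) {
        span <- range(atoms$residue_index[atoms$chain_id == chains$chain_id[k]])
        if (ts > te || ts < span[1] || te > span[2]) {
          stop("tail range [", ts, ",", te, "] outside residue span of chain ",
               chains$chain_id[k])
        }
      }
    }
  }
  out <- structure(list(atoms = atoms, chains = chains, source = source),
                   class = "mol_structure")
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    if (any(bonds < 1L) || any(bonds > nrow(atoms))) stop("bond index out of range")
    attr(out, "bonds") <- bonds
  }
  out
}

#' Blacklist atom pairs from the contact map
#'
#' Marks pairs that must never become native contacts (they keep their
#' excluded-volume repulsion).  Used by generators for scaffold beads whose
#' mid-range native distances would otherwise create contacts that the
#' formed criterion could satisfy from a non-translocated state.
#'
#' @param structure a [mol_structure()].
#' @param pairs two-column matrix of atom indices.
#' @export
blacklist_contacts <- function(structure, pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  attr(structure, "contact_blacklist") <-
    rbind(attr(structure, "contact_blacklist"), pairs)
  structure
}

#' @export
print.mol_structure <- function(x, ...) {
  cat("mol_structure:", nrow(x$atoms), "atoms,", nrow(x$chains), "chains",
      if (nzchar(x$source)) paste0("[", x$source, "]") else "", "\n")
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure a `mol_structure`.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' Coordinate matrix of a structure
#' @param structure a `mol_structure`.
#' @return numeric matrix, one row per atom, columns x/y/z in nm.
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[c("x", "y", "z")])
}

#' Replace the coordinates of a structure
#' @param structure a `mol_structure`.
#' @param xyz numeric matrix (n_atoms x 3), nm.
#' @export
set_coords <- function(structure, xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != n_atoms(structure) || ncol(xyz) != 3) {
    stop("coordinate matrix must be n_atoms x 3")
  }
  structure$atoms$x <- xyz[, 1]; structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

## standard atomic masses (u); pseudo-atoms default to carbon
.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     S = 32.06, P = 30.974, SE = 78.971)

atom_masses <- function(structure) {
  m <- .element_masses[toupper(structure$atoms$element)]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Global atom indices for a chain / residue selection
#'
#' @param structure a `mol_structure`.
#' @param chain_id chain identifier.
#' @param residues optional integer vector (or length-2 range) of residue
#'   indices within that chain.
#' @export
atom_indices <- function(structure, chain_id, residues = NULL) {
  sel <- structure$atoms$chain_id == chain_id
  if (!any(sel)) stop("no such chain: ", chain_id)
  if (!is.null(residues)) {
    if (length(residues) == 2 && residues[2] >= residues[1]) {
      residues <- seq.int(residues[1], residues[2])
    }
    sel <- sel & structure$atoms$residue_index %in% residues
  }
  which(sel)
}

# ---------------------------------------------------------------------------
# reading / writing structures

#' Read a structure from file
#'
#' Reads PDB (`.pdb`, via bio3d) or the package's plain-text coordinate
#' dialect (`.cgs`, tab-separated with multi-character chain ids).  PDB
#' coordinates are converted from Angstrom to nm.  Only the first alternate
#' location is kept; atoms carrying insertion codes are dropped with a
#' warning.
#'
#' @param path file path.
#' @param heavy_only drop hydrogens (default `TRUE`).
#' @return a [mol_structure()].
#' @export
read_structure <- function(path, heavy_only = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "cgs") return(read_cgs(path, heavy_only = heavy_only))
  pdb <- tryCatch(
    bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("PDB format error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("empty structure (no atoms) in ", path)
  ## first altloc only
  alts <- unique(at$alt[!is.na(at$alt) & at$alt != ""])
  if (length(alts) > 1 || (length(alts) == 1 && any(is.na(at$alt) | at$alt == ""))) {
    at <- at[is.na(at$alt) | at$alt == "" | at$alt == sort(alts)[1], , drop = FALSE]
  }
  ins <- !is.na(at$insert) & at$insert != ""
  if (any(ins)) {
    warning(sum(ins), " atom(s) with insertion codes dropped from ", path)
    at <- at[!ins, , drop = FALSE]
  }
  element <- toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                            gsub("[^A-Za-z].*$", "", substr(trimws(at$elety), 1, 1)),
                            trimws(at$elesy)))
  if (heavy_only) {
    keep <- !(element %in% c("H", "D"))
    at <- at[keep, , drop = FALSE]; element <- element[keep]
  }
  if (nrow(at) == 0) stop("empty structure after filtering in ", path)
  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  atoms <- data.frame(element = element,
                      atom_name = trimws(at$elety),
                      residue_index = as.integer(at$resno),
                      residue_name = trimws(at$resid),
                      chain_id = chain,
                      x = at$x / 10, y = at$y / 10, z = at$z / 10,
                      stringsAsFactors = FALSE)
  mol_structure(atoms, source = path)
}

read_cgs <- function(path, heavy_only = TRUE) {
  at <- tryCatch(
    read.delim(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("cgs format error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  req <- c("chain_id", "residue_index", "residue_name", "atom_name",
           "element", "x", "y", "z")
  if (!all(req %in% names(at))) {
    stop("cgs format error in ", path, ": expected columns ",
         paste(req, collapse = ", "))
  }
  if (heavy_only) at <- at[!(toupper(at$element) %in% c("H", "D")), , drop = FALSE]
  if (nrow(at) == 0) stop("empty structure in ", path)
  mol_structure(at, source = path)
}

#' Write a structure to file
#'
#' PDB output (single-character chain ids required, coordinates emitted in
#' Angstrom at 0.001 A precision) or the `.cgs` dialect (full precision,
#' arbitrary chain ids).
#'
#' @param structure a [mol_structure()].
#' @param path output path; format chosen by extension (`.pdb` or `.cgs`).
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "mol_structure"))
  ext <- tolower(tools::file_ext(path))
  at <- structure$atoms
  if (ext == "pdb") {
    if (any(nchar(at$chain_id) > 1)) {
      stop("PDB output requires single-character chain ids; use .cgs instead")
    }
    ok <- tryCatch({
      bio3d::write.pdb(file = path,
                       xyz = as.vector(t(coords(structure) * 10)),
                       resno = at$residue_index,
                       resid = at$residue_name,
                       eleno = seq_len(nrow(at)),
                       elety = at$atom_name,
                       chain = at$chain_id,
                       elesy = at$element)
      TRUE
    }, error = function(e) stop("cannot write ", path, ": ",
                                conditionMessage(e), call. = FALSE))
    invisible(ok)
  } else {
    con <- tryCatch(file(path, "w"),
                    error = function(e) stop("cannot write ", path, call. = FALSE))
    on.exit(close(con))
    writeLines("# capsidgo structure (.cgs); coordinates in nm", con)
    out <- at
    out$x <- sprintf("%.6f", out$x); out$y <- sprintf("%.6f", out$y)
    out$z <- sprintf("%.6f", out$z)
    ## keep column order stable for round-tripping
    out <- out[c("chain_id", "residue_index", "residue_name", "atom_name",
                 "element", "x", "y", "z")]
    suppressWarnings(write.table(out, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE))
    invisible(TRUE)
  }
}

# ---------------------------------------------------------------------------
# assembly expansion

#' Build an assembly from an asymmetric unit
#'
#' Applies a list of proper rigid motions to a structure and concatenates the
#' copies (e.g. 60 icosahedral symmetry operators applied to a 7-chain
#' asymmetric subunit give the full 420-chain shell).  Chain ids are
#' disambiguated by transform index; position labels and tail ranges are
#' inherited.
#'
#' @param asym a [mol_structure()].
#' @param transforms list of `list(R = <3x3 rotation>, t = <3-vector, nm>)`.
#' @return a [mol_structure()] with `n_atoms(asym) * length(transforms)` atoms.
#' @export
expand_assembly <- function(asym, transforms) {
  stopifnot(inherits(asym, "mol_structure"), length(transforms) >= 1)
  for (k in seq_along(transforms)) {
    R <- transforms[[k]]$R
    if (is.null(R) || !all(dim(R) == c(3, 3)) ||
        max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0) {
      stop("invalid transform ", k, ": rotation must be proper orthonormal ",
           "(tolerance 1e-6)")
    }
    if (length(transforms[[k]]$t) != 3) {
      stop("invalid transform ", k, ": translation must have length 3")
    }
  }
  xyz <- coords(asym)
  pieces <- vector("list", length(transforms))
  ann <- vector("list", length(transforms))
  for (k in seq_along(transforms)) {
    at <- asym$atoms
    newxyz <- xyz %*% t(transforms[[k]]$R) +
      matrix(transforms[[k]]$t, nrow(xyz), 3, byrow = TRUE)
    at$x <- newxyz[, 1]; at$y <- newxyz[, 2]; at$z <- newxyz[, 3]
    at$chain_id <- paste0(at$chain_id, ".", k)
    pieces[[k]] <- at
    ck <- asym$chains
    ck$chain_id <- paste0(ck$chain_id, ".", k)
    ann[[k]] <- ck
  }
  mol_structure(do.call(rbind, pieces), chains = do.call(rbind, ann),
                source = paste0(asym$source, " x", length(transforms)))
}

#' Read rigid-body transforms
#'
#' Parses either PDB `REMARK 350 BIOMT` records (translations in Angstrom,
#' converted to nm) or a plain numeric format: three whitespace-separated
#' rows of `r1 r2 r3 t` per transform (translations in nm), transforms
#' separated by blank lines or simply concatenated.
#'
#' @param path file path.
#' @return list of `list(R, t)` transforms.
#' @export
read_transforms <- function(path) {
  lines <- readLines(path)
  biomt <- grepl("BIOMT[123]", lines)
  if (any(biomt)) {
    rows <- lines[biomt]
    parse_row <- function(s) {
      toks <- strsplit(trimws(sub(".*BIOMT[123]", "", s)), "\\s+")[[1]]
      as.numeric(toks[-1])  # first token is the transform serial
    }
    vals <- unname(t(vapply(rows, parse_row, numeric(4))))
    scale_t <- 0.1  # Angstrom -> nm
  } else {
    toks <- as.numeric(unlist(strsplit(trimws(lines[nzchar(trimws(lines))]), "\\s+")))
    toks <- toks[!is.na(toks)]
    if (length(toks) %% 12 != 0) stop("transform file not a multiple of 3x4 rows")
    vals <- matrix(toks, ncol = 4, byrow = TRUE)
    scale_t <- 1
  }
  if (nrow(vals) %% 3 != 0) stop("incomplete BIOMT transform in ", path)
  n <- nrow(vals) / 3
  lapply(seq_len(n), function(k) {
    block <- vals[(3 * k - 2):(3 * k), , drop = FALSE]
    list(R = block[, 1:3], t = block[, 4] * scale_t)
  })
}

# ---------------------------------------------------------------------------
# geometry

#' Radius of gyration
#'
#' `Rg = sqrt( sum w_i |r_i - rbar|^2 / sum w_i )`.  Default is unweighted
#' over the (heavy) atoms present; set `mass_weighted = TRUE` to weight by
#' element masses.
#'
#' @param x a [mol_structure()] or an `n x 3` coordinate matrix (nm).
#' @param mass_weighted logical flag.
#' @return length in nm.
#' @export
radius_of_gyration <- function(x, mass_weighted = FALSE) {
  if (inherits(x, "mol_structure")) {
    w <- if (mass_weighted) atom_masses(x) else rep(1, n_atoms(x))
    x <- coords(x)
  } else {
    x <- as.matrix(x)
    w <- rep(1, nrow(x))
    if (mass_weighted) {
      warning("mass weighting ignored for bare coordinate matrices")
    }
  }
  if (nrow(x) == 0) stop("empty input: radius of gyration needs >= 1 atom")
  ctr <- colSums(x * w) / sum(w)
  d2 <- rowSums(sweep(x, 2, ctr)^2)
  sqrt(sum(w * d2) / sum(w))
}

#' Root-mean-square coordinate deviation (no superposition)
#' @param a,b `n x 3` matrices or structures with equal atom counts.
#' @export
rmsd_coords <- function(a, b) {
  if (inherits(a, "mol_structure")) a <- coords(a)
  if (inherits(b, "mol_structure")) b <- coords(b)
  stopifnot(all(dim(a) == dim(b)))
  sqrt(mean(rowSums((a - b)^2)))
}

# ---------------------------------------------------------------------------
# trajectories

#' Trajectory container
#'
#' @param frames numeric array `n_frames x n_atoms x 3` (nm).
#' @param times numeric vector of frame times in reduced units.
#' @param elements character vector of element symbols (recycled "C" if NULL).
#' @param metadata named list of run metadata (seed, temperature, ...).
#' @export
cg_trajectory <- function(frames, times, elements = NULL, metadata = list()) {
  frames <- as.array(frames)
  if (length(dim(frames)) != 3 || dim(frames)[3] != 3) {
    stop("frames must be an n_frames x n_atoms x 3 array")
  }
  if (dim(frames)[1] != length(times)) stop("times length must equal frame count")
  if (is.unsorted(times, strictly = TRUE) && length(times) > 1) {
    stop("frame times must be strictly increasing")
  }
  if (is.null(elements)) elements <- rep("C", dim(frames)[2])
  structure(list(frames = frames, times = as.numeric(times),
                 elements = elements, metadata = metadata),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("cg_trajectory:", dim(x$frames)[1], "frames x", dim(x$frames)[2],
      "atoms; t =", format(min(x$times)), "..", format(max(x$times)),
      "(reduced units)\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory a [cg_trajectory()].
#' @export
n_frames <- function(trajectory) dim(trajectory$frames)[1]

#' Extract one frame as a coordinate matrix
#' @param trajectory a [cg_trajectory()].
#' @param i frame index.
#' @export
frame_coords <- function(trajectory, i) {
  stopifnot(i >= 1, i <= n_frames(trajectory))
  matrix(trajectory$frames[i, , ], ncol = 3)
}

#' Write a trajectory in the plain-text XYZ-class format
#'
#' Per frame: an atom-count line, a comment line carrying the frame time in
#' reduced units (the first frame's comment also carries the run metadata as
#' JSON), then one `element x y z` line per atom in nm.
#'
#' @param trajectory a [cg_trajectory()].
#' @param path output path.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "cg_trajectory"))
  nf <- n_frames(trajectory)
  if (nf == 0) stop("empty trajectory: nothing to write")
  na <- dim(trajectory$frames)[2]
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path, call. = FALSE))
  on.exit(close(con))
  for (i in seq_len(nf)) {
    writeLines(as.character(na), con)
    cmt <- sprintf("t= %.9g", trajectory$times[i])
    if (i == 1 && length(trajectory$metadata) > 0) {
      cmt <- paste0(cmt, " meta= ", jsonlite::toJSON(trajectory$metadata,
                                                     auto_unbox = TRUE))
    }
    writeLines(cmt, con)
    fr <- matrix(trajectory$frames[i, , ], ncol = 3)
    writeLines(sprintf("%s %.6f %.6f %.6f", trajectory$elements,
                       fr[, 1], fr[, 2], fr[, 3]), con)
  }
  invisible(TRUE)
}

#' Read a trajectory written by [write_trajectory()]
#' @param path file path.
#' @return a [cg_trajectory()].
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  pos <- 1L; nf <- 0L
  frames <- list(); times <- numeric(); meta <- list(); elements <- NULL
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    na <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(na)) stop("trajectory format error at line ", pos)
    cmt <- lines[pos + 1L]
    t <- as.numeric(sub("^t=\\s*(\\S+).*$", "\\1", cmt))
    if (grepl("meta= ", cmt, fixed = TRUE) && nf == 0L) {
      meta <- jsonlite::fromJSON(sub("^.*meta= ", "", cmt))
    }
    block <- lines[(pos + 2L):(pos + 1L + na)]
    toks <- strsplit(trimws(block), "\\s+")
    if (is.null(elements)) elements <- vapply(toks, `[[`, "", 1)
    xyz <- t(vapply(toks, function(v) as.numeric(v[2:4]), numeric(3)))
    nf <- nf + 1L
    frames[[nf]] <- xyz; times[nf] <- t
    pos <- pos + 2L + na
  }
  if (nf == 0L) stop("empty trajectory file: ", path)
  arr <- array(0, dim = c(nf, nrow(frames[[1]]), 3))
  for (i in seq_len(nf)) arr[i, , ] <- frames[[i]]
  cg_trajectory(arr, times, elements = elements, metadata = meta)
}
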