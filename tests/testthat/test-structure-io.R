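test_that("structure construction enforces its invariants", {
  at <- data.frame(element = "C", atom_name = "CA", residue_index = 1:3,
                   residue_name = "GLY", chain_id = "A",
                   x = c(0, 0.4, 0.8), y = 0, z = 0)
  s <- mol_structure(at)
  expect_equal(n_atoms(s), 3)
  expect_equal(nrow(s$chains), 1)

  expect_error(mol_structure(at[0, ]), "empty")
  bad <- at; bad$x[2] <- NA
  expect_error(mol_structure(bad), "non-finite")
  split_chain <- at; split_chain$chain_id <- c("A", "B", "A")
  expect_error(mol_structure(split_chain), "grouped")
  unsorted <- at; unsorted$residue_index <- c(2L, 1L, 3L)
  expect_error(mol_structure(unsorted), "non-decreasing")
  expect_error(
    mol_structure(at, chains = data.frame(chain_id = "A",
                                          position_label = "A",
                                          tail_start = 1L, tail_end = 9L)),
    "outside")
})

test_that("radius of gyration matches closed forms and is rigid-motion invariant", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  two <- matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(radius_of_gyration(two), 1)
  cube <- as.matrix(expand.grid(c(0, 2), c(0, 2), c(0, 2)))
  expect_equal(radius_of_gyration(cube), sqrt(3))

  expect_error(radius_of_gyration(matrix(numeric(), 0, 3)), "empty")

  set.seed(11)
  pts <- matrix(rnorm(60), 20, 3)
  rg0 <- radius_of_gyration(pts)
  for (rep in 1:5) {
    R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    moved <- pts %*% t(R) + matrix(rnorm(3), 20, 3, byrow = TRUE)
    expect_lt(abs(radius_of_gyration(moved) - rg0), 1e-9)
  }
})

test_that("PDB and cgs round trips preserve coordinates at format precision", {
  at <- data.frame(element = c("C", "N", "O"), atom_name = c("CA", "N", "O"),
                   residue_index = c(1L, 1L, 2L), residue_name = "GLY",
                   chain_id = "A",
                   x = c(0.1234, 0.5678, 1.23456),
                   y = c(-0.4321, 0, 0.5),
                   z = c(0.001, 2.0, -1.5))
  s <- mol_structure(at, source = "fixture")

  pdb <- tempfile(fileext = ".pdb")
  write_structure(s, pdb)
  back <- read_structure(pdb)
  expect_equal(n_atoms(back), 3)
  expect_lt(max(abs(coords(back) - coords(s))), 1e-3)

  cgs <- tempfile(fileext = ".cgs")
  write_structure(s, cgs)
  back2 <- read_structure(cgs)
  expect_lt(max(abs(coords(back2) - coords(s))), 1e-6)
  expect_equal(back2$atoms$chain_id, s$atoms$chain_id)
})

test_that("hydrogens are filtered by heavy_only and empty files error", {
  at <- data.frame(element = c("C", "H", "N", "H", "O"),
                   atom_name = c("CA", "HA", "N", "H", "O"),
                   residue_index = 1L, residue_name = "GLY", chain_id = "A",
                   x = seq(0, 0.4, by = 0.1), y = 0, z = 0)
  p <- tempfile(fileext = ".cgs")
  write_structure(mol_structure(at), p)
  expect_equal(n_atoms(read_structure(p, heavy_only = TRUE)), 3)
  expect_equal(n_atoms(read_structure(p, heavy_only = FALSE)), 5)
  expect_error(read_structure(tempfile(fileext = ".pdb")), "no such file")
})

test_that("assembly expansion multiplies atoms, preserves geometry and labels", {
  at <- data.frame(element = "C", atom_name = "CA", residue_index = 1:10,
                   residue_name = "GLY", chain_id = "A",
                   x = runif(10), y = runif(10), z = runif(10))
  ann <- data.frame(chain_id = "A", position_label = "D",
                    tail_start = 1L, tail_end = 3L)
  asym <- mol_structure(at, chains = ann)

  ident <- expand_assembly(asym, list(list(R = diag(3), t = c(0, 0, 0))))
  expect_equal(coords(ident), coords(asym), ignore_attr = TRUE)

  set.seed(5)
  trs <- lapply(1:2, function(k) {
    R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    list(R = R, t = rnorm(3))
  })
  out <- expand_assembly(asym, trs)
  expect_equal(n_atoms(out), 20)
  expect_equal(out$chains$position_label, c("D", "D"))
  ## inverse consistency: mapping each copy back gives zero RMSD
  for (k in 1:2) {
    copy <- coords(out)[((k - 1) * 10 + 1):(k * 10), ]
    undone <- sweep(copy, 2, trs[[k]]$t) %*% trs[[k]]$R
    expect_lt(rmsd_coords(undone, coords(asym)), 1e-9)
  }
  ## intra-chain distances invariant
  d0 <- dist(coords(asym))
  d1 <- dist(coords(out)[11:20, ])
  expect_lt(max(abs(d0 - d1)), 1e-6)

  ## a 7-chain asymmetric unit under 60 operators gives 420 chains
  at7 <- do.call(rbind, lapply(1:7, function(c0) {
    data.frame(element = "C", atom_name = "CA", residue_index = 1L,
               residue_name = "GLY", chain_id = LETTERS[c0],
               x = c0 * 0.5, y = 0, z = 0)
  }))
  asym7 <- mol_structure(at7)
  set.seed(6)
  ops <- lapply(1:60, function(k) {
    R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    list(R = R, t = rnorm(3, sd = 5))
  })
  shell420 <- expand_assembly(asym7, ops)
  expect_equal(nrow(shell420$chains), 420)
  expect_equal(n_atoms(shell420), 7 * 60)

  expect_error(expand_assembly(asym, list(list(R = diag(3) * 1.01, t = rep(0, 3)))),
               "invalid transform")
})

test_that("BIOMT and plain transform files parse with unit conversion", {
  p <- tempfile()
  writeLines(c(
    "REMARK 350   BIOMT1   1  1.000000  0.000000  0.000000        0.00000",
    "REMARK 350   BIOMT2   1  0.000000  1.000000  0.000000        0.00000",
    "REMARK 350   BIOMT3   1  0.000000  0.000000  1.000000       10.00000"),
    p)
  tr <- read_transforms(p)
  expect_length(tr, 1)
  expect_equal(tr[[1]]$R, diag(3))
  expect_equal(tr[[1]]$t, c(0, 0, 1))  # 10 Angstrom -> 1 nm

  p2 <- tempfile()
  writeLines(c("0 -1 0 0.5", "1 0 0 0", "0 0 1 0"), p2)
  tr2 <- read_transforms(p2)
  expect_equal(tr2[[1]]$t, c(0.5, 0, 0))
  expect_equal(det(tr2[[1]]$R), 1)
})

test_that("trajectory round trips preserve frames, times and metadata", {
  fr <- array(0, dim = c(2, 4, 3))
  fr[1, , ] <- matrix(runif(12), 4, 3)
  fr[2, , ] <- fr[1, , ] + 0.1
  traj <- cg_trajectory(fr, times = c(0, 2.5),
                        elements = c("C", "N", "O", "C"),
                        metadata = list(seed = 7, temperature = 0.582))
  p <- tempfile(fileext = ".xyz")
  write_trajectory(traj, p)
  back <- read_trajectory(p)
  expect_equal(n_frames(back), 2)
  expect_lt(max(abs(back$frames - traj$frames)), 1e-6)
  expect_equal(back$times, traj$times)
  expect_equal(back$metadata$seed, 7)

  expect_error(cg_trajectory(array(0, c(0, 4, 3)), numeric(0)) |>
                 write_trajectory(p), "empty")
})
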