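test_that("the generator is deterministic with complete annotations", {
  a <- make_toy_shell(toy_shell_spec(chains_per_class = 2L), seed = 4L)
  b <- make_toy_shell(toy_shell_spec(chains_per_class = 2L), seed = 4L)
  expect_identical(coords(a$compact), coords(b$compact))
  expect_identical(coords(a$expanded_reference), coords(b$expanded_reference))
  c2 <- make_toy_shell(toy_shell_spec(chains_per_class = 2L), seed = 5L)
  expect_false(identical(coords(a$compact), coords(c2$compact)))

  ann <- a$annotations
  caps <- ann[!is.na(ann$position_label), ]
  expect_equal(nrow(caps), 14)
  expect_true(all(table(caps$position_label) == 2))
  expect_true(all(!is.na(caps$tail_start) & !is.na(caps$tail_end)))
  expect_false(anyDuplicated(ann$chain_id) > 0)
})

test_that("default shell bookkeeping: 7 classes x 3 chains, balanced labels", {
  sp <- toy_shell_spec()
  sh <- make_toy_shell(sp, seed = 2L)
  caps <- sh$annotations[!is.na(sh$annotations$position_label), ]
  expect_equal(nrow(caps), 21)
  expect_true(all(table(caps$position_label) == 3))
  expect_length(sh$cavity_map, 21)
})

test_that("the expanded/compact pair reproduces the capsid radius relationship", {
  rg_e <- radius_of_gyration(ts_shell$expanded_reference)
  rg_c <- radius_of_gyration(ts_shell$compact)
  expect_gt(rg_e, rg_c)
  target <- ts_shell$spec$expanded_radius / ts_shell$spec$compact_radius
  expect_lt(abs((rg_e / rg_c) / target - 1), 0.10)

  ## tails exterior in the expanded reference, interior in the compact state
  caps <- capsomer_chains(ts_shell)
  xe <- coords(ts_shell$expanded_reference)
  xc <- coords(ts_shell$compact)
  body <- unlist(lapply(caps, function(cid)
    atom_indices(ts_shell$expanded_reference, cid, c(9L, 40L))))
  surf_e <- median(sqrt(rowSums(xe[body, ]^2)))
  surf_c <- median(sqrt(rowSums(xc[body, ]^2)))
  for (cid in caps) {
    ti <- atom_indices(ts_shell$expanded_reference, cid, c(1L, 8L))
    expect_true(all(sqrt(rowSums(xe[ti, , drop = FALSE]^2)) > surf_e))
    expect_true(all(sqrt(rowSums(xc[ti, , drop = FALSE]^2)) < surf_c))
  }

  ## every tail has at least one intermolecular contact in the reference
  for (cid in caps) {
    sub <- tail_contact_subset(ts_topo$contacts, ts_shell$expanded_reference,
                               cid)
    expect_gt(nrow(sub), 0)
  }
})

test_that("infeasible specifications are rejected", {
  expect_error(toy_shell_spec(cavity_half_widths = rep(0.1, 7)),
               "infeasible")
  expect_error(toy_shell_spec(tail_length = 2L), "tail_length")
  expect_error(toy_shell_spec(tail_length = 20L,
                              residues_per_chain = 40L),
               "infeasible spec: tail longer")
  expect_error(toy_shell_spec(compact_radius = 3, expanded_radius = 2.5),
               "must exceed")
  expect_error(toy_shell_spec(cavity_half_widths = c(A = 0.3)),
               "one entry per position class")
})

test_that("unit fixtures are small, deterministic and annotated as documented", {
  expect_equal(n_atoms(fx$harmonic_dimer), 2)
  expect_equal(nrow(attr(fx$harmonic_dimer, "bonds")), 1)
  again <- make_unit_fixtures()
  expect_identical(coords(again$random_cloud), coords(fx$random_cloud))
  expect_equal(n_atoms(fx$dipeptide), 11)
  expect_equal(sum(fx$dipeptide$atoms$atom_name == "CB"), 2)
})

test_that("exported toy shells round-trip through PDB plus sidecar", {
  dir <- tempfile()
  export_toy_shell(ts_shell, dir)
  expect_true(file.exists(file.path(dir, "compact.pdb")))
  back <- read_structure(file.path(dir, "expanded.pdb"))
  expect_equal(n_atoms(back), n_atoms(ts_shell$expanded_reference))
  side <- jsonlite::fromJSON(file.path(dir, "annotations.json"))
  expect_equal(nrow(side$annotations), nrow(ts_shell$annotations))
  expect_equal(side$spec$chains_per_class, 2)
})
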