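test_that("shadow screening removes occluded pairs and respects the cutoff", {
  ## three collinear atoms 0.3 nm apart on separate chains: the outer pair
  ## is occluded by the middle atom
  at <- data.frame(element = "C", atom_name = "CA", residue_index = 1L,
                   residue_name = "GLY", chain_id = c("A", "B", "C"),
                   x = c(0, 0.3, 0.6), y = 0, z = 0)
  s <- mol_structure(at)
  cm <- shadow_contact_map(s, shadow_params(contact_cutoff = 0.7,
                                            shadow_radius = 0.1))
  expect_equal(nrow(cm), 2)
  expect_false(any(cm$i == 1 & cm$j == 3))

  ## two atoms 0.4 nm apart: exactly one contact
  s2 <- mol_structure(at[1:2, ] |> transform(x = c(0, 0.4)))
  expect_equal(nrow(shadow_contact_map(s2, shadow_params())), 1)

  expect_error(shadow_params(contact_cutoff = 0.05, shadow_radius = 0.1),
               "parameter error")
})

test_that("shadow map is a subset of the cutoff map, equal at radius zero", {
  cl <- random_cloud(101)
  cm_shadow <- shadow_contact_map(cl, shadow_params())
  cm_zero <- shadow_contact_map(cl, shadow_params(shadow_radius = 0,
                                                  bonded_radius = 0))
  key <- function(cm) paste(cm$i, cm$j)
  expect_true(all(key(cm_shadow) %in% key(cm_zero)))
  ## radius 0: only exact collinearity occludes, so this is the cutoff map
  d <- as.matrix(dist(coords(cl)))
  at <- cl$atoms
  plain <- 0L
  excl <- capsidgo:::bonded_exclusions(attr(cl, "bonds"), n_atoms(cl))
  ek <- paste(excl[, 1], excl[, 2])
  for (i in 1:(n_atoms(cl) - 1)) for (j in (i + 1):n_atoms(cl)) {
    if (d[i, j] > 0.6) next
    if (at$chain_id[i] == at$chain_id[j] &&
        abs(at$residue_index[i] - at$residue_index[j]) < 3) next
    if (paste(i, j) %in% ek) next
    plain <- plain + 1L
  }
  expect_equal(nrow(cm_zero), plain)
})

test_that("contact count is monotone in shadow radius and cutoff", {
  cl <- random_cloud(202, n = 40)
  n_at_radius <- vapply(c(0, 0.05, 0.1, 0.15), function(r) {
    nrow(shadow_contact_map(cl, shadow_params(shadow_radius = r,
                                              bonded_radius = min(r, 0.05))))
  }, numeric(1))
  expect_true(all(diff(n_at_radius) <= 0))
  n_at_cut <- vapply(c(0.4, 0.5, 0.6, 0.7), function(cc) {
    nrow(shadow_contact_map(cl, shadow_params(contact_cutoff = cc)))
  }, numeric(1))
  expect_true(all(diff(n_at_cut) >= 0))
})

test_that("contact-minimum scaling composes multiplicatively", {
  cl <- random_cloud(303)
  cm <- shadow_contact_map(cl, shadow_params())
  s1 <- scale_contact_minima(cm, 0.95)
  expect_equal(s1$sigma, 0.95 * s1$r_native)
  expect_equal(scale_contact_minima(cm, 1.0)$sigma, cm$r_native)
  s2 <- scale_contact_minima(s1, 0.95)
  expect_equal(s2$sigma, 0.9025 * s2$r_native)
  expect_equal(s2$r_native, cm$r_native)
  expect_error(scale_contact_minima(cm, 0), "parameter error")
})

test_that("a single scaled contact example reproduces the printed value", {
  cm <- data.frame(i = 1L, j = 2L, r_native = 0.50)
  expect_equal(scale_contact_minima(cm, 0.95)$sigma, 0.475)
})

test_that("dihedral classification matches the hand-built dipeptide table", {
  ## ALA-ALA heavy atoms: rotatable central bonds are CA1-C1 (psi),
  ## N2-CA2 (phi) and CA2-C2 (psi'); the peptide bond C1-N2 joins two
  ## planar atoms and is rigid
  d <- classify_dihedrals(fx$dipeptide)
  expect_equal(nrow(d), 4)
  key <- paste(d$j, d$k)
  expected <- c("2 3" = "flexible",  # CA1-C1
                "3 6" = "rigid",     # C1-N2 (omega)
                "6 7" = "flexible",  # N2-CA2 (phi)
                "7 8" = "flexible")  # CA2-C2
  expect_equal(stats::setNames(d$class, key), expected)

  unk <- fx$dipeptide
  unk$atoms$residue_name <- "XXX"
  expect_error(classify_dihedrals(unk), "unknown residue.*XXX")
})

test_that("covalent bonds of the dipeptide match hand enumeration", {
  topo <- build_topology(fx$dipeptide)
  ## N1-CA1, CA1-C1, CA1-CB1, C1-O1, C1-N2, N2-CA2, CA2-C2, CA2-CB2,
  ## C2-O2, C2-OXT
  expect_equal(nrow(topo$bonds), 10)
  expect_true(all(c(paste(1, 2), paste(3, 6)) %in%
                    paste(topo$bonds$i, topo$bonds$j)))
})

test_that("bonded parameter table lookups use ff03 values with logged fallback", {
  tab <- default_parameter_table()
  expect_equal(capsidgo:::lookup_bonded(tab, "bond", "ALA", c("N", "CA")),
               0.1449)
  expect_equal(capsidgo:::lookup_bonded(tab, "angle", "GLY", c("N", "CA", "C")),
               110.1)
  ## residue-specific rows take precedence over the generic class
  expect_equal(capsidgo:::lookup_bonded(tab, "bond", "PHE", c("CG", "CD1")),
               0.1400)
  expect_true(is.na(capsidgo:::lookup_bonded(tab, "bond", "GLY",
                                             c("CA", "CA"))))

  topo <- build_topology(fx$dipeptide)
  expect_equal(topo$bonds$r0[topo$bonds$i == 1 & topo$bonds$j == 2], 0.1449)
  ## toy beads have no table entries: fallback to reference geometry logs
  topo_toy <- build_topology(fx$harmonic_dimer)
  expect_match(paste(topo_toy$notes, collapse = " "), "reference geometry")
  expect_error(build_topology(fx$harmonic_dimer, allow_fallback = FALSE),
               "missing bond parameter")
})

test_that("potential energy terms match closed forms and sum to the total", {
  topo <- build_topology(fx$harmonic_dimer, param_table = NULL)
  x <- coords(fx$harmonic_dimer)
  x[2, 1] <- x[2, 1] + 0.05
  e <- potential_energy(topo, x)
  expect_equal(e$bond, 0.5 * 500 * 0.05^2)
  expect_equal(e$total,
               e$bond + e$angle + e$dihedral + e$contact +
                 e$excluded_volume + e$restraint,
               tolerance = 1e-9)
  expect_error(potential_energy(topo, x[1, , drop = FALSE]), "shape error")
})

test_that("every contact at its scaled minimum contributes exactly -eps", {
  cl <- random_cloud(404)
  topo <- build_topology(cl, param_table = NULL)
  ## compress every contact to sigma along the pair axis is impractical for
  ## a shared cloud, so check the converse identity at scale 1: the
  ## reference has every contact at its minimum
  topo1 <- build_topology(cl, param_table = NULL, scale_factor = 1)
  e <- potential_energy(topo1, coords(cl))
  expect_equal(e$contact, -nrow(topo1$contacts), tolerance = 1e-9)
})

test_that("analytic forces agree with finite differences for every term", {
  set.seed(3)
  x <- coords(fx$dipeptide) + matrix(rnorm(33, 0, 0.01), 11, 3)
  expect_lt(max_force_error(build_topology(fx$dipeptide), x), 1e-5)
  cl <- random_cloud(505)
  set.seed(4)
  xc <- coords(cl) + matrix(rnorm(3 * n_atoms(cl), 0, 0.005), n_atoms(cl), 3)
  expect_lt(max_force_error(build_topology(cl, param_table = NULL), xc), 1e-5)
})

test_that("the reference with contacts at scaled minima is stationary", {
  ## native-centric terms only: the smooth excluded-volume background is
  ## switched off, bonded equilibria come from the reference geometry
  topo <- build_topology(ts_shell$expanded_reference, param_table = NULL,
                         scale_factor = 1, dihedral_contact_ratio = 0,
                         excluded_volume_strength = 0)
  f <- forces(topo, coords(ts_shell$expanded_reference))
  expect_lt(max(abs(f)), 1e-6)
})

test_that("exclusions cover bonded pairs and contacts", {
  topo <- build_topology(fx$dipeptide)
  ek <- paste(topo$exclusions[, 1], topo$exclusions[, 2])
  expect_true(all(paste(topo$bonds$i, topo$bonds$j) %in% ek))
  if (nrow(topo$contacts) > 0) {
    expect_true(all(paste(pmin(topo$contacts$i, topo$contacts$j),
                          pmax(topo$contacts$i, topo$contacts$j)) %in% ek))
  }
})

test_that("topology exports are written and carry the full term counts", {
  topo <- build_topology(fx$dipeptide)
  pj <- tempfile(fileext = ".json")
  export_topology_json(topo, pj)
  back <- jsonlite::fromJSON(pj)
  expect_equal(back$n_atoms, 11)
  expect_equal(length(back$bonds$i), nrow(topo$bonds))
  expect_equal(length(back$contacts$i), nrow(topo$contacts))

  pt <- tempfile(fileext = ".top")
  write_topology_gromacs(topo, pt)
  lines <- readLines(pt)
  expect_true(any(grepl("\\[ bonds \\]", lines)))
  expect_equal(sum(grepl("^\\s*\\d", lines[(which(grepl("\\[ bonds \\]", lines)) + 1):
                                             (which(grepl("\\[ angles \\]", lines)) - 1)])),
               nrow(topo$bonds))
})

test_that("gaussian contact form is available and keeps the minimum depth", {
  at <- data.frame(element = "C", atom_name = "CA", residue_index = 1L,
                   residue_name = "GLY", chain_id = c("A", "B"),
                   x = c(0, 0.45), y = 0, z = 0)
  s <- mol_structure(at)
  topo <- build_topology(s, param_table = NULL, scale_factor = 1,
                         contact_form = "gaussian")
  e <- potential_energy(topo, coords(s))
  ## -eps at the minimum plus the small r^-12 core
  expect_lt(abs(e$contact - (-1 + (0.25 / 0.45)^12)), 1e-9)
})
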