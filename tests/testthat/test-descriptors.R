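# The five descriptors and the per-loop lipophilicity profile.

test_that("the central residue of an extended tripeptide is fully exposed", {
  # use a scale whose sasa_max comes from the same builder/radii, so the
  # extended tripeptide is the maximal-exposure reference by construction
  tri <- build_extended_tripeptide("LEU")
  sr <- shrake_rupley(tri)
  sc <- default_lipo_scale()
  sc$sasa_max[sc$code == "LEU"] <- max_sidechain_sasa("LEU")
  rl <- residue_lipophilicity(tri, sc, sr)
  expect_equal(rl$exposure[2], 1, tolerance = 1e-6)
  expect_equal(rl$intensity[2], rl$normalized[2] * rl$exposure[2])
  expect_equal(rl$normalized[2], 0.19)
  # glycine flanks carry zero intensity
  expect_equal(rl$intensity[c(1, 3)], c(0, 0))
})

test_that("a buried residue has zero intensity regardless of scale value", {
  tri <- build_extended_tripeptide("TRP")
  rl <- residue_lipophilicity(tri, default_lipo_scale(),
                              rep(0, nrow(tri$atoms)))
  expect_equal(rl$intensity, rep(0, 3))
})

test_that("direction vectors are unit length where defined", {
  pep <- make_toy_peptide(seed = 6)
  rl <- residue_lipophilicity(pep, default_lipo_scale(), shrake_rupley(pep))
  nn <- sqrt(rl$ux^2 + rl$uy^2 + rl$uz^2)
  expect_equal(nn, rep(1, nrow(rl)), tolerance = 1e-9)
})

test_that("symmetric intensities cancel in the lipophilic moment", {
  rl <- data.frame(residue_index = 1:4, code = "LEU", normalized = 0.19,
                   exposure = 1, intensity = 0.19,
                   ux = c(1, -1, 0, 0), uy = c(0, 0, 1, -1), uz = 0)
  expect_equal(lipophilic_moment(rl), 0)
})

test_that("L_M is invariant under rotation of the structure", {
  pep <- make_toy_peptide(seed = 7)
  sc <- default_lipo_scale()
  sr <- shrake_rupley(pep)
  lm0 <- lipophilic_moment(residue_lipophilicity(pep, sc, sr))
  set.seed(31)
  rot <- rotate_peptide(pep, random_rotation())
  lm1 <- lipophilic_moment(residue_lipophilicity(rot, sc,
                                                 shrake_rupley(rot)))
  expect_equal(lm1, lm0, tolerance = 1e-9)
})

test_that("an all-lipophobic peptide has negative L_S and zero L_S*", {
  pep <- toy_sequence_peptide(rep("ASP", 8), cyclic = FALSE)
  rl <- residue_lipophilicity(pep, default_lipo_scale(), shrake_rupley(pep))
  expect_lt(total_lipophilicity(rl), 0)
  expect_equal(as.numeric(exclusive_lipophilicity(rl)), 0)
})

test_that("a single lipophilic residue gives L_S = L_S* = its intensity", {
  rl <- data.frame(residue_index = 1, code = "LEU", normalized = 0.19,
                   exposure = 0.8, intensity = 0.152,
                   ux = 1, uy = 0, uz = 0)
  expect_equal(total_lipophilicity(rl), 0.152)
  expect_equal(as.numeric(exclusive_lipophilicity(rl)), 0.152)
})

test_that("opposite-side lipophobic residues lower L_S but not L_S*", {
  # lipophilic cluster pointing into +z, lipophobic addition at the -z pole
  up <- data.frame(residue_index = 1:3, code = "LEU", normalized = 0.19,
                   exposure = 1, intensity = 0.19,
                   ux = c(0, 0.5, -0.5), uy = 0, uz = c(1, 0.866, 0.866))
  down <- data.frame(residue_index = 4, code = "ASP", normalized = -0.51,
                     exposure = 1, intensity = -0.51,
                     ux = 0, uy = 0, uz = -1)
  both <- rbind(up, down)
  expect_lt(total_lipophilicity(both), total_lipophilicity(up))
  expect_equal(as.numeric(exclusive_lipophilicity(both)),
               as.numeric(exclusive_lipophilicity(up)))
})

test_that("a vanishing resultant flags L_S* as degenerate", {
  rl <- data.frame(residue_index = 1:2, code = "LEU", normalized = 0.19,
                   exposure = 1, intensity = 0.19,
                   ux = c(1, -1), uy = 0, uz = 0)
  out <- exclusive_lipophilicity(rl)
  expect_true(isTRUE(attr(out, "degenerate")))
  expect_equal(as.numeric(out), 0.38)
})

test_that("E_S is zero without charges and grows with more of them", {
  none <- toy_sequence_peptide(rep("LEU", 6), cyclic = FALSE)
  expect_equal(hbd_surface_area(peptide_surface(none)$samples), 0)
  one <- make_toy_peptide(n_charged = 1, seed = 3)
  two <- make_toy_peptide(n_charged = 4, seed = 3)
  expect_gt(hbd_surface_area(peptide_surface(two)$samples),
            hbd_surface_area(peptide_surface(one)$samples))
})

test_that("uniform scaling quadruples E_S and doubles E_M", {
  pep <- make_toy_peptide(seed = 12)
  s1 <- peptide_surface(pep, probe = 1.4)
  pep2 <- pep
  pep2$atoms$x <- 2 * pep$atoms$x
  pep2$atoms$y <- 2 * pep$atoms$y
  pep2$atoms$z <- 2 * pep$atoms$z
  pep2$atoms$vdw <- 2 * pep$atoms$vdw
  pep2$center <- 2 * pep$center
  s2 <- peptide_surface(pep2, probe = 2.8)
  sc <- default_lipo_scale()
  expect_equal(hbd_surface_area(s2$samples),
               4 * hbd_surface_area(s1$samples), tolerance = 1e-6)
  expect_equal(hbd_amphipathic_moment(pep2, s2$samples, sc),
               2 * hbd_amphipathic_moment(pep, s1$samples, sc),
               tolerance = 1e-6)
})

test_that("E_M vanishes for a co-centered symmetric fixture", {
  # two +1 nitrogens and two lipophilic pseudo-atoms of the same radius,
  # all fully exposed and centered on the origin
  pep <- atoms_peptide(c("NZ", "NZ", "NX1", "NX1"), 1:4,
                       c("LYS", "LYS", "LEU", "LEU"),
                       rbind(c(10, 0, 0), c(-10, 0, 0),
                             c(0, 10, 0), c(0, -10, 0)))
  surf <- peptide_surface(pep)
  expect_equal(hbd_amphipathic_moment(pep, surf$samples,
                                      default_lipo_scale()),
               0, tolerance = 1e-6)
})

test_that("polar charge/hydrophobe separation reproduces the hand value", {
  # one +1 charge sphere at +z, one lipophilic sphere of equal radius at -z:
  # both sample clouds are full spheres centered on the atoms, so E_M is the
  # center separation, 20 Angstrom
  pep <- atoms_peptide(c("NZ", "NX1"), 1:2, c("LYS", "LEU"),
                       rbind(c(0, 0, 10), c(0, 0, -10)))
  surf <- peptide_surface(pep)
  expect_equal(hbd_amphipathic_moment(pep, surf$samples,
                                      default_lipo_scale()),
               20, tolerance = 0.05 * 20)
})

test_that("E_M is translation invariant", {
  pep <- make_toy_peptide(seed = 4)
  sc <- default_lipo_scale()
  e0 <- hbd_amphipathic_moment(pep, peptide_surface(pep)$samples, sc)
  mv <- translate_peptide(pep, c(100, -50, 25))
  e1 <- hbd_amphipathic_moment(mv, peptide_surface(mv)$samples, sc)
  expect_equal(e1, e0, tolerance = 1e-6)
})

test_that("loop profile partitions L_S minus the cysteine contributions", {
  codes <- c("CYS", "LEU", "TRP", "CYS", "SER", "CYS",
             "ASP", "CYS", "GLU", "CYS", "PHE", "CYS")
  pep <- assign_loops(toy_sequence_peptide(codes, cyclic = TRUE))
  sc <- default_lipo_scale()
  rl <- residue_lipophilicity(pep, sc, shrake_rupley(pep))
  prof <- loop_lipophilicity_profile(pep, rl)
  expect_named(prof, paste0("loop", 1:6))
  cys_sum <- sum(rl$intensity[rl$code == "CYS"])
  expect_equal(sum(prof), total_lipophilicity(rl) - cys_sum,
               tolerance = 1e-12)
})

test_that("an all-Gly loop contributes zero and a lipophilic loop peaks", {
  codes <- c("CYS", "GLY", "GLY", "CYS", "SER", "CYS",
             "ASP", "CYS", "GLU", "CYS", "TRP", "CYS")
  pep <- assign_loops(toy_sequence_peptide(codes, cyclic = TRUE))
  rl <- residue_lipophilicity(pep, default_lipo_scale(), shrake_rupley(pep))
  prof <- loop_lipophilicity_profile(pep, rl)
  # the all-Gly loop is the one holding both glycines
  gly_loop <- unique(pep$residues$loop_id[pep$residues$code == "GLY"])
  expect_equal(unname(prof[gly_loop]), 0)
  trp_loop <- pep$residues$loop_id[pep$residues$code == "TRP"]
  expect_equal(which.max(prof), trp_loop, ignore_attr = TRUE)
})

test_that("the loop profile requires assigned loops", {
  codes <- c("CYS", "LEU", "TRP", "CYS", "SER", "CYS",
             "ASP", "CYS", "GLU", "CYS", "PHE", "CYS")
  pep <- toy_sequence_peptide(codes, cyclic = TRUE)
  rl <- residue_lipophilicity(pep, default_lipo_scale(), shrake_rupley(pep))
  expect_error(loop_lipophilicity_profile(pep, rl), "assign_loops")
})

test_that("peptide_descriptors returns one tidy row, bit-reproducibly", {
  pep <- make_toy_peptide(seed = 1)
  d1 <- peptide_descriptors(pep)
  d2 <- peptide_descriptors(pep)
  expect_identical(d1, d2)
  expect_equal(names(d1), c("label", "L_S", "L_S_star", "L_M", "E_S", "E_M"))
  expect_true(all(c(d1$L_S_star, d1$L_M, d1$E_S, d1$E_M) >= 0))
})
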