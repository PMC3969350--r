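# Structure model, PDB I/O, loop annotation and RMSD.

test_that("new_peptide builds the atom and residue tables", {
  xyz <- matrix(c(0, 0, 0), 1, 3)
  pep <- atoms_peptide("N", 1L, "ALA", xyz)
  expect_s3_class(pep, "peptide")
  expect_equal(nrow(pep$residues), 1)
  expect_equal(pep$atoms$element, "N")
  expect_false(pep$atoms$is_sidechain)
  expect_equal(pep$center, c(x = 0, y = 0, z = 0), ignore_attr = TRUE)
})

test_that("new_peptide rejects empty and non-finite input", {
  expect_error(new_peptide(data.frame(name = character(0),
                                      resno = integer(0),
                                      code = character(0),
                                      x = numeric(0), y = numeric(0),
                                      z = numeric(0))),
               "empty structure")
  expect_error(atoms_peptide("CA", 1L, "ALA", matrix(c(NA, 0, 0), 1, 3)),
               "non-finite")
})

test_that("vdW radii follow the united-atom table", {
  tri <- build_extended_tripeptide("PHE")
  a <- tri$atoms
  expect_equal(unique(a$vdw[a$name == "CA"]), 1.87)   # aliphatic C
  expect_equal(unique(a$vdw[a$name == "C"]), 1.76)    # carbonyl C
  expect_equal(unique(a$vdw[a$name == "N"]), 1.65)
  expect_equal(unique(a$vdw[a$name == "O"]), 1.40)
  expect_equal(a$vdw[a$name == "CZ"], 1.76)           # aromatic C
  trc <- build_extended_tripeptide("CYS")
  expect_equal(trc$atoms$vdw[trc$atoms$name == "SG"], 1.85)
})

test_that("charge shares within a residue sum to its formal charge", {
  for (code in c("ARG", "LYS", "ASP", "GLU", "HIS")) {
    tri <- build_extended_tripeptide(code)
    mid <- tri$atoms$resno == 2
    expect_equal(sum(tri$atoms$charge_share[mid]),
                 tri$residues$formal_charge[2],
                 tolerance = 1e-12, label = code)
  }
  expect_equal(build_extended_tripeptide("ARG")$residues$formal_charge[2], 1)
  expect_equal(build_extended_tripeptide("GLU")$residues$formal_charge[2], -1)
  his <- build_extended_tripeptide("HIS")
  expect_equal(his$residues$formal_charge[2], his_protonated_fraction(),
               tolerance = 1e-12)
})

test_that("histidine protonated fraction follows Henderson-Hasselbalch", {
  expect_equal(round(his_protonated_fraction(7.4, 6.5), 3), 0.112)
  expect_equal(his_protonated_fraction(6.5, 6.5), 0.5)
  expect_gt(his_protonated_fraction(5, 6.5), 0.9)
})

test_that("a minimal one-residue PDB file parses with correct elements", {
  txt <- c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      12.560   6.351  -6.509  1.00  0.00           C",
    "ATOM      3  CB  ALA A   1      13.020   6.938  -7.845  1.00  0.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(txt, f)
  pep <- read_pdb(f)
  expect_equal(nrow(pep$residues), 1)
  expect_equal(pep$atoms$element, c("N", "C", "C"))
  expect_equal(pep$atoms$x[2], 12.560)
  expect_false(pep$cyclic)
})

test_that("PDB write/read round-trips coordinates to 1e-3", {
  tri <- build_extended_tripeptide("LYS")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(tri, f)
  back <- read_pdb(f)
  expect_equal(nrow(back$atoms), nrow(tri$atoms))
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(tri$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_error(read_pdb(file.path(tempdir(), "no_such_file.pdb")),
               "cannot read")
})

test_that("a 6-Cys fixture is recognized as such", {
  codes <- c("CYS", "ALA", "ALA", "CYS", "SER", "CYS",
             "ASP", "CYS", "GLU", "CYS", "PHE", "CYS")
  pep <- toy_sequence_peptide(codes, cyclic = TRUE)
  expect_equal(sum(pep$residues$code == "CYS"), 6)
  expect_true(pep$cyclic)
})

test_that("assign_loops reproduces the hand-enumerated cyclic example", {
  codes <- c("CYS", "ALA", "ALA", "CYS", "SER", "CYS",
             "ASP", "CYS", "GLU", "CYS", "PHE", "CYS")
  pep <- assign_loops(toy_sequence_peptide(codes, cyclic = TRUE))
  lid <- pep$residues$loop_id
  loop_codes <- function(k) sort(pep$residues$code[!is.na(lid) & lid == k])
  expect_equal(loop_codes(1), c("ALA", "ALA"))
  expect_equal(loop_codes(2), "SER")
  expect_equal(loop_codes(3), "ASP")
  expect_equal(loop_codes(4), "GLU")
  expect_equal(loop_codes(5), "PHE")
  expect_equal(loop_codes(6), character(0))
  expect_true(all(is.na(lid[pep$residues$code == "CYS"])))
})

test_that("assign_loops: all-Cys hexapeptide gives six empty loops", {
  pep <- assign_loops(toy_sequence_peptide(rep("CYS", 6), cyclic = TRUE))
  expect_true(all(is.na(pep$residues$loop_id)))
})

test_that("assign_loops splits loop 6 over the termini of a linear chain", {
  codes <- c("GLY", "CYS", "ALA", "CYS", "SER", "CYS",
             "ASP", "CYS", "GLU", "CYS", "PHE", "CYS", "THR")
  pep <- assign_loops(toy_sequence_peptide(codes, cyclic = FALSE))
  lid <- pep$residues$loop_id
  expect_equal(lid[1], 6L)                 # N-terminal open part
  expect_equal(lid[13], 6L)                # C-terminal open part
  expect_equal(lid[3], 1L)
  expect_equal(lid[11], 5L)
})

test_that("assign_loops errors without exactly 6 cysteines", {
  expect_error(assign_loops(toy_sequence_peptide(c("CYS", "ALA", "CYS"))),
               "6 Cys")
})

test_that("loop membership is invariant to cyclic rotation of input order", {
  codes <- c("CYS", "ALA", "ALA", "CYS", "SER", "CYS",
             "ASP", "CYS", "GLU", "CYS", "PHE", "CYS")
  ref <- assign_loops(toy_sequence_peptide(codes, cyclic = TRUE))
  ref_map <- split(ref$residues$code, ref$residues$loop_id)
  for (r in c(3, 5, 8)) {
    rot <- c(codes[r:length(codes)], codes[seq_len(r - 1)])
    got <- assign_loops(toy_sequence_peptide(rot, cyclic = TRUE))
    got_map <- split(got$residues$code, got$residues$loop_id)
    expect_equal(lapply(got_map, sort), lapply(ref_map, sort),
                 label = paste("rotation by", r))
  }
})

test_that("rmsd_ca handles identity, translation and symmetry", {
  set.seed(4)
  xyz <- matrix(rnorm(30, sd = 5), 10, 3)
  a <- atoms_peptide(rep("CA", 10), 1:10, rep("GLY", 10), xyz)
  expect_equal(rmsd_ca(a, a), 0)
  b <- translate_peptide(a, c(3, 4, 0))
  expect_equal(rmsd_ca(a, b), 5, tolerance = 1e-12)
  expect_equal(rmsd_ca(a, b, superpose = TRUE), 0, tolerance = 1e-9)
  expect_equal(rmsd_ca(a, b), rmsd_ca(b, a))
  expect_lte(rmsd_ca(a, b, superpose = TRUE), rmsd_ca(a, b))
})

test_that("superposed rmsd_ca matches the brute-force rotation oracle", {
  set.seed(11)
  xa <- matrix(rnorm(30, sd = 4), 10, 3)
  xb <- xa %*% t(random_rotation()) + matrix(rnorm(30, sd = 0.3), 10, 3)
  a <- atoms_peptide(rep("CA", 10), 1:10, rep("GLY", 10), xa)
  b <- atoms_peptide(rep("CA", 10), 1:10, rep("GLY", 10), xb)
  expect_equal(rmsd_ca(a, b, superpose = TRUE),
               oracle_superposed_rmsd(xa, xb), tolerance = 1e-3)
})

test_that("rmsd_ca rejects mismatched residue counts", {
  a <- atoms_peptide(rep("CA", 3), 1:3, rep("GLY", 3), diag(3))
  b <- atoms_peptide(rep("CA", 4), 1:4, rep("GLY", 4), rbind(diag(3), 1))
  expect_error(rmsd_ca(a, b), "mismatch")
})

test_that("the peptide center is translation-equivariant", {
  pep <- make_toy_peptide(seed = 5)
  t <- c(-2, 7, 1.5)
  expect_equal(translate_peptide(pep, t)$center, pep$center + t)
})

test_that("disulfides are detected from SG proximity", {
  xyz <- rbind(c(0, 0, 0), c(2.05, 0, 0), c(10, 0, 0))
  pep <- atoms_peptide(rep("SG", 3), 1:3, rep("CYS", 3), xyz)
  expect_equal(nrow(pep$disulfides), 1)
  expect_equal(as.integer(pep$disulfides[1, ]), c(1L, 2L))
})
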