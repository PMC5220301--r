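# Structure I/O, selections and rigid-body geometry.

pdb_fixture <- function(lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  path
}

test_that("read_structure parses a hand-written PDB and converts to nm", {
  path <- pdb_fixture(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.000   2.000   3.000  1.00  0.00           C",
    "ATOM      3  N   GLY A   2       4.500   2.000   3.000  1.00  0.00           N",
    "END"))
  st <- read_structure(path)
  expect_equal(n_atoms(st), 3)
  expect_equal(nrow(residue_table(st)), 2)
  expect_equal(coords(st)[1, ], c(0.1, 0.2, 0.3))
  expect_equal(st$atoms$element, c("N", "C", "N"))
})

test_that("read_structure handles MODELs, rejects malformed and empty files", {
  path <- pdb_fixture(c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1       0.000   0.000   1.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       3.800   0.000   1.000  1.00  0.00           C",
    "ENDMDL", "END"))
  st <- read_structure(path, frame_policy = "all")
  expect_equal(n_frames(st), 2)
  expect_equal(n_atoms(st), 2)
  expect_equal(coords(st, 2)[1, 3] - coords(st, 1)[1, 3], 0.1)
  st1 <- read_structure(path, frame_policy = "first")
  expect_equal(n_frames(st1), 1)

  bad <- pdb_fixture(c("ATOM      1  CA  ALA A   1       xxx"))
  expect_error(read_structure(bad), "malformed.*line 1")
  empty <- pdb_fixture(c("REMARK nothing here", "END"))
  expect_error(read_structure(empty), "no ATOM records")
})

test_that("alternate locations resolve to highest occupancy", {
  path <- pdb_fixture(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CB  ALA A   1       2.000   0.000   0.000  1.00  0.00           C",
    "END"))
  st <- read_structure(path)
  # brute-force expectation from the records: altLoc A has higher occupancy
  expect_equal(n_atoms(st), 2)
  expect_equal(coords(st)[st$atoms$name == "CA", 1], 0.1)
})

test_that("write_structure round-trips coordinates to PDB precision", {
  fx <- i1_dimer()
  path <- tempfile(fileext = ".pdb")
  write_structure(fx$dimer$structure, path)
  st2 <- read_structure(path)
  expect_equal(n_atoms(st2), n_atoms(fx$dimer$structure))
  # 0.001 A = 1e-4 nm
  expect_lt(max(abs(coords(st2) - coords(fx$dimer$structure))), 1e-4 + 1e-9)
})

test_that("selection mini-language matches keyword selection", {
  st <- i1_dimer()$dimer$structure
  s1 <- select_atoms(st, "chain A and resid 94-101 and name CA")
  s2 <- select_atoms(st, chain = "A", resid = 94:101, name = "CA")
  expect_identical(s1, s2)
  expect_equal(length(s1), 8)
  expect_error(select_atoms(st, "bogus A"), "unknown selection keyword")
  expect_error(structure_subset(st, integer(0)), "empty selection")
})

test_that("kabsch recovers planted rotations and is symmetric", {
  set.seed(42)
  A <- matrix(rnorm(45), 15, 3)
  expect_equal(kabsch_superpose(A, A)$rmsd, 0, tolerance = 1e-12)
  expect_equal(kabsch_superpose(A, A)$rotation, diag(3), tolerance = 1e-9)

  R90 <- rotation_about_axis(c(0, 0, 1), 90)
  B <- A %*% t(R90) + matrix(c(1, -2, 0.5), 15, 3, byrow = TRUE)
  tf <- kabsch_superpose(A, B)
  expect_equal(tf$rmsd, 0, tolerance = 1e-10)
  expect_equal(rotation_angle(tf$rotation), 90, tolerance = 1e-7)
  expect_equal(det(tf$rotation), 1, tolerance = 1e-10)

  # perturbed: rmsd equals the direct formula after applying the transform
  Bp <- B + matrix(rnorm(45, 0, 0.05), 15, 3)
  tf2 <- kabsch_superpose(A, Bp)
  aligned <- apply_transform(A, tf2)
  expect_equal(tf2$rmsd, sqrt(mean(rowSums((aligned - Bp)^2))),
               tolerance = 1e-12)
  # symmetry of the minimized rmsd
  expect_equal(tf2$rmsd, kabsch_superpose(Bp, A)$rmsd, tolerance = 1e-10)
})

test_that("kabsch rejects degenerate input", {
  expect_error(kabsch_superpose(matrix(rnorm(6), 2, 3),
                                matrix(rnorm(6), 2, 3)), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("center_of_mass handles weighting and errors", {
  st <- toy_structure(c("CA", "N", "O"), c("C", "N", "O"),
                      rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_equal(center_of_mass(st, sel = 1), c(0, 0, 0))
  # two equal-mass atoms at +-x
  st2 <- toy_structure(c("CA", "CB"), c("C", "C"),
                       rbind(c(-1, 0, 0), c(1, 0, 0)))
  expect_equal(center_of_mass(st2), c(0, 0, 0))
  # explicit arithmetic oracle with distinct masses
  m <- c(12.011, 14.007, 15.999)
  expected <- colSums(coords(st) * m) / sum(m)
  expect_equal(center_of_mass(st), expected, tolerance = 1e-12)
  expect_equal(center_of_mass(st, weighting = "geometric"),
               colMeans(coords(st)))
  expect_error(center_of_mass(st, sel = integer(0)), "empty")
})

test_that("geometric operations are invariant under global rigid motion", {
  fx <- i1_dimer()
  d <- fx$dimer
  R <- rotation_about_axis(c(1, 2, 3), 37)
  moved <- transform_structure(d$structure, R, c(1.5, -2, 0.7))
  dm <- dimer_model(moved, "A", "B")
  expect_equal(com_distance(dm), com_distance(d), tolerance = 1e-9)
  expect_equal(nrow(salt_bridges(dm)), nrow(salt_bridges(d)))
  expect_equal(hydrophobic_contacts(dm)$count, hydrophobic_contacts(d)$count)
  s1 <- shrake_rupley(d$structure, n_sphere_points = 240)
  s2 <- shrake_rupley(moved, n_sphere_points = 240)
  # identical lattice rotates with nothing; areas agree to sampling noise
  expect_equal(s2$total, s1$total, tolerance = 0.01)
})

test_that("secondary structure follows dihedral windows with run lengths", {
  helix <- build_peptide(rep("ALA", 10), phi = -57, psi = -47)
  expect_true(all(assign_secondary_structure(helix)$ss == "helix"))
  ext <- build_peptide(rep("ALA", 6), phi = 180, psi = 180)
  ss_ext <- assign_secondary_structure(ext)$ss
  expect_true(all(ss_ext %in% c("strand", "coil")))
  expect_false(any(ss_ext == "helix"))

  # helix-coil-helix segmentation matches the construction plan
  plan_ss <- c(rep("helix", 9), rep("coil", 8), rep("helix", 9))
  hch <- build_peptide(rep("ALA", 26),
                       phi = c(rep(-57, 9), rep(-70, 8), rep(-57, 9)),
                       psi = c(rep(-47, 9), rep(150, 8), rep(-47, 9)))
  expect_equal(assign_secondary_structure(hch)$ss, plan_ss)

  # user-supplied override wins
  ov <- data.frame(chain = "A", resid = 3, ss = "strand")
  expect_equal(assign_secondary_structure(helix, override = ov)$ss[3],
               "strand")

  # missing backbone -> coil with warning
  broken <- structure_subset(helix, which(!(helix$atoms$resid == 5 &
                                              helix$atoms$name == "CA")))
  expect_warning(ss_b <- assign_secondary_structure(broken), "coil")
  expect_equal(ss_b$ss[ss_b$resid == 5], "coil")
})

test_that("torsion angle matches known configurations", {
  # cis (0) and trans (180) butane-like chains
  p1 <- c(0, 1, 0); p2 <- c(0, 0, 0); p3 <- c(1, 0, 0)
  expect_equal(torsion_angle(p1, p2, p3, c(1, 1, 0)), 0)
  expect_equal(abs(torsion_angle(p1, p2, p3, c(1, -1, 0))), 180)
  expect_equal(abs(torsion_angle(p1, p2, p3, c(1, 0, 1))), 90)
})
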