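# Shrake-Rupley SASA against closed forms and an independent quadrature.

lone_carbons <- function(xyz) {
  toy_structure(rep("CB", nrow(xyz)), rep("C", nrow(xyz)), xyz,
                resid = seq_len(nrow(xyz)))
}

test_that("isolated sphere reproduces the closed form", {
  st <- lone_carbons(matrix(0, 1, 3))
  s <- shrake_rupley(st, probe_radius = 0.14, n_sphere_points = 960)
  expect_equal(s$total, 4 * pi * 0.31^2, tolerance = 1e-12)
  expect_equal(s$per_residue$area, s$total)
})

test_that("distant atoms do not occlude; close atoms match the two-sphere formula", {
  far <- shrake_rupley(lone_carbons(rbind(c(0, 0, 0), c(2, 0, 0))),
                       n_sphere_points = 960)
  expect_equal(far$total, 2 * 4 * pi * 0.31^2, tolerance = 1e-12)

  near <- shrake_rupley(lone_carbons(rbind(c(0, 0, 0), c(0.25, 0, 0))),
                        n_sphere_points = 960)
  exact <- oracle_two_sphere_area(0.31, 0.31, 0.25)
  expect_equal(near$per_atom, exact, tolerance = 0.01)
})

test_that("lattice refinement converges to the two-sphere form", {
  # error averaged over separations shrinks monotonically with density
  # (pointwise errors of an indicator quadrature oscillate)
  ds <- seq(0.15, 0.55, 0.05)
  mean_err <- vapply(c(240, 960, 3840), function(np) {
    mean(vapply(ds, function(d) {
      st <- lone_carbons(rbind(c(0, 0, 0), c(d, 0, 0)))
      exact <- sum(oracle_two_sphere_area(0.31, 0.31, d))
      abs(shrake_rupley(st, n_sphere_points = np)$total - exact)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_err) < 0))
  # and at 960 points a single configuration is within 1% of the closed form
  near <- shrake_rupley(lone_carbons(rbind(c(0, 0, 0), c(0.25, 0, 0))),
                        n_sphere_points = 960)
  exact <- sum(oracle_two_sphere_area(0.31, 0.31, 0.25))
  expect_lt(abs(near$total - exact) / exact, 0.01)
})

test_that("shrake_rupley validates its inputs", {
  st <- toy_structure("FE", "F", matrix(0, 1, 3))
  expect_error(shrake_rupley(st), "element")
  st2 <- lone_carbons(matrix(0, 1, 3))
  expect_error(shrake_rupley(st2, n_sphere_points = 30), ">= 60")
})

test_that("delta_sasa is zero for separated monomers and matches an independent quadrature in contact", {
  seqv <- setNames(rep("ALA", 10), 1:10)
  short_plan <- function(sep)
    helix_dimer_plan(sequence = seqv, separation = sep,
                     planted_bridges = list(), pi_stacks = list())
  apart <- build_helix_dimer(short_plan(10))$dimer
  expect_equal(delta_sasa(apart, n_sphere_points = 960)$delta_total, 0,
               tolerance = 1e-9)

  touch <- build_helix_dimer(short_plan(0.95))$dimer
  ds <- delta_sasa(touch, n_sphere_points = 3840)
  expect_gt(ds$delta_total, 0)

  xyz <- coords(touch$structure)
  radii <- vdw_radius(touch$structure$atoms$element)
  ia <- touch$sel_a; ib <- touch$sel_b
  oracle <- sum(oracle_sasa_latlong(xyz[ia, ], radii[ia], 0.14)) +
    sum(oracle_sasa_latlong(xyz[ib, ], radii[ib], 0.14)) -
    sum(oracle_sasa_latlong(xyz, radii, 0.14))
  expect_equal(ds$delta_total, oracle, tolerance = 0.02 * oracle)
})

test_that("delta_sasa is symmetric in the monomer labels", {
  fx <- i1_dimer()
  ds_ab <- delta_sasa(fx$dimer, n_sphere_points = 240)
  swapped <- dimer_model(fx$dimer$structure, "B", "A")
  ds_ba <- delta_sasa(swapped, n_sphere_points = 240)
  expect_equal(ds_ab$delta_total, ds_ba$delta_total, tolerance = 1e-9)
})

test_that("relative residue SASA classifies exposure with an inclusive threshold", {
  # a residue alone in its reference context scores ~1
  ref <- reference_max_sasa("LYS")
  tri <- build_peptide(c("GLY", "LYS", "GLY"), phi = 180, psi = 180)
  s <- shrake_rupley(tri)
  area <- s$per_residue$area[2]
  rel <- relative_residue_sasa("LYS", area)
  expect_equal(rel$rel_area, 1, tolerance = 1e-9)
  expect_true(rel$exposed)

  # boundary: exactly at the threshold counts as exposed (inclusive rule)
  expect_true(relative_residue_sasa("LYS", 0.25 * ref)$exposed)
  expect_false(relative_residue_sasa("LYS", 0.249 * ref)$exposed)
  expect_error(relative_residue_sasa("XXX", 1), "unknown residue")
})

test_that("a residue enclosed in an occluding shell is classified buried", {
  tri <- build_peptide(c("GLY", "ALA", "GLY"), phi = 180, psi = 180)
  mid <- select_atoms(tri, resid = 2)
  ctr <- colMeans(coords(tri)[mid, , drop = FALSE])
  # dense cage of carbons tight around the central residue: occluding
  # spheres must overlap the probe-expanded surface to bury it
  th <- seq(0.12, pi - 0.12, length.out = 16)
  pts <- do.call(rbind, lapply(th, function(t) {
    nph <- max(8, round(22 * sin(t)))
    ph <- seq(0, 2 * pi, length.out = nph + 1)[-1]
    cbind(ctr[1] + 0.5 * sin(t) * cos(ph), ctr[2] + 0.5 * sin(t) * sin(ph),
          ctr[3] + 0.5 * cos(t))
  }))
  cage <- toy_structure(rep("CB", nrow(pts)), rep("C", nrow(pts)), pts,
                        resid = 100 + seq_len(nrow(pts)), chain = "B")
  cage$atoms$serial <- cage$atoms$serial + n_atoms(tri)
  st <- dimerscope:::new_structure(rbind(tri$atoms, cage$atoms),
                                   list(rbind(coords(tri), pts)))
  expo <- residue_exposure(st, sel = select_atoms(st, chain = "A", resid = 2),
                           context = seq_len(n_atoms(st)))
  expect_lt(expo$rel_area, 0.05)
  expect_false(expo$exposed)
})

test_that("buried area floor: delta_sasa never goes negative on random rigid configurations", {
  # small random monomers, many geometries; occlusion can only remove area
  for (s in 1:25) {
    set.seed(s)
    xa <- matrix(runif(18, 0, 0.8), 6, 3)
    xb <- matrix(runif(18, 0, 0.8), 6, 3) +
      matrix(runif(3, -0.8, 0.8), 6, 3, byrow = TRUE)
    a <- lone_carbons(xa); b <- lone_carbons(xb)
    b$atoms$chain <- "B"; b$atoms$serial <- b$atoms$serial + 6
    st <- dimerscope:::new_structure(rbind(a$atoms, b$atoms),
                                     list(rbind(xa, xb)))
    d <- dimer_model(st, "A", "B")
    expect_gte(delta_sasa(d, n_sphere_points = 240)$delta_total, -1e-9)
  }
})
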