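# Pose RMSD, greedy-leader clustering with the 5% enrichment rule, and the
# three empirical viability filters.

base_pose <- function(R = diag(3), tvec = c(1.0, 0, 0)) {
  p <- helix_dimer_plan(include_loop = TRUE, anchor = TRUE,
                        planted_bridges = list(), pi_stacks = list())
  p$b_transform <- list(rotation = R, translation = tvec)
  build_helix_dimer(p)$dimer
}

test_that("pairwise pose RMSD handles duplicates, translations and label swaps", {
  p1 <- base_pose()
  p2 <- base_pose(tvec = c(2.0, 0, 0))
  ens <- pose_ensemble(list(p1, p1, p2))
  M <- pairwise_pose_rmsd(ens)
  expect_equal(M[1, 2], 0, tolerance = 1e-12)
  expect_equal(M[1, 3], 1.0, tolerance = 1e-9)
  expect_true(isSymmetric(M))

  # a label-swapped copy of the same physical dimer scores zero
  st <- p1$structure
  swapped <- dimer_model(st, "B", "A")
  M2 <- pairwise_pose_rmsd(pose_ensemble(list(p1, swapped)))
  expect_equal(M2[1, 2], 0, tolerance = 1e-9)
  expect_error(pairwise_pose_rmsd(pose_ensemble(list(p1))), "at least 2")
})

test_that("greedy-leader clustering recovers planted clusters and flags minors", {
  syn <- synth_pose_ensemble(pose_plan(n_poses = 100,
                                       cluster_fractions = c(0.40, 0.04),
                                       seed = 5))
  cl <- cluster_poses(pairwise_pose_rmsd(syn$ensemble))
  big <- cl$clusters[cl$clusters$size == 40, ]
  expect_equal(nrow(big), 1)
  expect_equal(big$enrichment, 0.40)
  expect_false(big$minor)
  small <- cl$clusters[cl$clusters$size == 4, ]
  expect_equal(nrow(small), 1)
  expect_true(small$minor)   # the 5% rule, applied to a 4% cluster
})

test_that("clustering is a partition with unit total enrichment", {
  syn <- pose_scenario()
  cl <- cluster_poses(syn$rmsd)
  expect_false(anyNA(cl$membership))
  expect_equal(length(cl$membership), 100)
  expect_equal(sum(cl$clusters$enrichment), 1, tolerance = 1e-12)
  expect_equal(sum(cl$clusters$size), 100)
  # identical poses collapse to one cluster with enrichment 1
  p <- base_pose()
  M0 <- matrix(0, 5, 5)
  cl0 <- cluster_poses(M0)
  expect_equal(nrow(cl0$clusters), 1)
  expect_equal(cl0$clusters$enrichment, 1.0)
  expect_error(cluster_poses(M0, radius = 0), "positive")
})

test_that("tightening the radius never merges clusters", {
  syn <- pose_scenario()
  n_wide <- nrow(cluster_poses(syn$rmsd, radius = 0.8)$clusters)
  n_tight <- nrow(cluster_poses(syn$rmsd, radius = 0.3)$clusters)
  expect_gte(n_tight, n_wide)
})

test_that("interface-composition filter distinguishes reactive and loop-only interfaces", {
  hot <- c(94, 95, 97, 98, 101, 102, 107)
  pass <- filter_interface_composition(base_pose(), hot,
                                       n_sphere_points = 240)
  expect_true(pass$pass)

  # contact away from every reactive residue: fails with the right reason
  p5 <- base_pose(rotation_about_axis(c(1, 0, 0), 180), c(1.0, 0, 4.35))
  f5 <- filter_interface_composition(p5, hot, n_sphere_points = 240)
  expect_false(f5$pass)
  expect_true(any(grepl("no reactive residue", f5$reasons)))

  # an all-coil contact is loop-only even when it touches a reactive id
  coil <- build_peptide(rep("ALA", 12), phi = -70, psi = 150, resid = 94:105)
  shifted <- coil
  shifted$atoms$chain <- "B"
  shifted$atoms$serial <- shifted$atoms$serial + n_atoms(coil)
  st <- dimerscope:::new_structure(
    rbind(coil$atoms, shifted$atoms),
    list(rbind(coords(coil),
               sweep(coords(coil), 2, c(0.55, 0, 0), "+"))))
  fl <- filter_interface_composition(dimer_model(st, "A", "B"), hot,
                                     n_sphere_points = 240)
  expect_false(fl$pass)
  expect_true(any(grepl("loop-only", fl$reasons)))
})

test_that("effector-exposure filter requires both protomers exposed", {
  ok <- filter_effector_exposure(base_pose(), 25:40, n_sphere_points = 240)
  expect_true(ok$pass)
  expect_true(all(ok$exposure > 0.5))

  # bury monomer A's loop under a cage of carbons attached to monomer B
  pose <- base_pose()
  st <- pose$structure
  loop_sel <- select_atoms(st, chain = "A", resid = 25:40)
  lx <- coords(st)[loop_sel, , drop = FALSE]
  set.seed(2)
  cage <- do.call(rbind, lapply(seq_len(nrow(lx)), function(i)
    sweep(matrix(rnorm(3 * 12, 0, 0.28), 12, 3), 2, lx[i, ], "+")))
  cage_atoms <- data.frame(serial = max(st$atoms$serial) + seq_len(nrow(cage)),
                           name = "CB", resname = "ALA", chain = "B",
                           resid = 900, element = "C", occ = 1,
                           stringsAsFactors = FALSE)
  st2 <- dimerscope:::new_structure(rbind(st$atoms, cage_atoms),
                                    list(rbind(coords(st), cage)))
  buried <- filter_effector_exposure(dimer_model(st2, "A", "B"), 25:40,
                                     n_sphere_points = 240)
  expect_false(buried$pass)
  expect_lt(buried$exposure["A"], 0.25)
  # one protomer buried is enough to fail (B stayed exposed)
  expect_gt(buried$exposure["B"], 0.25)
  expect_error(filter_effector_exposure(base_pose(), 500:510), "outside")
})

test_that("membrane-competence filter checks anchor half-space and exposure", {
  ok <- filter_membrane_competence(base_pose(), 140, n_sphere_points = 240)
  expect_true(ok$pass)
  expect_gt(prod(ok$side), 0)

  flipped <- base_pose(rotation_about_axis(c(1, 0, 0), 180), c(1.0, 0, 0))
  bad <- filter_membrane_competence(flipped, 140, n_sphere_points = 240)
  expect_false(bad$pass)
  expect_lt(prod(bad$side), 0)
  expect_true(any(grepl("opposite faces", bad$reasons)))
  expect_error(filter_membrane_competence(base_pose(), 999), "missing")
})

test_that("the six-cluster scenario yields exactly four survivors", {
  syn <- pose_scenario()
  cl <- cluster_poses(syn$rmsd)
  audit <- apply_filters(cl, syn$ensemble, hotspots = syn$truth$hotspots,
                         effector_loop = syn$truth$effector_loop,
                         anchor_resid = syn$truth$anchor_resid)
  expect_equal(length(audit$survivors), 4)
  expect_equal(sum(!audit$audit$minor), 6)
  failed <- audit$audit[!audit$audit$minor & !audit$audit$survived, ]
  expect_equal(nrow(failed), 2)
  expect_true(any(grepl("no reactive residue", failed$reasons)))
  expect_true(any(grepl("opposite faces", failed$reasons)))
  # audit covers every cluster with a verdict or a minor annotation
  expect_equal(nrow(audit$audit), nrow(cl$clusters))
})

test_that("degenerate filter inputs behave cleanly", {
  empty <- apply_filters(cluster_poses(matrix(0, 2, 2)),
                         pose_ensemble(list()), hotspots = 1)
  expect_equal(nrow(empty$audit), 0)
  expect_equal(length(empty$survivors), 0)

  # all clusters minor -> zero survivors with a warning
  syn <- pose_scenario()
  cl <- cluster_poses(syn$rmsd, min_enrichment = 1.01)
  expect_warning(
    aud <- apply_filters(cl, syn$ensemble, hotspots = syn$truth$hotspots,
                         effector_loop = syn$truth$effector_loop,
                         anchor_resid = syn$truth$anchor_resid),
    "minor")
  expect_equal(length(aud$survivors), 0)
})

test_that("minor clusters can be promoted for evaluation", {
  syn <- pose_scenario()
  cl <- cluster_poses(syn$rmsd)
  minor_id <- cl$clusters$cluster[cl$clusters$size == 4]
  audit <- apply_filters(cl, syn$ensemble, hotspots = syn$truth$hotspots,
                         effector_loop = syn$truth$effector_loop,
                         anchor_resid = syn$truth$anchor_resid,
                         promote = minor_id)
  # the promoted 4% cluster is a viable parallel placement: now 5 survivors
  expect_equal(length(audit$survivors), 5)
  expect_true(minor_id %in% audit$survivors)
})
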