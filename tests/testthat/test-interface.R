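# Interface descriptors: hydrogen bonds, hydrophobic contacts, d_COM,
# relative orientation, salt bridges, pi-stacking, quasi-symmetry, series
# summaries.

hb_fixture <- function(d_no, deviation_deg) {
  # N-H...O with chosen N-O distance and deviation from linearity at H
  th <- deviation_deg * pi / 180
  h <- c(0.1, 0, 0)
  o <- h + (d_no - 0.1) * c(cos(th), sin(th), 0)
  a <- toy_structure(c("N", "H"), c("N", "H"), rbind(c(0, 0, 0), h),
                     resid = 1, resname = "ALA", chain = "A")
  b <- toy_structure("O", "O", rbind(o), resid = 2, resname = "ALA",
                     chain = "B")
  b$atoms$serial <- 3
  st <- dimerscope:::new_structure(rbind(a$atoms, b$atoms),
                                   list(rbind(coords(a), coords(b))))
  dimer_model(st, "A", "B")
}

test_that("hydrogen bonds obey both distance and angle cutoffs", {
  expect_equal(nrow(hydrogen_bonds(hb_fixture(0.29, 5))), 1)
  expect_equal(nrow(hydrogen_bonds(hb_fixture(0.31, 5))), 0)
  expect_equal(nrow(hydrogen_bonds(hb_fixture(0.29, 25))), 0)
  # with hydrogens present the result is not flagged as fallback
  expect_false(hydrogen_bonds(hb_fixture(0.29, 5))$fallback)
})

test_that("heavy-atom fallback applies when hydrogens are absent and is flagged", {
  a <- toy_structure("N", "N", rbind(c(0, 0, 0)), resid = 1, chain = "A")
  b <- toy_structure("O", "O", rbind(c(0.29, 0, 0)), resid = 2, chain = "B")
  b$atoms$serial <- 2
  st <- dimerscope:::new_structure(rbind(a$atoms, b$atoms),
                                   list(rbind(coords(a), coords(b))))
  hb <- hydrogen_bonds(dimer_model(st, "A", "B"))
  expect_equal(nrow(hb), 1)
  expect_true(hb$fallback)
})

test_that("hydrophobic contacts: boundary cases and brute-force agreement", {
  two_c <- function(d) {
    a <- toy_structure("CB", "C", rbind(c(0, 0, 0)), resid = 1, chain = "A")
    b <- toy_structure("CB", "C", rbind(c(d, 0, 0)), resid = 2, chain = "B")
    b$atoms$serial <- 2
    st <- dimerscope:::new_structure(rbind(a$atoms, b$atoms),
                                     list(rbind(coords(a), coords(b))))
    dimer_model(st, "A", "B")
  }
  expect_equal(hydrophobic_contacts(two_c(0.37))$count, 1L)
  expect_equal(hydrophobic_contacts(two_c(0.39))$count, 0L)

  for (s in 1:10) {
    d <- random_toy_dimer(s)
    expect_equal(hydrophobic_contacts(d)$count, oracle_hc_count(d))
  }
})

test_that("HB and HC counts are monotone as cutoffs tighten", {
  d <- random_toy_dimer(99)
  hcs <- vapply(c(0.30, 0.38, 0.45), function(ct)
    hydrophobic_contacts(d, d_cut = ct)$count, integer(1))
  expect_true(all(diff(hcs) >= 0))
  hbs <- vapply(c(0.25, 0.30, 0.35), function(ct)
    nrow(hydrogen_bonds(d, d_cut = ct)), integer(1))
  expect_true(all(diff(hbs) >= 0))
})

test_that("com_distance matches construction and explicit arithmetic", {
  pa <- build_helix_dimer(helix_dimer_plan(sequence = "polyala",
                                           separation = 3.5))$dimer
  expect_equal(com_distance(pa), 3.5, tolerance = 1e-9)

  a <- toy_structure(c("CA", "N", "O"), c("C", "N", "O"),
                     rbind(c(0, 0, 0), c(0.2, 0, 0), c(0, 0.3, 0)),
                     resid = 1, chain = "A")
  b <- toy_structure(c("CA", "N", "O"), c("C", "N", "O"),
                     rbind(c(1, 0, 0), c(1.2, 0, 0), c(1, 0.3, 0)),
                     resid = 2, chain = "B")
  b$atoms$serial <- 4:6
  st <- dimerscope:::new_structure(rbind(a$atoms, b$atoms),
                                   list(rbind(coords(a), coords(b))))
  m <- atomic_mass(c("C", "N", "O"))
  coma <- colSums(coords(a) * m) / sum(m)
  comb <- colSums(coords(b) * m) / sum(m)
  expect_equal(com_distance(dimer_model(st, "A", "B")),
               sqrt(sum((coma - comb)^2)), tolerance = 1e-12)
  # superposed monomers
  st0 <- dimerscope:::new_structure(rbind(a$atoms, b$atoms),
                                    list(rbind(coords(a), coords(a))))
  expect_equal(com_distance(dimer_model(st0, "A", "B")), 0)
})

test_that("relative orientation equals the axis-angle of the planted rotation", {
  ref <- build_helix_dimer(helix_dimer_plan(sequence = "polyala"))$dimer
  expect_equal(relative_orientation(ref, ref), 0, tolerance = 1e-9)

  rot70 <- build_helix_dimer(helix_dimer_plan(sequence = "polyala",
    b_transform = list(rotation = rotation_about_axis(c(0, 0, 1), 70),
                       translation = c(1.2, 0, 0))))$dimer
  expect_equal(relative_orientation(rot70, ref), 70, tolerance = 1e-6)

  # random rotation about the helix axis: equals acos((tr(R) - 1) / 2)
  set.seed(5)
  ang <- runif(1, 10, 170)
  R <- rotation_about_axis(c(0, 0, 1), ang)
  d <- build_helix_dimer(helix_dimer_plan(sequence = "polyala",
    b_transform = list(rotation = R, translation = c(1.3, 0, 0))))$dimer
  oracle <- acos((sum(diag(R)) - 1) / 2) * 180 / pi
  expect_equal(relative_orientation(d, ref), oracle, tolerance = 1e-6)
  expect_error(relative_orientation(
    dimer_model(structure_subset(ref$structure,
                                 which(ref$structure$atoms$resid > 90)),
                "A", "B"), ref), "topolog")
})

test_that("salt bridges recover exactly the planted set and respect the cutoff", {
  fx <- i1_dimer()
  sb <- salt_bridges(fx$dimer)
  found <- sort(paste(sb$basic_chain, sb$basic_resid, sb$acidic_chain,
                      sb$acidic_resid))
  expect_equal(found, sort(c("A 101 B 107", "B 97 A 98")))
  expect_equal(sort(unique(sb$type)), c("K->E", "R->E"))
  expect_equal(sb$distance, rep(0.32, 2), tolerance = 1e-9)

  # pulled apart beyond the cutoff: absent
  wide <- build_helix_dimer(helix_dimer_plan(bridge_distance = 0.45))
  expect_equal(nrow(salt_bridges(wide$dimer)), 0)

  # brute-force set equality on random multi-group toy dimers
  for (s in 1:10) {
    d <- random_toy_dimer(s)
    sb <- salt_bridges(d)
    got <- sort(paste(sb$basic_chain, sb$basic_resid, sb$acidic_chain,
                      sb$acidic_resid))
    expect_equal(got, oracle_salt_pairs(d))
  }
})

test_that("pi stacking classifies geometry and respects the centroid cutoff", {
  par <- build_helix_dimer(helix_dimer_plan(
    pi_stacks = list(list(a = 94, b = 137))))
  ps <- pi_stacking(par$dimer)
  expect_equal(nrow(ps), 1)
  expect_equal(ps$centroid_distance, 0.40, tolerance = 1e-9)
  expect_equal(ps$class, "parallel")

  perp <- build_helix_dimer(helix_dimer_plan(
    pi_stacks = list(list(a = 94, b = 137, angle = 90)), stack_gap = 0.50))
  ps2 <- pi_stacking(perp$dimer)
  expect_equal(ps2$class, "t-shaped")
  expect_equal(ps2$normal_angle, 90, tolerance = 1e-6)

  farr <- build_helix_dimer(helix_dimer_plan(
    pi_stacks = list(list(a = 94, b = 137)), stack_gap = 0.70))
  expect_equal(nrow(pi_stacking(farr$dimer)), 0)
})

test_that("quasi-symmetry scores set overlap and rejects heterodimers", {
  c2 <- build_helix_dimer(helix_dimer_plan(sequence = "polyala",
    b_transform = list(rotation = rotation_about_axis(c(0, 0, 1), 180),
                       translation = c(1.0, 0, 0))))$dimer
  expect_equal(quasi_symmetry_score(c2, n_sphere_points = 240), 1)
  # partially overlapping sets: |{94}| / |{94,95,101,107}|
  expect_equal(quasi_symmetry_score(c2, interface_a = c(94, 95, 101),
                                    interface_b = c(94, 107)), 0.25)
  # disjoint interfaces score zero
  p5 <- build_helix_dimer(helix_dimer_plan(sequence = "polyala",
    b_transform = list(rotation = rotation_about_axis(c(1, 0, 0), 180),
                       translation = c(1.0, 0, 4.35))))$dimer
  expect_equal(quasi_symmetry_score(p5, n_sphere_points = 240), 0)

  het <- c2
  het$structure$atoms$resname[het$structure$atoms$chain == "B" &
                                het$structure$atoms$resid == 90] <- "GLY"
  expect_error(quasi_symmetry_score(dimer_model(het$structure, "A", "B")),
               "homodimer")
})

test_that("ensemble summaries: running averages and moments", {
  const <- ensemble_summary(rep(3.5, 20), window = 5)
  expect_equal(const$running, rep(3.5, 20))
  alt <- ensemble_summary(rep(0:1, 5), window = 2)
  expect_equal(alt$running[1:9], rep(0.5, 9))
  set.seed(11)
  v <- rnorm(50)
  es <- ensemble_summary(v, window = 7)
  expect_equal(es$mean, mean(v))
  expect_equal(es$sd, sd(v))
  expect_warning(ensemble_summary(1:3, window = 10), "window larger")
})

test_that("interface_report aggregates the five descriptors over frames", {
  fx <- i1_dimer()
  d <- fx$dimer
  # two-frame ensemble: frame 2 slightly shifted
  st <- d$structure
  st$xyz <- list(st$xyz[[1]], st$xyz[[1]])
  selb <- select_atoms(st, chain = "B")
  st$xyz[[2]][selb, 1] <- st$xyz[[2]][selb, 1] + 0.05
  rep2 <- interface_report(dimer_model(st, "A", "B"), n_sphere_points = 240)
  expect_equal(nrow(rep2$per_frame), 2)
  expect_equal(rep2$per_frame$delta[1], 0)
  expect_equal(rep2$per_frame$d_com[2] - rep2$per_frame$d_com[1], 0.05,
               tolerance = 1e-3)
  expect_equal(nrow(rep2$salt_bridges), 2)
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_interface_report(rep2, tsv, js)
  expect_true(file.exists(tsv) && file.exists(js))
  expect_equal(nrow(read.table(tsv, header = TRUE)), 2)
})
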