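# Shared fixtures and independent oracles. Oracles are deliberately naive
# (double loops, closed forms, alternative quadratures) and never reuse the
# package's fast paths.

# memoised expensive fixtures
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

i1_dimer <- function() cached("i1", build_helix_dimer(helix_dimer_plan()))

pose_scenario <- function() cached("poses", {
  syn <- synth_pose_ensemble(pose_plan(n_poses = 100, seed = 2))
  syn$rmsd <- pairwise_pose_rmsd(syn$ensemble)
  syn
})

# minimal structure from raw atom specs
toy_structure <- function(names, elements, xyz, resid = seq_along(names),
                          resname = "UNK", chain = "A") {
  atoms <- data.frame(serial = seq_along(names), name = names,
                      resname = rep_len(resname, length(names)),
                      chain = rep_len(chain, length(names)),
                      resid = rep_len(resid, length(names)),
                      element = elements, occ = 1, stringsAsFactors = FALSE)
  dimerscope:::new_structure(atoms, list(as.matrix(xyz)))
}

# random toy dimer: one atom per residue, names drawn so that donors,
# acceptors, carbons and charged groups all occur; monomers overlap in space
random_toy_dimer <- function(seed, n_per_monomer = 25, box = 1.2) {
  set.seed(seed)
  pool <- data.frame(
    name = c("CB", "CA", "C", "N", "O", "NZ", "OE1", "NH1", "OD2", "SG"),
    resname = c("ALA", "ALA", "ALA", "ALA", "ALA", "LYS", "GLU", "ARG",
                "ASP", "CYS"), stringsAsFactors = FALSE)
  build <- function(chain, offset) {
    pick <- sample(nrow(pool), n_per_monomer, replace = TRUE)
    toy_structure(pool$name[pick], element_from_name(pool$name[pick]),
                  cbind(runif(n_per_monomer, 0, box) + offset,
                        runif(n_per_monomer, 0, box),
                        runif(n_per_monomer, 0, box)),
                  resid = seq_len(n_per_monomer),
                  resname = pool$resname[pick], chain = chain)
  }
  a <- build("A", 0); b <- build("B", box * 0.25)
  b$atoms$serial <- b$atoms$serial + n_per_monomer
  st <- dimerscope:::new_structure(rbind(a$atoms, b$atoms),
                                   list(rbind(a$xyz[[1]], b$xyz[[1]])))
  dimer_model(st, "A", "B")
}

# ---- brute-force detectors (O(N^2) double loops) ----------------------------

oracle_hc_count <- function(dimer, d_cut = 0.38) {
  st <- dimer$structure; a <- st$atoms; xyz <- coords(st)
  ca <- dimer$sel_a[a$element[dimer$sel_a] == "C"]
  cb <- dimer$sel_b[a$element[dimer$sel_b] == "C"]
  n <- 0
  for (i in ca) {
    hit <- FALSE
    for (j in cb)
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= d_cut) { hit <- TRUE; break }
    if (hit) n <- n + 1
  }
  n
}

oracle_hb_pairs <- function(dimer, d_cut = 0.30) {
  # heavy-atom fallback rule (no hydrogens in the toy dimers)
  st <- dimer$structure; a <- st$atoms; xyz <- coords(st)
  don <- dimerscope:::DONOR_NAMES; acc <- dimerscope:::ACCEPTOR_NAMES
  out <- character(0)
  for (dir in list(c("a", "b"), c("b", "a"))) {
    sd <- if (dir[1] == "a") dimer$sel_a else dimer$sel_b
    sa <- if (dir[2] == "a") dimer$sel_a else dimer$sel_b
    for (i in sd[a$name[sd] %in% don & a$element[sd] != "H"])
      for (j in sa[a$name[sa] %in% acc])
        if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= d_cut)
          out <- c(out, paste(i, j))
  }
  sort(unique(out))
}

oracle_salt_pairs <- function(dimer, d_cut = 0.4) {
  st <- dimer$structure; a <- st$atoms; xyz <- coords(st)
  basic <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"))
  acidic <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  in_group <- function(i, tab)
    !is.null(tab[[a$resname[i]]]) && a$name[i] %in% tab[[a$resname[i]]]
  out <- character(0)
  for (dir in list(list(dimer$sel_a, dimer$sel_b),
                   list(dimer$sel_b, dimer$sel_a))) {
    for (i in dir[[1]]) {
      if (!in_group(i, basic)) next
      for (j in dir[[2]]) {
        if (!in_group(j, acidic)) next
        if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= d_cut)
          out <- c(out, paste(a$chain[i], a$resid[i], a$chain[j], a$resid[j]))
      }
    }
  }
  sort(unique(out))
}

# ---- SASA oracles -----------------------------------------------------------

# exact exposed area of two intersecting spheres (expanded radii R1, R2)
oracle_two_sphere_area <- function(R1, R2, d) {
  if (d >= R1 + R2) return(c(4 * pi * R1^2, 4 * pi * R2^2))
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
  x2 <- d - x1
  c(4 * pi * R1^2 - 2 * pi * R1 * (R1 - x1),
    4 * pi * R2^2 - 2 * pi * R2 * (R2 - x2))
}

# independent quadrature: latitude-longitude grid with cos-weighted bands
oracle_sasa_latlong <- function(xyz, radii, probe, n_lat = 180) {
  n <- nrow(xyz)
  th <- (seq_len(n_lat) - 0.5) * pi / n_lat     # polar angle band centres
  areas <- numeric(n)
  for (i in seq_len(n)) {
    R <- radii[i] + probe
    nb <- which(sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2)) <
                  (radii + probe) + R & seq_len(n) != i)
    band_area <- 2 * pi * R^2 * sin(th) * (pi / n_lat)
    tot <- 0
    for (k in seq_len(n_lat)) {
      n_lon <- max(8, round(2 * n_lat * sin(th[k])))
      ph <- (seq_len(n_lon) - 0.5) * 2 * pi / n_lon
      pts <- cbind(xyz[i, 1] + R * sin(th[k]) * cos(ph),
                   xyz[i, 2] + R * sin(th[k]) * sin(ph),
                   xyz[i, 3] + R * cos(th[k]))
      expo <- rep(TRUE, n_lon)
      for (j in nb) {
        Rj2 <- (radii[j] + probe)^2
        expo <- expo & (rowSums(sweep(pts, 2, xyz[j, ])^2) >= Rj2)
      }
      tot <- tot + band_area[k] * mean(expo)
    }
    areas[i] <- tot
  }
  areas
}
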