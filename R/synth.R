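# Synthetic-data generators with known ground truth: ideal helical homodimers
# with planted salt bridges / pi-stacks, alignments with planted covarying
# columns, mean-force profiles of known well depth (hence known Kd), and
# docked-pose ensembles with planted clusters. Every generator is a pure
# function of its plan (seeded), so outputs are byte-identical on repeat.

# ---- ideal peptide geometry (NeRF internal -> cartesian) --------------------

BOND_N_CA <- 0.1458; BOND_CA_C <- 0.1525; BOND_C_N <- 0.1329
BOND_C_O <- 0.1231; BOND_CA_CB <- 0.1530
ANG_N_CA_C <- 111.2; ANG_CA_C_N <- 116.2; ANG_C_N_CA <- 121.7
ANG_CA_C_O <- 120.8

unit3 <- function(v) v / sqrt(sum(v^2))
cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# place atom D given A-B-C, bond |CD|, angle B-C-D and torsion A-B-C-D
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- unit3(c - b)
  n <- unit3(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# CB from backbone (tetrahedral, fixed handedness; chirality is immaterial
# for the synthetic fixtures)
place_cb <- function(n, ca, c) {
  u1 <- unit3(n - ca); u2 <- unit3(c - ca)
  bis <- unit3(u1 + u2); nrm <- unit3(cross3(u1, u2))
  ca + BOND_CA_CB * unit3(-0.618 * bis + 0.786 * nrm)
}

# Approximate heavy-atom side-chain topologies built as stubs off CB: linear
# chain atoms 0.15 nm apart, terminal branch pairs, and planar rings. These
# give each residue type a realistic amount of surface without rotamer
# libraries; orientation is set by `direction`.
SIDECHAIN_SPEC <- list(
  ALA = list(), GLY = list(),
  SER = list(chain = "OG"), CYS = list(chain = "SG"),
  THR = list(chain = "OG1", branch = "CG2"),
  VAL = list(branch = c("CG1", "CG2")),
  LEU = list(chain = "CG", branch = c("CD1", "CD2")),
  ILE = list(chain = c("CG1", "CD1"), branch = "CG2"),
  MET = list(chain = c("CG", "SD", "CE")),
  PRO = list(chain = c("CG", "CD")),
  ASN = list(chain = "CG", branch = c("OD1", "ND2")),
  GLN = list(chain = c("CG", "CD"), branch = c("OE1", "NE2")),
  LYS = list(chain = c("CG", "CD", "CE", "NZ")),
  ARG = list(chain = c("CG", "CD", "NE", "CZ"), branch = c("NH1", "NH2")),
  ASP = list(chain = "CG", branch = c("OD1", "OD2")),
  GLU = list(chain = c("CG", "CD"), branch = c("OE1", "OE2")),
  HIS = list(ring = c("CG", "ND1", "CD2", "CE1", "NE2"), ring_radius = 0.113),
  PHE = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
             ring_radius = 0.139),
  TYR = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
             ring_radius = 0.139, apex = "OH", apex_bond = 0.136),
  TRP = list(ring = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3",
                      "CH2"), ring_radius = 0.190)
)

sidechain_atoms <- function(resname) {
  sp <- SIDECHAIN_SPEC[[resname]]
  if (is.null(sp)) stop("unknown residue name: ", resname)
  c(sp$chain, sp$branch, sp$ring, sp$apex)
}

# positions of side-chain atoms beyond CB, extending from CB along `dir`
sidechain_coords <- function(resname, cb, dir, perp) {
  sp <- SIDECHAIN_SPEC[[resname]]
  if (is.null(sp)) stop("unknown residue name: ", resname)
  pos <- list(); base <- cb
  step <- 0.15
  for (nm in sp$chain) {
    base <- base + step * dir
    pos[[nm]] <- base
  }
  if (!is.null(sp$branch)) {
    sgn <- c(1, -1)
    for (k in seq_along(sp$branch))
      pos[[sp$branch[k]]] <- base +
        0.124 * (0.5 * dir + sgn[k] * 0.866 * perp)
  }
  if (!is.null(sp$ring)) {
    R <- sp$ring_radius
    center <- base + (step + R) * dir
    nv <- length(sp$ring)
    for (k in seq_len(nv)) {
      th <- pi + (k - 1) * 2 * pi / nv   # vertex 1 (CG) nearest CB
      pos[[sp$ring[k]]] <- center + R * (cos(th) * dir + sin(th) * perp)
    }
    if (!is.null(sp$apex)) pos[[sp$apex]] <- center + (R + sp$apex_bond) * dir
  }
  if (length(pos) == 0) return(NULL)
  do.call(rbind, pos)
}

#' Build an ideal peptide from backbone dihedrals
#'
#' Constructs heavy-atom coordinates (N, CA, C, O, CB and approximate
#' side-chain stubs) for a chain with the given per-residue phi/psi, using
#' standard bond lengths and angles and trans peptide bonds. An ideal
#' alpha-helix corresponds to phi = -57, psi = -47.
#'
#' @param resnames character vector of 3-letter residue codes.
#' @param phi,psi backbone dihedrals in degrees (recycled to length).
#' @param chain chain id.
#' @param resid author residue numbers (default 1..n).
#' @param sidechains build side-chain stubs beyond CB.
#' @return a `Structure`.
#' @export
build_peptide <- function(resnames, phi = -57, psi = -47, chain = "A",
                          resid = seq_along(resnames), sidechains = TRUE) {
  n <- length(resnames)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  N <- CA <- C <- vector("list", n)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(BOND_N_CA, 0, 0)
  th <- ANG_N_CA_C * pi / 180
  C[[1]] <- CA[[1]] + BOND_CA_C * c(-cos(th), sin(th), 0)
  for (i in seq_len(n - 1)) {
    N[[i + 1]] <- nerf_place(N[[i]], CA[[i]], C[[i]], BOND_C_N, ANG_CA_C_N,
                             psi[i])
    CA[[i + 1]] <- nerf_place(CA[[i]], C[[i]], N[[i + 1]], BOND_N_CA,
                              ANG_C_N_CA, 180)
    C[[i + 1]] <- nerf_place(C[[i]], N[[i + 1]], CA[[i + 1]], BOND_CA_C,
                             ANG_N_CA_C, phi[i + 1])
  }
  names_out <- character(0); res_out <- integer(0); resn_out <- character(0)
  xyz_out <- list()
  push <- function(nm, rs, rn, p) {
    names_out <<- c(names_out, nm); res_out <<- c(res_out, rs)
    resn_out <<- c(resn_out, rn); xyz_out[[length(xyz_out) + 1]] <<- p
  }
  for (i in seq_len(n)) {
    rn <- resnames[i]
    push("N", resid[i], rn, N[[i]])
    push("CA", resid[i], rn, CA[[i]])
    push("C", resid[i], rn, C[[i]])
    push("O", resid[i], rn,
         nerf_place(N[[i]], CA[[i]], C[[i]], BOND_C_O, ANG_CA_C_O,
                    psi[i] + 180))
    if (rn != "GLY") {
      cb <- place_cb(N[[i]], CA[[i]], C[[i]])
      push("CB", resid[i], rn, cb)
      if (sidechains && length(sidechain_atoms(rn)) > 0) {
        dir <- unit3(cb - CA[[i]])
        perp <- unit3(cross3(dir, unit3(CA[[i]] - N[[i]])))
        sc <- sidechain_coords(rn, cb, dir, perp)
        for (k in seq_len(nrow(sc)))
          push(rownames(sc)[k], resid[i], rn, sc[k, ])
      }
    }
  }
  atoms <- data.frame(serial = seq_along(names_out), name = names_out,
                      resname = resn_out, chain = chain, resid = res_out,
                      element = element_from_name(names_out), occ = 1,
                      stringsAsFactors = FALSE)
  new_structure(atoms, list(do.call(rbind, xyz_out)))
}

#' Fitted axis of a helix (or any roughly linear selection)
#'
#' First principal axis of the C-alpha coordinates, oriented from the first
#' to the last residue.
#'
#' @param structure a `Structure`.
#' @param sel atom indices (C-alphas are extracted from them).
#' @param frame frame index.
#' @return unit length-3 vector.
#' @export
helix_axis <- function(structure, sel = NULL, frame = 1) {
  if (is.null(sel)) sel <- seq_len(n_atoms(structure))
  ca <- sel[structure$atoms$name[sel] == "CA"]
  if (length(ca) < 3) stop("need at least 3 C-alpha atoms")
  xyz <- coords(structure, frame)[ca, , drop = FALSE]
  ax <- prcomp(xyz, center = TRUE)$rotation[, 1]
  if (sum((xyz[nrow(xyz), ] - xyz[1, ]) * ax) < 0) ax <- -ax
  unit3(ax)
}

# rotate/translate so the CA principal axis of `axis_sel` is +z, centred at
# the selection's CA centroid, with the N-terminus at low z
align_axis_z <- function(st, axis_sel) {
  ax <- helix_axis(st, axis_sel)
  v <- cross3(ax, c(0, 0, 1)); s <- sqrt(sum(v^2)); cth <- ax[3]
  R <- if (s < 1e-12) {
    if (cth > 0) diag(3) else diag(c(1, -1, -1))
  } else {
    rotation_about_axis(v, atan2(s, cth) * 180 / pi)
  }
  ca <- axis_sel[st$atoms$name[axis_sel] == "CA"]
  ctr <- colMeans(coords(st)[ca, , drop = FALSE])
  st <- transform_structure(st, translation = -ctr)
  # row-vector convention: x %*% t(R) applies R
  st$xyz <- lapply(st$xyz, function(m) m %*% t(R))
  st
}

# ---- helix homodimer with planted interactions ------------------------------

BRIDGE_TERMINAL <- c(LYS = "NZ", ARG = "NH1", HIS = "NE2",
                     GLU = "OE1", ASP = "OD1")

default_i1_sequence <- function() {
  res <- 86:137
  rn <- rep("ALA", length(res))
  names(rn) <- res
  rn[as.character(c(94, 95))] <- "HIS"
  rn[as.character(c(97, 102))] <- "ARG"
  rn[as.character(c(98, 107))] <- "GLU"
  rn[as.character(101)] <- "LYS"
  rn[as.character(137)] <- "TYR"
  rn
}

#' Plan for a synthetic helical homodimer
#'
#' Defines the fixture geometry: two ideal alpha-helices at a given axis
#' separation and crossing angle, with salt bridges and/or pi-stacks planted
#' at named residue positions. The default sequence mimics an i1-like
#' interface: a 52-residue helix numbered 86-137 carrying His94/His95,
#' Arg97, Glu98, Lys101, Arg102, Glu107 and Tyr137, with Lys101(A)-Glu107(B)
#' and Glu98(A)-Arg97(B) bridges planted.
#'
#' @param separation helix-axis separation in nm.
#' @param crossing_angle inter-axis angle in degrees (rotation of monomer B
#'   about the separation axis).
#' @param sequence named character vector (names = author residue ids) of
#'   3-letter codes, or `"i1"` / `"polyala"`.
#' @param planted_bridges list of `list(a = <resid on A>, b = <resid on B>)`.
#' @param pi_stacks list of `list(a =, b =, angle =)` ring plants (angle =
#'   inter-normal angle in degrees, 0 = parallel).
#' @param bridge_distance planted donor-acceptor heavy-atom distance (nm).
#' @param stack_gap planted ring-centroid distance (nm).
#' @param include_loop prepend a 16-residue coil tail numbered 25-40
#'   (a stand-in effector-binding loop).
#' @param anchor append a schematic exposed C-terminal anchor residue
#'   (id 140) offset along +y (a stand-in lipid-anchor attachment site).
#' @param b_transform optional `list(rotation, translation)` placing monomer
#'   B explicitly (overrides separation/crossing_angle).
#' @param seed RNG seed (only used by downstream jittering).
#' @return plan list (class `helix_dimer_plan`).
#' @export
helix_dimer_plan <- function(separation = 1.0, crossing_angle = 0,
                             sequence = "i1",
                             planted_bridges = list(list(a = 101, b = 107),
                                                    list(a = 98, b = 97)),
                             pi_stacks = list(),
                             bridge_distance = 0.32, stack_gap = 0.40,
                             include_loop = FALSE, anchor = FALSE,
                             b_transform = NULL, seed = 1) {
  if (identical(sequence, "i1")) sequence <- default_i1_sequence()
  if (identical(sequence, "polyala")) {
    sequence <- setNames(rep("ALA", 52), 86:137)
    planted_bridges <- list(); pi_stacks <- list()
  }
  structure(list(separation = separation, crossing_angle = crossing_angle,
                 sequence = sequence, planted_bridges = planted_bridges,
                 pi_stacks = pi_stacks, bridge_distance = bridge_distance,
                 stack_gap = stack_gap, include_loop = include_loop,
                 anchor = anchor, b_transform = b_transform, seed = seed),
            class = "helix_dimer_plan")
}

# rebuild the side chain of one residue from CB along `dir`
redirect_sidechain <- function(st, ch, rs, dir) {
  a <- st$atoms
  i_cb <- which(a$chain == ch & a$resid == rs & a$name == "CB")
  i_ca <- which(a$chain == ch & a$resid == rs & a$name == "CA")
  if (length(i_cb) == 0) return(st)
  rn <- a$resname[i_cb]
  scn <- sidechain_atoms(rn)
  if (length(scn) == 0) return(st)
  xyz <- st$xyz[[1]]
  cb <- xyz[i_cb, ]
  dir <- unit3(dir)
  ref <- unit3(xyz[i_ca, ] - cb)
  pv <- cross3(dir, ref)
  if (sqrt(sum(pv^2)) < 1e-6) pv <- cross3(dir, c(0, 0, 1))
  perp <- unit3(pv)
  sc <- sidechain_coords(rn, cb, dir, perp)
  for (k in seq_len(nrow(sc))) {
    j <- which(a$chain == ch & a$resid == rs & a$name == rownames(sc)[k])
    xyz[j, ] <- sc[k, ]
  }
  st$xyz[[1]] <- xyz
  st
}

# stretch a charged side chain so its terminal heavy atom sits at `target`
plant_terminal <- function(st, ch, rs, target) {
  a <- st$atoms
  i_cb <- which(a$chain == ch & a$resid == rs & a$name == "CB")
  rn <- a$resname[i_cb]
  term <- BRIDGE_TERMINAL[[rn]]
  if (is.null(term)) stop("residue ", rn, " has no bridge terminal atom")
  sp <- SIDECHAIN_SPEC[[rn]]
  xyz <- st$xyz[[1]]
  cb <- xyz[i_cb, ]
  u <- unit3(target - cb)
  pv <- cross3(u, c(0, 0, 1))
  if (sqrt(sum(pv^2)) < 1e-6) pv <- cross3(u, c(0, 1, 0))
  perp <- unit3(pv)
  set_pos <- function(nm, p) {
    j <- which(a$chain == ch & a$resid == rs & a$name == nm)
    xyz[j, ] <<- p
  }
  if (!is.null(sp$ring)) {
    # ring residue (protonated His): centre the ring so `term` hits target
    R <- sp$ring_radius
    center <- target - R * (cos(pi) * u)   # place terminal vertex at target
    nv <- length(sp$ring)
    k_term <- match(term, sp$ring)
    th0 <- pi + (k_term - 1) * 2 * pi / nv
    center <- target - R * (cos(th0) * u + sin(th0) * perp)
    for (k in seq_len(nv)) {
      th <- pi + (k - 1) * 2 * pi / nv
      set_pos(sp$ring[k], center + R * (cos(th) * u + sin(th) * perp))
    }
  } else {
    chain_atoms <- sp$chain
    is_branch_term <- !is.null(sp$branch) && term %in% sp$branch
    if (is_branch_term) {
      # terminal is one of a branch pair hanging off the last chain atom
      m <- length(chain_atoms)
      for (k in seq_len(m))
        set_pos(chain_atoms[k], cb + (target - cb) * k / (m + 1))
      base <- cb + (target - cb) * m / (m + 1)
      set_pos(term, target)
      other <- setdiff(sp$branch, term)
      if (length(other))
        set_pos(other, base + 0.124 * (0.5 * u - 0.866 * perp))
    } else {
      # terminal is the last chain atom (e.g. Lys NZ)
      m <- length(chain_atoms)
      for (k in seq_len(m))
        set_pos(chain_atoms[k], cb + (target - cb) * k / m)
      if (!is.null(sp$branch))
        for (bn in sp$branch)
          set_pos(bn, target + 0.124 * (0.5 * u + 0.866 * perp))
    }
  }
  st$xyz[[1]] <- xyz
  st
}

# place an aromatic ring with a given centroid and normal
plant_ring <- function(st, ch, rs, center, normal, perp_hint = c(1, 0, 0)) {
  a <- st$atoms
  i_cb <- which(a$chain == ch & a$resid == rs & a$name == "CB")
  rn <- a$resname[i_cb]
  sp <- SIDECHAIN_SPEC[[rn]]
  if (is.null(sp$ring)) stop("residue ", rn, " is not aromatic")
  normal <- unit3(normal)
  e1 <- perp_hint - sum(perp_hint * normal) * normal
  if (sqrt(sum(e1^2)) < 1e-6) e1 <- cross3(normal, c(0, 1, 0))
  e1 <- unit3(e1); e2 <- cross3(normal, e1)
  xyz <- st$xyz[[1]]
  nv <- length(sp$ring); R <- sp$ring_radius
  for (k in seq_len(nv)) {
    th <- (k - 1) * 2 * pi / nv
    j <- which(a$chain == ch & a$resid == rs & a$name == sp$ring[k])
    xyz[j, ] <- center + R * (cos(th) * e1 + sin(th) * e2)
  }
  if (!is.null(sp$apex)) {
    j <- which(a$chain == ch & a$resid == rs & a$name == sp$apex)
    xyz[j, ] <- center + (R + sp$apex_bond) * e1
  }
  st$xyz[[1]] <- xyz
  st
}

#' Build a synthetic helical homodimer with planted interactions
#'
#' Constructs two ideal alpha-helices (3.6 residues/turn via phi = -57,
#' psi = -47; 0.15 nm rise) at the planned separation and crossing angle.
#' Monomer B is a rigid copy of A. Side chains of charged/aromatic residues
#' not involved in a planted contact are rebuilt pointing away from the
#' partner monomer; planted salt-bridge side chains are stretched so the two
#' charged terminal heavy atoms sit `bridge_distance` apart at the interface
#' midline, and planted pi-stacks get explicitly oriented rings.
#'
#' @param plan a [helix_dimer_plan()].
#' @return list with `dimer` (a `DimerModel`) and `truth` (ground-truth
#'   annotation: planted bridges/stacks, per-residue secondary structure,
#'   geometry parameters).
#' @export
build_helix_dimer <- function(plan) {
  stopifnot(inherits(plan, "helix_dimer_plan"))
  seq_rn <- plan$sequence
  res_ids <- as.integer(names(seq_rn))
  resnames <- unname(seq_rn)
  planted_ids <- c(unlist(lapply(plan$planted_bridges, unlist)),
                   vapply(plan$pi_stacks, function(p) c(p$a, p$b),
                          numeric(2)))
  if (length(planted_ids) && !all(planted_ids %in% as.integer(names(seq_rn))))
    stop("planted residue id(s) not present in the sequence")
  phi <- rep(-57, length(res_ids)); psi <- rep(-47, length(res_ids))
  loop_ids <- integer(0)
  if (plan$include_loop) {
    loop_ids <- 25:40
    res_ids <- c(loop_ids, res_ids)
    resnames <- c(rep("ALA", length(loop_ids)), resnames)
    phi <- c(rep(-70, length(loop_ids)), phi)
    psi <- c(rep(150, length(loop_ids)), psi)
  }
  monoA <- build_peptide(resnames, phi, psi, chain = "A", resid = res_ids)
  helix_sel <- select_atoms(monoA, resid = as.integer(names(seq_rn)))
  monoA <- align_axis_z(monoA, helix_sel)
  if (plan$include_loop) {
    # swing the coil tail to extend straight below the helix (-z) so pose
    # placements around the helix cannot collide with a meandering tail
    a <- monoA$atoms
    loop_sel <- which(a$resid %in% loop_ids)
    xyz <- monoA$xyz[[1]]
    pivot <- xyz[which(a$resid == loop_ids[length(loop_ids)] &
                         a$name == "CA"), ]
    tip <- xyz[which(a$resid == loop_ids[1] & a$name == "CA"), ]
    v <- unit3(tip - pivot)
    axv <- cross3(v, c(0, 0, -1))
    if (sqrt(sum(axv^2)) > 1e-9) {
      Rl <- rotation_about_axis(axv, acos(max(-1, min(1, -v[3]))) * 180 / pi)
      xyz[loop_sel, ] <- sweep(sweep(xyz[loop_sel, , drop = FALSE], 2, pivot) %*%
                                 t(Rl), 2, pivot, "+")
      monoA$xyz[[1]] <- xyz
    }
  }

  if (plan$anchor) {
    # schematic exposed anchor-attachment residue offset along +y from the
    # C-terminal CA
    a <- monoA$atoms
    last_res <- res_ids[length(res_ids)]
    i_last <- which(a$resid == last_res & a$name %in% c("N", "CA", "C", "O",
                                                        "CB"))
    anc_xyz <- monoA$xyz[[1]][i_last, , drop = FALSE] +
      matrix(c(0, 0.8, 0.1), nrow = length(i_last), ncol = 3, byrow = TRUE)
    anc_atoms <- a[i_last, , drop = FALSE]
    anc_atoms$resid <- 140L; anc_atoms$resname <- "ALA"
    anc_atoms$serial <- max(a$serial) + seq_len(nrow(anc_atoms))
    monoA <- new_structure(rbind(a, anc_atoms),
                           list(rbind(monoA$xyz[[1]], anc_xyz)))
  }

  # monomer B: rigid copy
  if (is.null(plan$b_transform)) {
    R <- rotation_about_axis(c(1, 0, 0), plan$crossing_angle)
    tvec <- c(plan$separation, 0, 0)
  } else {
    R <- plan$b_transform$rotation
    tvec <- plan$b_transform$translation
  }
  atomsB <- monoA$atoms
  atomsB$chain <- "B"
  atomsB$serial <- max(monoA$atoms$serial) + seq_len(nrow(atomsB))
  xyzB <- monoA$xyz[[1]] %*% t(R) +
    matrix(tvec, nrow = nrow(atomsB), ncol = 3, byrow = TRUE)
  st <- new_structure(rbind(monoA$atoms, atomsB),
                      list(rbind(monoA$xyz[[1]], xyzB)))

  planted_res <- list(A = integer(0), B = integer(0))
  for (br in plan$planted_bridges) {
    planted_res$A <- c(planted_res$A, br$a)
    planted_res$B <- c(planted_res$B, br$b)
  }
  for (ps in plan$pi_stacks) {
    planted_res$A <- c(planted_res$A, ps$a)
    planted_res$B <- c(planted_res$B, ps$b)
  }

  # point uninvolved long side chains away from the partner monomer so the
  # only engineered inter-monomer contacts are the planted ones
  comA <- center_of_mass(st, select_atoms(st, chain = "A"))
  comB <- center_of_mass(st, select_atoms(st, chain = "B"))
  busy <- c("LYS", "ARG", "GLU", "ASP", "GLN", "ASN", "MET", "HIS", "TYR",
            "PHE", "TRP")
  for (ch in c("A", "B")) {
    away <- if (ch == "A") unit3(comA - comB) else unit3(comB - comA)
    rt <- residue_table(st)
    rt <- rt[rt$chain == ch & rt$resname %in% busy, ]
    for (k in seq_len(nrow(rt))) {
      if (rt$resid[k] %in% planted_res[[ch]]) next
      st <- redirect_sidechain(st, ch, rt$resid[k], away)
    }
  }

  # anchor the planted-contact midline on the CA positions (near the helix
  # axes) so the planted atoms sit between the monomers, not inside one
  ca_of <- function(ch, rs) {
    st$xyz[[1]][which(st$atoms$chain == ch & st$atoms$resid == rs &
                        st$atoms$name == "CA"), ]
  }
  truth_bridges <- list()
  for (br in plan$planted_bridges) {
    cba <- ca_of("A", br$a); cbb <- ca_of("B", br$b)
    u <- unit3(cbb - cba); m <- (cba + cbb) / 2
    st <- plant_terminal(st, "A", br$a, m - (plan$bridge_distance / 2) * u)
    st <- plant_terminal(st, "B", br$b, m + (plan$bridge_distance / 2) * u)
    rtab <- residue_table(st)
    truth_bridges[[length(truth_bridges) + 1]] <-
      list(a = br$a, b = br$b,
           type_a = rtab$resname[rtab$chain == "A" & rtab$resid == br$a],
           type_b = rtab$resname[rtab$chain == "B" & rtab$resid == br$b],
           distance = plan$bridge_distance)
  }
  truth_stacks <- list()
  for (ps in plan$pi_stacks) {
    ang <- if (is.null(ps$angle)) 0 else ps$angle
    cba <- ca_of("A", ps$a); cbb <- ca_of("B", ps$b)
    u <- unit3(cbb - cba); m <- (cba + cbb) / 2
    nB <- rotation_about_axis(cross3(u, c(0, 0, 1)), ang) %*% u
    st <- plant_ring(st, "A", ps$a, m - (plan$stack_gap / 2) * u, u)
    st <- plant_ring(st, "B", ps$b, m + (plan$stack_gap / 2) * u,
                     as.numeric(nB))
    truth_stacks[[length(truth_stacks) + 1]] <-
      list(a = ps$a, b = ps$b, angle = ang, gap = plan$stack_gap)
  }

  selA <- select_atoms(st, chain = "A"); selB <- select_atoms(st, chain = "B")
  xyz <- st$xyz[[1]]
  dmin <- min_intermonomer_distance(xyz, selA, selB)
  if (dmin < 0.2)
    stop(sprintf("infeasible geometry: inter-monomer clash at %.3f nm", dmin))

  truth <- list(
    planted_bridges = truth_bridges, pi_stacks = truth_stacks,
    separation = plan$separation, crossing_angle = plan$crossing_angle,
    loop_resids = loop_ids, anchor_resid = if (plan$anchor) 140L else NULL,
    helix_resids = as.integer(names(seq_rn)),
    ss = data.frame(resid = res_ids,
                    ss = c(rep("coil", length(loop_ids)),
                           rep("helix", length(seq_rn))),
                    stringsAsFactors = FALSE))
  list(dimer = dimer_model(st, "A", "B", provenance = "synthetic helix dimer"),
       truth = truth)
}

min_intermonomer_distance <- function(xyz, selA, selB) {
  # blocked to bound memory on large systems
  best <- Inf
  bs <- 2000
  for (i0 in seq(1, length(selA), by = bs)) {
    ia <- selA[i0:min(i0 + bs - 1, length(selA))]
    d2 <- outer(rowSums(xyz[ia, , drop = FALSE]^2),
                rowSums(xyz[selB, , drop = FALSE]^2), "+") -
      2 * xyz[ia, , drop = FALSE] %*% t(xyz[selB, , drop = FALSE])
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0))
}

# ---- synthetic MSA ----------------------------------------------------------

# Robinson-Robinson style background amino-acid frequencies
AA_BACKGROUND <- c(A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019,
                   Q = 0.043, E = 0.063, G = 0.074, H = 0.022, I = 0.051,
                   L = 0.091, K = 0.057, M = 0.022, F = 0.039, P = 0.052,
                   S = 0.071, T = 0.058, W = 0.013, Y = 0.032, V = 0.065)

#' Plan for a synthetic multiple sequence alignment
#'
#' Background columns are i.i.d. draws from a documented amino-acid
#' frequency vector; planted column pairs are drawn jointly from a two-state
#' coupled distribution: with probability `coupling` the pair takes one of
#' the two coupled state combinations (E with K, or D with R), otherwise the
#' two columns draw their two states independently.
#'
#' @param n_seq number of sequences.
#' @param n_col alignment length.
#' @param planted_pairs list of length-2 integer vectors (column pairs).
#' @param coupling coupling strength in \[0, 1\].
#' @param seed RNG seed.
#' @return plan list (class `msa_plan`).
#' @export
msa_plan <- function(n_seq = 500, n_col = 60,
                     planted_pairs = list(c(10, 35)), coupling = 0.9,
                     seed = 1) {
  structure(list(n_seq = n_seq, n_col = n_col, planted_pairs = planted_pairs,
                 coupling = coupling, seed = seed), class = "msa_plan")
}

#' Generate a synthetic MSA with planted covarying column pairs
#' @param plan an [msa_plan()].
#' @return list with `msa` (an `MSA`) and `truth` (planted pairs, coupling).
#' @export
synth_msa <- function(plan) {
  stopifnot(inherits(plan, "msa_plan"))
  with_seed(plan$seed, {
    aln <- matrix(sample(names(AA_BACKGROUND), plan$n_seq * plan$n_col,
                         replace = TRUE, prob = AA_BACKGROUND),
                  nrow = plan$n_seq, ncol = plan$n_col)
    states <- matrix(c("E", "K", "D", "R"), nrow = 2, byrow = TRUE)
    for (pp in plan$planted_pairs) {
      coupled <- runif(plan$n_seq) < plan$coupling
      joint <- sample(1:2, plan$n_seq, replace = TRUE)
      ind_i <- sample(1:2, plan$n_seq, replace = TRUE)
      ind_j <- sample(1:2, plan$n_seq, replace = TRUE)
      si <- ifelse(coupled, joint, ind_i)
      sj <- ifelse(coupled, joint, ind_j)
      aln[, pp[1]] <- states[si, 1]
      aln[, pp[2]] <- states[sj, 2]
    }
    rownames(aln) <- sprintf("seq%04d", seq_len(plan$n_seq))
    list(msa = new_msa(aln),
         truth = list(planted_pairs = plan$planted_pairs,
                      coupling = plan$coupling))
  })
}

# ---- synthetic mean-force profile -------------------------------------------

#' Plan for a synthetic mean-force profile
#'
#' The underlying free-energy profile is a Gaussian well
#' `W(r) = -depth * exp(-(r - center)^2 / (2 width^2))`; the mean force
#' `F = -dW/dr` is sampled on a grid with i.i.d. Gaussian noise of standard
#' deviation `noise_sd` (the reported per-point standard error).
#'
#' @param depth well depth, kcal/mol.
#' @param center well position (nm).
#' @param width Gaussian width (nm).
#' @param r_min,r_max,dr grid (nm).
#' @param noise_sd force noise / standard error, kcal/(mol nm).
#' @param temperature K.
#' @param seed RNG seed.
#' @return plan list (class `pmf_plan`).
#' @export
pmf_plan <- function(depth = 3.0, center = 3.6, width = 0.15,
                     r_min = 2.6, r_max = 6.0, dr = 0.02,
                     noise_sd = 0, temperature = 300, seed = 1) {
  structure(list(depth = depth, center = center, width = width,
                 r_min = r_min, r_max = r_max, dr = dr, noise_sd = noise_sd,
                 temperature = temperature, seed = seed), class = "pmf_plan")
}

pmf_analytic_w <- function(plan) {
  function(r) -plan$depth * exp(-(r - plan$center)^2 / (2 * plan$width^2))
}

pmf_analytic_f <- function(plan) {
  function(r) -plan$depth * (r - plan$center) / plan$width^2 *
    exp(-(r - plan$center)^2 / (2 * plan$width^2))
}

#' Generate a synthetic mean-force profile of known true Kd
#'
#' @param plan a [pmf_plan()].
#' @param reference_from start of the flat reference window (nm).
#' @return list with `profile` (a `MeanForceProfile`), `truth` (analytic
#'   `W(r)`, true Kd/deltaG under the package's standard-state convention
#'   evaluated by adaptive quadrature on the analytic profile, bound window
#'   used).
#' @export
synth_mean_force <- function(plan, reference_from = 4.6) {
  stopifnot(inherits(plan, "pmf_plan"))
  r <- seq(plan$r_min, plan$r_max, by = plan$dr)
  Wfun <- pmf_analytic_w(plan)
  Ffun <- pmf_analytic_f(plan)
  F <- Ffun(r)
  s <- rep(plan$noise_sd, length(r))
  if (plan$noise_sd > 0)
    F <- with_seed(plan$seed, F + rnorm(length(r), 0, plan$noise_sd))
  prof <- mean_force_profile(r, F, s)

  # true Kd: same windowing convention as kd_from_pmf, on the analytic W
  bw <- bound_window_from_w(r, Wfun(r), plan$temperature)
  RT <- GAS_CONSTANT_KCAL * plan$temperature
  integrand <- function(x) 4 * pi * x^2 * exp(-Wfun(x) / RT)
  vol <- integrate(integrand, bw[1], bw[2], rel.tol = 1e-10)$value
  ka <- vol / STANDARD_STATE_VOLUME_NM3
  kd <- 1 / ka
  list(profile = prof,
       truth = list(W = Wfun, F = Ffun, kd = kd,
                    dg = dg_from_kd(kd, plan$temperature),
                    bound_window = bw, temperature = plan$temperature))
}

#' Find the well depth giving a target true Kd
#'
#' Bisection (via [stats::uniroot]) on the plan's depth so the analytic
#' profile's standard-state Kd equals `target_kd`.
#'
#' @param target_kd molar.
#' @param plan a [pmf_plan()] (its depth field is ignored).
#' @param interval depth search interval, kcal/mol.
#' @return the calibrated depth (kcal/mol).
#' @export
depth_for_kd <- function(target_kd, plan = pmf_plan(),
                         interval = c(1e-3, 15)) {
  f <- function(d) {
    p <- plan; p$depth <- d; p$noise_sd <- 0
    log(synth_mean_force(p)$truth$kd) - log(target_kd)
  }
  uniroot(f, interval, tol = 1e-10)$root
}

# ---- synthetic docked-pose ensemble -----------------------------------------

rot180x <- function() rotation_about_axis(c(1, 0, 0), 180)

#' Plan for a synthetic docked-pose ensemble
#'
#' Poses are rigid placements of monomer B around a fixed monomer A (built
#' once from a [helix_dimer_plan()] with loop tail and anchor residue).
#' Placements marked `fails` are designed to violate a viability filter:
#' `"reactive"` (interface avoids all hotspot residues) or `"membrane"`
#' (anchor residues end up on opposite faces). Cluster members are jittered
#' rigid perturbations of the placement; the remainder of the ensemble is
#' scattered uniformly.
#'
#' @param n_poses ensemble size.
#' @param cluster_fractions fraction of poses per planted cluster.
#' @param jitter_sd rigid-jitter scale (nm translation sd; degrees rotation
#'   sd is `jitter_sd * 40`).
#' @param placements optional list of `list(rotation, translation, fails)`;
#'   the default set contains four viable placements, one hotspot-avoiding
#'   antiparallel placement and one anchor-flipped antiparallel placement,
#'   mirroring a six-cluster docking outcome of which two fail the filters.
#' @param seed RNG seed.
#' @return plan list (class `pose_plan`).
#' @export
pose_plan <- function(n_poses = 100,
                      cluster_fractions = c(0.20, 0.16, 0.14, 0.12,
                                            0.10, 0.08, 0.04),
                      jitter_sd = 0.03, placements = NULL, seed = 1) {
  if (is.null(placements)) {
    I3 <- diag(3)
    placements <- list(
      list(rotation = I3, translation = c(1.0, 0, 0), fails = "none"),
      list(rotation = I3, translation = c(1.0, 0, 2.0), fails = "none"),
      list(rotation = I3, translation = c(1.0, 0, -2.0), fails = "none"),
      list(rotation = I3, translation = c(0.8, 0.8, 0), fails = "none"),
      list(rotation = rot180x(), translation = c(1.0, 0, 4.35),
           fails = "reactive"),
      list(rotation = rot180x(), translation = c(1.0, 0, 0),
           fails = "membrane"),
      list(rotation = I3, translation = c(1.0, 0, 4.35), fails = "none"))
  }
  if (length(cluster_fractions) > length(placements))
    stop("more cluster fractions than placements")
  if (sum(cluster_fractions) > 1) stop("cluster fractions must sum to <= 1")
  structure(list(n_poses = n_poses, cluster_fractions = cluster_fractions,
                 jitter_sd = jitter_sd, placements = placements, seed = seed),
            class = "pose_plan")
}

random_rotation <- function(max_angle = 180) {
  ax <- rnorm(3)
  rotation_about_axis(ax, runif(1, 0, max_angle))
}

#' Generate a synthetic docked-pose ensemble with planted clusters
#'
#' @param plan a [pose_plan()].
#' @return list with `ensemble` (a `PoseEnsemble`), `truth` (planted
#'   membership per pose, 0 = scatter; per-cluster designed filter failure;
#'   hotspot/loop/anchor annotations of the shared monomer).
#' @export
synth_pose_ensemble <- function(plan) {
  stopifnot(inherits(plan, "pose_plan"))
  base_plan <- helix_dimer_plan(include_loop = TRUE, anchor = TRUE,
                                planted_bridges = list(), pi_stacks = list())
  with_seed(plan$seed, {
    sizes <- round(plan$n_poses * plan$cluster_fractions)
    n_scatter <- plan$n_poses - sum(sizes)
    membership <- integer(0); poses <- list()
    make_pose <- function(R, tvec) {
      p <- base_plan
      p$b_transform <- list(rotation = R, translation = tvec)
      build_helix_dimer(p)$dimer
    }
    for (k in seq_along(sizes)) {
      pl <- plan$placements[[k]]
      for (j in seq_len(sizes[k])) {
        jR <- random_rotation(plan$jitter_sd * 40) %*% pl$rotation
        jt <- pl$translation + rnorm(3, 0, plan$jitter_sd)
        poses[[length(poses) + 1]] <- make_pose(jR, jt)
        membership <- c(membership, k)
      }
    }
    for (j in seq_len(n_scatter)) {
      repeat {
        R <- random_rotation()
        dir <- unit3(rnorm(3))
        tvec <- dir * runif(1, 3.0, 6.0)
        pose <- try(make_pose(R, tvec), silent = TRUE)
        if (!inherits(pose, "try-error")) break
      }
      poses[[length(poses) + 1]] <- pose
      membership <- c(membership, 0L)
    }
    truth <- list(
      membership = membership,
      cluster_fails = vapply(plan$placements[seq_along(sizes)],
                             function(p) p$fails, character(1)),
      hotspots = c(94, 95, 97, 98, 101, 102, 107),
      effector_loop = 25:40, anchor_resid = 140L)
    list(ensemble = pose_ensemble(poses), truth = truth)
  })
}
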