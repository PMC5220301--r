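# Computational alanine scanning: side-chain truncation to C-beta plus a
# transparent fixed-parameter pairwise interaction energy (Coulomb with a
# distance-dependent dielectric and 12-6 Lennard-Jones). Rankings, not
# absolute energies, are the deliverable; all parameters sit in one table.

# per-element Lennard-Jones well depths (kcal/mol); r_min pairs are sums of
# the united-atom vdW radii from ELEMENT_TABLE
LJ_EPSILON <- c(C = 0.10, N = 0.16, O = 0.17, S = 0.25, H = 0.02, P = 0.20)

# formal +-1 e charges distributed over terminal heavy atoms
charge_table <- function(his_protonated = FALSE) {
  q <- list(
    LYS = c(NZ = 1),
    ARG = c(NE = 1 / 3, NH1 = 1 / 3, NH2 = 1 / 3),
    ASP = c(OD1 = -0.5, OD2 = -0.5),
    GLU = c(OE1 = -0.5, OE2 = -0.5))
  if (his_protonated) q$HIS <- c(ND1 = 0.5, NE2 = 0.5)
  q
}

COULOMB_CONST <- 332.0636   # kcal mol^-1 A e^-2

atom_charges <- function(atoms, his_protonated = FALSE) {
  qt <- charge_table(his_protonated)
  q <- numeric(nrow(atoms))
  for (rn in names(qt)) {
    tab <- qt[[rn]]
    for (nm in names(tab))
      q[atoms$resname == rn & atoms$name == nm] <- tab[[nm]]
  }
  q
}

# CHARMM-style switching function on [r_on, r_cut]
switch_factor <- function(r, r_on, r_cut) {
  s <- rep(1, length(r))
  mid <- r > r_on & r < r_cut
  rc2 <- r_cut^2; ro2 <- r_on^2; r2 <- r[mid]^2
  s[mid] <- (rc2 - r2)^2 * (rc2 + 2 * r2 - 3 * ro2) / (rc2 - ro2)^3
  s[r >= r_cut] <- 0
  s
}

#' Inter-monomer interaction energy of a dimer
#'
#' Pairwise sum over inter-monomer atom pairs within `r_cut`, smoothly
#' switched off from `r_on`: Coulomb with formal charges on charged-group
#' terminal atoms and a distance-dependent dielectric `eps = 4 r` (r in
#' Angstrom), plus 12-6 Lennard-Jones with per-element well depths and
#' `r_min` = sum of the united-atom vdW radii.
#'
#' @param dimer a `DimerModel`.
#' @param r_cut,r_on cutoff and switch-on distances (nm).
#' @param his_protonated treat His as +1 charged.
#' @param frame frame index.
#' @return list with `total`, `coulomb`, `lj` (kcal/mol).
#' @export
inter_monomer_energy <- function(dimer, r_cut = 1.2, r_on = 1.0,
                                 his_protonated = FALSE, frame = 1) {
  st <- dimer$structure; a <- st$atoms
  xyz <- coords(st, frame)
  ia <- dimer$sel_a; ib <- dimer$sel_b
  ea <- a$element[ia]; eb <- a$element[ib]
  bad <- setdiff(unique(c(ea, eb)), names(LJ_EPSILON))
  if (length(bad)) stop("untyped element(s): ", paste(bad, collapse = ", "))
  D <- pair_distances(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
  within <- which(D <= r_cut, arr.ind = TRUE)
  if (nrow(within) == 0)
    return(list(total = 0, coulomb = 0, lj = 0))
  r <- D[within]
  sw <- switch_factor(r, r_on, r_cut)

  qa <- atom_charges(a[ia, , drop = FALSE], his_protonated)[within[, 1]]
  qb <- atom_charges(a[ib, , drop = FALSE], his_protonated)[within[, 2]]
  r_ang <- r * 10
  e_coul <- sum(COULOMB_CONST * qa * qb / (4 * r_ang^2) * sw)

  rmin <- vdw_radius(ea)[within[, 1]] + vdw_radius(eb)[within[, 2]]
  epsij <- sqrt(LJ_EPSILON[ea][within[, 1]] * LJ_EPSILON[eb][within[, 2]])
  x6 <- (rmin / r)^6
  e_lj <- sum(epsij * (x6^2 - 2 * x6) * sw)
  list(total = e_coul + e_lj, coulomb = e_coul, lj = e_lj)
}

#' Mutate a residue to alanine by side-chain truncation
#'
#' Removes side-chain atoms beyond C-beta (C-beta and backbone untouched)
#' and renames the residue ALA. Glycine and proline are skipped with a
#' reason; alanine is a no-op.
#'
#' @param structure a `Structure`.
#' @param chain,resid residue to mutate.
#' @return the mutated `Structure`, with attribute `"mutation"` describing
#'   what was done (`mutated`, `already-ala`, `skipped-gly`, `skipped-pro`).
#' @export
mutate_to_alanine <- function(structure, chain, resid) {
  a <- structure$atoms
  sel <- which(a$chain == chain & a$resid == resid)
  if (length(sel) == 0) stop("residue ", chain, ":", resid, " not found")
  rn <- a$resname[sel[1]]
  if (rn == "ALA") { attr(structure, "mutation") <- "already-ala"; return(structure) }
  if (rn == "GLY") { attr(structure, "mutation") <- "skipped-gly"; return(structure) }
  if (rn == "PRO") { attr(structure, "mutation") <- "skipped-pro"; return(structure) }
  if (!any(a$name[sel] == "CB"))
    stop("residue ", chain, ":", resid, " has no C-beta atom")
  keep_names <- c(BACKBONE_NAMES, "CB", "H", "HA", "HN")
  drop <- sel[!(a$name[sel] %in% keep_names)]
  keep <- setdiff(seq_len(nrow(a)), drop)
  out <- structure_subset(structure, keep)
  out$atoms$resname[out$atoms$chain == chain & out$atoms$resid == resid] <- "ALA"
  attr(out, "mutation") <- "mutated"
  out
}

#' Computational alanine scan of interfacial residues
#'
#' For each scanned residue, `ddE = E_mut - E_wt`: the loss of inter-monomer
#' interaction energy on truncating the side chain to alanine, with no
#' conformational relaxation (rigid scan). Positive values mean the residue
#' stabilizes the dimer. Results are ranked descending.
#'
#' @param dimer a `DimerModel`.
#' @param residues data.frame with columns `chain`, `resid` of residues to
#'   scan; defaults to the interfacial residues from [delta_sasa()].
#' @param contact_cut distance (nm) used to report contact partners.
#' @param n_sphere_points SASA lattice density for the default residue set.
#' @param ... passed to [inter_monomer_energy()].
#' @return a `ScanResult` data.frame: chain, resid, resname, `ddE`,
#'   electrostatic/LJ decomposition, `partners`, `note`, `rank`.
#' @export
scan_interface <- function(dimer, residues = NULL, contact_cut = 0.5,
                           n_sphere_points = 240, ...) {
  st <- dimer$structure; a <- st$atoms
  if (is.null(residues)) {
    ds <- delta_sasa(dimer, n_sphere_points = n_sphere_points)
    pr <- ds$per_residue[ds$per_residue$interfacial, , drop = FALSE]
    residues <- pr[, c("chain", "resid")]
  }
  if (nrow(residues) == 0) stop("no residues to scan")
  e_wt <- inter_monomer_energy(dimer, ...)
  xyz <- coords(st, 1)
  rows <- lapply(seq_len(nrow(residues)), function(k) {
    ch <- residues$chain[k]; rs <- residues$resid[k]
    sel <- which(a$chain == ch & a$resid == rs)
    rn <- a$resname[sel[1]]
    mut <- mutate_to_alanine(st, ch, rs)
    note <- attr(mut, "mutation")
    if (note != "mutated") {
      return(data.frame(chain = ch, resid = rs, resname = rn, ddE = 0,
                        coulomb = 0, lj = 0, partners = "", note = note,
                        stringsAsFactors = FALSE))
    }
    mdim <- dimer_model(mut, dimer$chains_a, dimer$chains_b,
                        provenance = dimer$provenance)
    e_mut <- inter_monomer_energy(mdim, ...)
    other <- if (ch %in% a$chain[dimer$sel_a]) dimer$sel_b else dimer$sel_a
    side <- sel[!(a$name[sel] %in% BACKBONE_NAMES)]
    partners <- character(0)
    if (length(side)) {
      D <- pair_distances(xyz[side, , drop = FALSE],
                          xyz[other, , drop = FALSE])
      near <- other[unique(which(D <= contact_cut, arr.ind = TRUE)[, 2])]
      if (length(near))
        partners <- unique(paste0(a$chain[near], ":", a$resid[near]))
    }
    data.frame(chain = ch, resid = rs, resname = rn,
               ddE = e_mut$total - e_wt$total,
               coulomb = e_mut$coulomb - e_wt$coulomb,
               lj = e_mut$lj - e_wt$lj,
               partners = paste(partners, collapse = ","), note = "mutated",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$ddE), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("ScanResult", "data.frame")
  out
}

#' Write an alanine-scan table as TSV
#' @param scan a `ScanResult`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
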