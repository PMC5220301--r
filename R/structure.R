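# Core structure model: hierarchical atom/residue/chain coordinates read from
# PDB, plus the rigid-body geometry shared by every downstream stage.
# Internal length unit is nm throughout; PDB I/O converts from Angstrom.

ANGSTROM_PER_NM <- 10

# Documented per-element parameter table (united-atom vdW radii, nm; masses in
# Da). SASA over heavy atoms uses these radii directly when hydrogens are
# absent, which is the common situation for docking and coarse MD outputs.
ELEMENT_TABLE <- data.frame(
  element = c("C", "N", "O", "S", "H", "P"),
  vdw_nm  = c(0.170, 0.155, 0.152, 0.180, 0.120, 0.180),
  mass    = c(12.011, 14.007, 15.999, 32.06, 1.008, 30.974),
  stringsAsFactors = FALSE
)

#' Infer the element symbol from a PDB atom name
#'
#' Leading digits are stripped (`1HB` is a hydrogen) and the first remaining
#' letter is taken, which is the right rule for protein `ATOM` records where
#' the only elements are C, N, O, S, H and P.
#'
#' @param name character vector of atom names.
#' @return character vector of element symbols.
#' @export
element_from_name <- function(name) {
  x <- gsub("[^A-Za-z]", "", toupper(trimws(name)))
  substr(x, 1, 1)
}

element_lookup <- function(element, what = c("vdw_nm", "mass")) {
  what <- match.arg(what)
  i <- match(element, ELEMENT_TABLE$element)
  if (anyNA(i)) {
    bad <- unique(element[is.na(i)])
    stop("no ", what, " entry for element(s): ", paste(bad, collapse = ", "))
  }
  ELEMENT_TABLE[[what]][i]
}

#' @rdname element_from_name
#' @param element character vector of element symbols.
#' @export
vdw_radius <- function(element) element_lookup(element, "vdw_nm")

#' @rdname element_from_name
#' @export
atomic_mass <- function(element) element_lookup(element, "mass")

new_structure <- function(atoms, xyz) {
  stopifnot(is.data.frame(atoms), is.list(xyz), length(xyz) >= 1)
  n <- nrow(atoms)
  for (fr in xyz) {
    stopifnot(is.matrix(fr), nrow(fr) == n, ncol(fr) == 3)
    if (!all(is.finite(fr))) stop("non-finite coordinates in structure")
  }
  structure(list(atoms = atoms, xyz = xyz), class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("Structure: %d atoms, %d residues, %d chain(s) [%s], %d frame(s)\n",
              nrow(x$atoms), nrow(rt), length(unique(x$atoms$chain)),
              paste(unique(x$atoms$chain), collapse = ","), length(x$xyz)))
  invisible(x)
}

#' Number of atoms / frames in a Structure
#' @param structure a `Structure`.
#' @return integer count.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' @rdname n_atoms
#' @export
n_frames <- function(structure) length(structure$xyz)

#' Coordinates of a Structure frame
#' @param structure a `Structure`.
#' @param frame frame index (1-based).
#' @return numeric matrix, one row per atom, columns x/y/z in nm.
#' @export
coords <- function(structure, frame = 1) {
  if (frame < 1 || frame > n_frames(structure)) stop("frame out of range")
  structure$xyz[[frame]]
}

#' Residue table of a Structure
#'
#' One row per residue in file order: chain, author residue number, name.
#'
#' @param structure a `Structure`.
#' @return data.frame with columns `chain`, `resid`, `resname`, `first_atom`.
#' @export
residue_table <- function(structure) {
  a <- structure$atoms
  key <- paste(a$chain, a$resid, sep = "|")
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resid = a$resid[first],
             resname = a$resname[first], first_atom = which(first),
             stringsAsFactors = FALSE)
}

residue_key <- function(atoms) paste(atoms$chain, atoms$resid, sep = "|")

validate_pdb_lines <- function(lines, path) {
  rec <- substr(lines, 1, 6)
  idx <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(idx) == 0)
    stop("no ATOM records found in '", path, "' (empty structure)")
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed PDB record at line ", i, " of '", path,
           "': fewer than 54 columns")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz))
      stop("malformed PDB record at line ", i, " of '", path,
           "': unparseable coordinates")
  }
  invisible(length(idx))
}

#' Read a protein structure from a PDB file
#'
#' Coordinates are converted from Angstrom to nm. Alternate locations are
#' resolved to the highest-occupancy conformer (ties broken by altLoc letter);
#' waters and other hetero groups are excluded unless `keep_hetero = TRUE`.
#' Multi-MODEL files become multi-frame structures under
#' `frame_policy = "all"` (all frames share one topology).
#'
#' @param path PDB file path.
#' @param frame_policy `"first"` (default) keeps the first MODEL only;
#'   `"all"` keeps every MODEL as a coordinate frame.
#' @param keep_hetero keep HETATM records (waters are always dropped).
#' @return a `Structure`.
#' @export
read_structure <- function(path, frame_policy = c("first", "all"),
                           keep_hetero = FALSE) {
  frame_policy <- match.arg(frame_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  validate_pdb_lines(readLines(path, warn = FALSE), path)
  pdb <- bio3d::read.pdb(path, multi = (frame_policy == "all"),
                         rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (frame_policy == "first") xyz <- xyz[1, , drop = FALSE]

  keep <- at$type == "ATOM"
  if (keep_hetero)
    keep <- keep | (at$type == "HETATM" &
                    !(at$resid %in% c("HOH", "WAT", "TIP3", "SOL")))
  at$row0 <- seq_len(nrow(at))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) stop("no atoms retained from '", path, "'")

  # resolve altLocs to highest occupancy
  at$alt[is.na(at$alt)] <- ""
  grp <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  occ <- at$o
  occ[is.na(occ)] <- 1
  ord <- order(grp, -occ, at$alt)
  at2 <- at[ord, , drop = FALSE]
  at2 <- at2[!duplicated(paste(at2$chain, at2$resno, at2$insert, at2$elety,
                               sep = "|")), , drop = FALSE]
  at2 <- at2[order(at2$row0), , drop = FALSE]

  elem <- toupper(trimws(at2$elesy))
  miss <- is.na(elem) | elem == "" | !(elem %in% ELEMENT_TABLE$element)
  elem[miss] <- element_from_name(at2$elety[miss])

  atoms <- data.frame(
    serial = at2$eleno, name = at2$elety, resname = at2$resid,
    chain = ifelse(is.na(at2$chain) | at2$chain == "", "A", at2$chain),
    resid = at2$resno, element = elem,
    occ = ifelse(is.na(at2$o), 1, at2$o),
    stringsAsFactors = FALSE)

  frames <- lapply(seq_len(nrow(xyz)), function(f) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)[at2$row0, , drop = FALSE]
    m / ANGSTROM_PER_NM
  })
  new_structure(atoms, frames)
}

#' Write a Structure to a PDB file
#'
#' Coordinates are converted back to Angstrom; multi-frame structures are
#' written as MODEL/ENDMDL blocks.
#'
#' @param structure a `Structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  one_frame <- function(fr) {
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp))
    bio3d::write.pdb(file = tmp,
                     xyz = as.numeric(t(coords(structure, fr) * ANGSTROM_PER_NM)),
                     resno = a$resid, resid = a$resname, chain = a$chain,
                     elety = a$name, eleno = a$serial, o = a$occ,
                     elesy = a$element)
    readLines(tmp, warn = FALSE)
  }
  nf <- n_frames(structure)
  if (nf == 1) {
    writeLines(one_frame(1), path)
  } else {
    out <- character(0)
    for (f in seq_len(nf)) {
      body <- one_frame(f)
      body <- body[!grepl("^END", body)]
      out <- c(out, sprintf("MODEL     %4d", f), body, "ENDMDL")
    }
    writeLines(c(out, "END"), path)
  }
  invisible(path)
}

# ---- selections -------------------------------------------------------------

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")

parse_selection <- function(structure, selection) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  clauses <- strsplit(selection, "\\s+and\\s+")[[1]]
  for (cl in clauses) {
    cl <- trimws(cl)
    toks <- strsplit(cl, "\\s+")[[1]]
    kw <- tolower(toks[1])
    args <- toks[-1]
    keep <- keep & switch(kw,
      chain = a$chain %in% args,
      resid = {
        ids <- integer(0)
        for (tk in args) {
          if (grepl("-", tk)) {
            rg <- as.integer(strsplit(tk, "-")[[1]])
            ids <- c(ids, seq(rg[1], rg[2]))
          } else ids <- c(ids, as.integer(tk))
        }
        a$resid %in% ids
      },
      name = a$name %in% args,
      element = a$element %in% toupper(args),
      backbone = a$name %in% BACKBONE_NAMES,
      calpha = a$name == "CA",
      ca = a$name == "CA",
      stop("unknown selection keyword: ", kw)
    )
  }
  which(keep)
}

#' Select atoms of a Structure
#'
#' Either pass a selection string in the mini-language
#' `"chain A and resid 87-104 and name CA"` (keywords: `chain`, `resid` with
#' 1-based inclusive ranges, `name`, `element`, `backbone`, `calpha`), or use
#' the keyword arguments directly.
#'
#' @param structure a `Structure`.
#' @param selection selection string, or `NULL`.
#' @param chain,resid,name,element vectors to match (ignored when `selection`
#'   is given).
#' @return integer vector of atom indices.
#' @export
select_atoms <- function(structure, selection = NULL, chain = NULL,
                         resid = NULL, name = NULL, element = NULL) {
  if (!is.null(selection)) return(parse_selection(structure, selection))
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(element)) keep <- keep & a$element %in% toupper(element)
  which(keep)
}

#' Subset a Structure by atom indices
#' @param structure a `Structure`.
#' @param idx integer atom indices (kept in the given order).
#' @return a `Structure`.
#' @export
structure_subset <- function(structure, idx) {
  if (length(idx) == 0) stop("empty selection")
  new_structure(structure$atoms[idx, , drop = FALSE],
                lapply(structure$xyz, function(m) m[idx, , drop = FALSE]))
}

#' Apply a rigid-body transform to a Structure
#'
#' Rotations act on column vectors (`y = R x`), so row-major coordinate
#' matrices are multiplied by `t(rotation)`.
#'
#' @param structure a `Structure`.
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 translation (nm).
#' @param idx atom indices to move (default: all).
#' @return the transformed `Structure`.
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0), idx = NULL) {
  if (is.null(idx)) idx <- seq_len(n_atoms(structure))
  structure$xyz <- lapply(structure$xyz, function(m) {
    m[idx, ] <- m[idx, , drop = FALSE] %*% t(rotation) +
      matrix(translation, nrow = length(idx), ncol = 3, byrow = TRUE)
    m
  })
  structure
}

# ---- dimer model ------------------------------------------------------------

#' Define a homodimer model inside a Structure
#'
#' @param structure a `Structure` containing both protomers.
#' @param chains_a,chains_b chain ids of monomer A and monomer B.
#' @param provenance free-text tag carried through reports.
#' @return a `DimerModel`.
#' @export
dimer_model <- function(structure, chains_a = "A", chains_b = "B",
                        provenance = "") {
  sel_a <- select_atoms(structure, chain = chains_a)
  sel_b <- select_atoms(structure, chain = chains_b)
  if (length(sel_a) == 0 || length(sel_b) == 0)
    stop("monomer selections must be non-empty")
  if (length(intersect(sel_a, sel_b)) > 0)
    stop("monomer selections must be disjoint")
  structure(list(structure = structure, sel_a = sel_a, sel_b = sel_b,
                 chains_a = chains_a, chains_b = chains_b,
                 provenance = provenance),
            class = "DimerModel")
}

#' @export
print.DimerModel <- function(x, ...) {
  cat(sprintf("DimerModel: A=[%s] %d atoms | B=[%s] %d atoms | %d frame(s)%s\n",
              paste(x$chains_a, collapse = ","), length(x$sel_a),
              paste(x$chains_b, collapse = ","), length(x$sel_b),
              n_frames(x$structure),
              if (nzchar(x$provenance)) paste0(" | ", x$provenance) else ""))
  invisible(x)
}

# ---- rigid-body geometry ----------------------------------------------------

#' Least-squares superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' paired coordinate sets, via SVD of the cross-covariance matrix with the
#' usual determinant correction so the returned rotation is never a
#' reflection.
#'
#' @param mobile,target n x 3 coordinate matrices (nm), n >= 3, paired rows.
#' @return list with `rotation` (3x3, det +1), `translation` (length 3) such
#'   that `mobile %*% rotation + translation` best fits `target`, and `rmsd`
#'   (nm).
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target)) stop("point counts differ")
  if (nrow(mobile) < 3) stop("need at least 3 points for superposition")
  cm <- colMeans(mobile); ct <- colMeans(target)
  M <- sweep(mobile, 2, cm); Tt <- sweep(target, 2, ct)
  for (X in list(M, Tt)) {
    s <- svd(X)$d
    if (s[2] < 1e-9 * max(s[1], 1e-30))
      stop("degenerate (collinear) point configuration")
  }
  H <- crossprod(M, Tt)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  aligned <- M %*% R
  rmsd <- sqrt(mean(rowSums((aligned - Tt)^2)))
  list(rotation = R, translation = as.numeric(ct - cm %*% R), rmsd = rmsd)
}

#' Apply a rigid transform to a coordinate matrix
#' @param xyz n x 3 matrix.
#' @param tf transform list from [kabsch_superpose()].
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, tf) {
  sweep(as.matrix(xyz) %*% tf$rotation, 2, tf$translation, "+")
}

#' Rotation angle of a rotation matrix
#' @param R 3x3 rotation matrix.
#' @return angle in degrees in \[0, 180\].
#' @export
rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

#' Rotation matrix about an axis
#' @param axis length-3 axis (normalized internally).
#' @param angle angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Centre of mass of an atom selection
#'
#' @param structure a `Structure`.
#' @param sel atom indices (default: all atoms).
#' @param weighting `"mass"` (element masses from the documented table) or
#'   `"geometric"` (unweighted centroid).
#' @param frame frame index.
#' @return length-3 numeric vector (nm).
#' @export
center_of_mass <- function(structure, sel = NULL,
                           weighting = c("mass", "geometric"), frame = 1) {
  weighting <- match.arg(weighting)
  if (is.null(sel)) sel <- seq_len(n_atoms(structure))
  if (length(sel) == 0) stop("empty selection")
  xyz <- coords(structure, frame)[sel, , drop = FALSE]
  w <- if (weighting == "mass")
    atomic_mass(structure$atoms$element[sel]) else rep(1, length(sel))
  as.numeric(colSums(xyz * w) / sum(w))
}

#' Torsion (dihedral) angle of four points
#' @param p1,p2,p3,p4 length-3 coordinates.
#' @return angle in degrees in (-180, 180\].
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

# ---- secondary structure ----------------------------------------------------

# dihedral windows (degrees); only the helix/strand/coil distinction is needed
SS_HELIX_PHI <- c(-120, -30); SS_HELIX_PSI <- c(-80, 0)
in_window <- function(x, w) !is.na(x) & x >= w[1] & x <= w[2]
is_strand_phi <- function(phi) !is.na(phi) & (phi <= -90 | phi >= 150)
is_strand_psi <- function(psi) !is.na(psi) & (psi >= 90 | psi <= -150)

backbone_dihedrals <- function(structure, frame = 1) {
  rt <- residue_table(structure)
  a <- structure$atoms
  xyz <- coords(structure, frame)
  idx_of <- function(ch, rs, nm) {
    i <- which(a$chain == ch & a$resid == rs & a$name == nm)
    if (length(i)) i[1] else NA_integer_
  }
  phi <- psi <- rep(NA_real_, nrow(rt))
  iN <- mapply(idx_of, rt$chain, rt$resid, MoreArgs = list(nm = "N"))
  iCA <- mapply(idx_of, rt$chain, rt$resid, MoreArgs = list(nm = "CA"))
  iC <- mapply(idx_of, rt$chain, rt$resid, MoreArgs = list(nm = "C"))
  for (i in seq_len(nrow(rt))) {
    if (anyNA(c(iN[i], iCA[i], iC[i]))) next
    if (i > 1 && rt$chain[i - 1] == rt$chain[i] && !is.na(iC[i - 1])) {
      # require a real peptide bond (chain breaks give NA)
      if (sqrt(sum((xyz[iC[i - 1], ] - xyz[iN[i], ])^2)) < 0.25)
        phi[i] <- torsion_angle(xyz[iC[i - 1], ], xyz[iN[i], ],
                                xyz[iCA[i], ], xyz[iC[i], ])
    }
    if (i < nrow(rt) && rt$chain[i + 1] == rt$chain[i] && !is.na(iN[i + 1])) {
      if (sqrt(sum((xyz[iC[i], ] - xyz[iN[i + 1], ])^2)) < 0.25)
        psi[i] <- torsion_angle(xyz[iN[i], ], xyz[iCA[i], ],
                                xyz[iC[i], ], xyz[iN[i + 1], ])
    }
  }
  cbind(rt, phi = phi, psi = psi, has_bb = !is.na(iN) & !is.na(iCA) & !is.na(iC))
}

#' Assign secondary structure from backbone dihedrals
#'
#' Classifies each residue as helix, strand or coil from phi/psi windows
#' (helix: phi in \[-120, -30\] and psi in \[-80, 0\]; strand: phi <= -90 or
#' >= 150 with psi >= 90 or <= -150), requiring runs of at least 4 (helix)
#' or 3 (strand) consecutive candidates. Terminal residues are judged on
#' their single available dihedral. Residues missing backbone atoms are
#' assigned coil with a warning. A user-supplied assignment overrides the
#' dihedral call.
#'
#' @param structure a `Structure`.
#' @param override optional data.frame with columns `chain`, `resid`, `ss`
#'   whose entries replace the computed assignment.
#' @param frame frame index.
#' @return data.frame with columns `chain`, `resid`, `resname`, `ss`
#'   (one of `"helix"`, `"strand"`, `"coil"`).
#' @export
assign_secondary_structure <- function(structure, override = NULL, frame = 1) {
  dh <- backbone_dihedrals(structure, frame)
  if (any(!dh$has_bb))
    warning("residues missing backbone atoms assigned coil: ",
            paste(dh$resid[!dh$has_bb], collapse = ","))
  helix_cand <- dh$has_bb & !(is.na(dh$phi) & is.na(dh$psi)) &
    (is.na(dh$phi) | in_window(dh$phi, SS_HELIX_PHI)) &
    (is.na(dh$psi) | in_window(dh$psi, SS_HELIX_PSI))
  strand_cand <- dh$has_bb & !(is.na(dh$phi) & is.na(dh$psi)) &
    (is.na(dh$phi) | is_strand_phi(dh$phi)) &
    (is.na(dh$psi) | is_strand_psi(dh$psi)) & !helix_cand
  ss <- rep("coil", nrow(dh))
  # enforce minimum run lengths within each chain
  for (ch in unique(dh$chain)) {
    ii <- which(dh$chain == ch)
    for (spec in list(list(cand = helix_cand[ii], lab = "helix", minlen = 4),
                      list(cand = strand_cand[ii], lab = "strand", minlen = 3))) {
      r <- rle(spec$cand)
      pos <- cumsum(r$lengths) - r$lengths + 1
      for (k in seq_along(r$lengths)) {
        if (r$values[k] && r$lengths[k] >= spec$minlen) {
          sel <- ii[pos[k]:(pos[k] + r$lengths[k] - 1)]
          ss[sel] <- spec$lab
        }
      }
    }
  }
  out <- data.frame(chain = dh$chain, resid = dh$resid, resname = dh$resname,
                    ss = ss, stringsAsFactors = FALSE)
  if (!is.null(override)) {
    for (i in seq_len(nrow(override))) {
      j <- out$chain == override$chain[i] & out$resid == override$resid[i]
      out$ss[j] <- override$ss[i]
    }
  }
  out
}
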