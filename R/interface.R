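# The five interface descriptors (delta-SASA, hydrogen bonds, hydrophobic
# contacts, centre-of-mass distance, relative orientation) plus interaction
# typing (salt bridges, pi-stacking) and quasi-symmetry, over single
# structures or conformer ensembles. Cutoff defaults are the conventional
# geometric criteria: 0.3 nm / 20 deg for hydrogen bonds, 0.38 nm for
# carbon-carbon contacts, 0.4 nm N-O for salt bridges.

DONOR_NAMES <- c("N", "ND1", "ND2", "NE", "NE1", "NE2", "NH1", "NH2", "NZ",
                 "OG", "OG1", "OH", "SG")
ACCEPTOR_NAMES <- c("O", "OXT", "OD1", "OD2", "OE1", "OE2", "OG", "OG1",
                    "OH", "ND1", "SD")

BASIC_GROUP <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"))
BASIC_GROUP_HISP <- c(BASIC_GROUP, list(HIS = c("ND1", "NE2")))
ACIDIC_GROUP <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

RING_ATOMS <- list(HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
                   PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                   TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                   TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))

pair_distances <- function(xa, xb) {
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  sqrt(pmax(d2, 0))
}

#' Inter-monomer hydrogen bonds
#'
#' Donor-acceptor pairs across the interface with heavy-atom distance at
#' most `d_cut`. When the donor carries hydrogens, the bond must also be
#' near-linear: the deviation of the donor-hydrogen-acceptor angle from 180
#' degrees must not exceed `angle_cut` for at least one attached hydrogen.
#' Donors without hydrogens (the common case for docking and coarse MD
#' output) fall back to the distance-only criterion and are flagged in the
#' output.
#'
#' @param dimer a `DimerModel`.
#' @param d_cut donor-acceptor heavy-atom distance cutoff (nm).
#' @param angle_cut allowed deviation from linearity (degrees).
#' @param frame frame index.
#' @return data.frame of bonds (donor/acceptor chain, resid, atom name,
#'   distance, `fallback` flag); each donor-acceptor pair appears once.
#' @export
hydrogen_bonds <- function(dimer, d_cut = 0.30, angle_cut = 20, frame = 1) {
  st <- dimer$structure
  a <- st$atoms
  xyz <- coords(st, frame)
  # attach hydrogens to the nearest covalent heavy partner
  h_idx <- which(a$element == "H")
  find_pairs <- function(sel_d, sel_a) {
    don <- sel_d[a$name[sel_d] %in% DONOR_NAMES & a$element[sel_d] != "H"]
    acc <- sel_a[a$name[sel_a] %in% ACCEPTOR_NAMES]
    if (length(don) == 0 || length(acc) == 0) return(NULL)
    D <- pair_distances(xyz[don, , drop = FALSE], xyz[acc, , drop = FALSE])
    hits <- which(D <= d_cut, arr.ind = TRUE)
    if (nrow(hits) == 0) return(NULL)
    out <- NULL
    for (k in seq_len(nrow(hits))) {
      i_d <- don[hits[k, 1]]; i_a <- acc[hits[k, 2]]
      hs <- h_idx[a$chain[h_idx] == a$chain[i_d] &
                    a$resid[h_idx] == a$resid[i_d]]
      if (length(hs) > 0) {
        dh <- sqrt(rowSums((xyz[hs, , drop = FALSE] -
                              matrix(xyz[i_d, ], length(hs), 3,
                                     byrow = TRUE))^2))
        hs <- hs[dh < 0.125]
      }
      fallback <- length(hs) == 0
      ok <- fallback
      if (!fallback) {
        for (ih in hs) {
          v1 <- xyz[i_d, ] - xyz[ih, ]; v2 <- xyz[i_a, ] - xyz[ih, ]
          ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                    sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
          if (180 - ang <= angle_cut) { ok <- TRUE; break }
        }
      }
      if (ok)
        out <- rbind(out, data.frame(
          donor_chain = a$chain[i_d], donor_resid = a$resid[i_d],
          donor_atom = a$name[i_d], acceptor_chain = a$chain[i_a],
          acceptor_resid = a$resid[i_a], acceptor_atom = a$name[i_a],
          distance = D[hits[k, 1], hits[k, 2]], fallback = fallback,
          stringsAsFactors = FALSE))
    }
    out
  }
  res <- rbind(find_pairs(dimer$sel_a, dimer$sel_b),
               find_pairs(dimer$sel_b, dimer$sel_a))
  if (is.null(res))
    res <- data.frame(donor_chain = character(0), donor_resid = integer(0),
                      donor_atom = character(0), acceptor_chain = character(0),
                      acceptor_resid = integer(0), acceptor_atom = character(0),
                      distance = numeric(0), fallback = logical(0))
  unique(res)
}

#' Inter-monomer hydrophobic contacts
#'
#' By the conventional atom-level definition: the number of carbon atoms in
#' monomer A having at least one monomer B carbon within `d_cut`. This count
#' is asymmetric in the monomer labels by construction; `symmetric = TRUE`
#' instead counts carbons on both sides that have a cross-monomer carbon
#' neighbour.
#'
#' @param dimer a `DimerModel`.
#' @param d_cut carbon-carbon distance cutoff (nm).
#' @param symmetric count both monomers' carbons.
#' @param frame frame index.
#' @return list with `count` and `pairs` (data.frame of contacting atom
#'   pairs).
#' @export
hydrophobic_contacts <- function(dimer, d_cut = 0.38, symmetric = FALSE,
                                 frame = 1) {
  st <- dimer$structure; a <- st$atoms
  xyz <- coords(st, frame)
  ca <- dimer$sel_a[a$element[dimer$sel_a] == "C"]
  cb <- dimer$sel_b[a$element[dimer$sel_b] == "C"]
  if (length(ca) == 0 || length(cb) == 0)
    return(list(count = 0L, pairs = data.frame()))
  D <- pair_distances(xyz[ca, , drop = FALSE], xyz[cb, , drop = FALSE])
  hit <- D <= d_cut
  count <- sum(rowSums(hit) > 0)
  if (symmetric) count <- count + sum(colSums(hit) > 0)
  idx <- which(hit, arr.ind = TRUE)
  pairs <- data.frame(
    chain_a = a$chain[ca[idx[, 1]]], resid_a = a$resid[ca[idx[, 1]]],
    atom_a = a$name[ca[idx[, 1]]], chain_b = a$chain[cb[idx[, 2]]],
    resid_b = a$resid[cb[idx[, 2]]], atom_b = a$name[cb[idx[, 2]]],
    distance = D[idx], stringsAsFactors = FALSE)
  list(count = as.integer(count), pairs = pairs)
}

#' Inter-monomer centre-of-mass distance
#' @param dimer a `DimerModel`.
#' @param frame frame index.
#' @return distance in nm.
#' @export
com_distance <- function(dimer, frame = 1) {
  ca <- center_of_mass(dimer$structure, dimer$sel_a, frame = frame)
  cb <- center_of_mass(dimer$structure, dimer$sel_b, frame = frame)
  sqrt(sum((ca - cb)^2))
}

#' Relative orientation of the monomers versus a reference arrangement
#'
#' Superposes monomer A onto the reference's monomer A, then measures the
#' rotation (axis-angle magnitude from the rotation-matrix trace) still
#' needed to bring monomer B onto the reference's monomer B. Zero for the
#' reference itself.
#'
#' @param dimer,reference `DimerModel`s with identical monomer topologies.
#' @param frame,ref_frame frame indices.
#' @return angle in degrees in \[0, 180\].
#' @export
relative_orientation <- function(dimer, reference, frame = 1, ref_frame = 1) {
  if (length(dimer$sel_a) != length(reference$sel_a) ||
      length(dimer$sel_b) != length(reference$sel_b))
    stop("monomer topologies do not match the reference")
  xyz <- coords(dimer$structure, frame)
  ref <- coords(reference$structure, ref_frame)
  tf_a <- kabsch_superpose(xyz[dimer$sel_a, , drop = FALSE],
                           ref[reference$sel_a, , drop = FALSE])
  b_aligned <- apply_transform(xyz[dimer$sel_b, , drop = FALSE], tf_a)
  tf_b <- kabsch_superpose(b_aligned, ref[reference$sel_b, , drop = FALSE])
  rotation_angle(tf_b$rotation)
}

#' Inter-monomer salt bridges
#'
#' Basic/acidic residue pairs across the interface whose charged-group
#' nitrogen-oxygen distance is at most `d_cut`. Histidine participates only
#' when flagged protonated.
#'
#' @param dimer a `DimerModel`.
#' @param d_cut N-O distance cutoff (nm).
#' @param his_protonated treat His as positively charged.
#' @param frame frame index.
#' @return data.frame: basic/acidic chain, resid, residue types, `type`
#'   (e.g. `"K->E"`), minimal N-O distance.
#' @export
salt_bridges <- function(dimer, d_cut = 0.4, his_protonated = FALSE,
                         frame = 1) {
  st <- dimer$structure; a <- st$atoms
  xyz <- coords(st, frame)
  basic_tab <- if (his_protonated) BASIC_GROUP_HISP else BASIC_GROUP
  group_atoms <- function(sel, tab) {
    keep <- logical(length(sel))
    for (rn in names(tab))
      keep <- keep | (a$resname[sel] == rn & a$name[sel] %in% tab[[rn]])
    sel[keep]
  }
  one_letter <- c(LYS = "K", ARG = "R", HIS = "H", ASP = "D", GLU = "E")
  find <- function(sel_basic, sel_acidic) {
    nb <- group_atoms(sel_basic, basic_tab)
    oa <- group_atoms(sel_acidic, ACIDIC_GROUP)
    if (length(nb) == 0 || length(oa) == 0) return(NULL)
    D <- pair_distances(xyz[nb, , drop = FALSE], xyz[oa, , drop = FALSE])
    hits <- which(D <= d_cut, arr.ind = TRUE)
    if (nrow(hits) == 0) return(NULL)
    df <- data.frame(
      basic_chain = a$chain[nb[hits[, 1]]], basic_resid = a$resid[nb[hits[, 1]]],
      basic_resname = a$resname[nb[hits[, 1]]],
      acidic_chain = a$chain[oa[hits[, 2]]],
      acidic_resid = a$resid[oa[hits[, 2]]],
      acidic_resname = a$resname[oa[hits[, 2]]],
      distance = D[hits], stringsAsFactors = FALSE)
    # one row per residue pair, at the minimal atom distance
    key <- paste(df$basic_chain, df$basic_resid, df$acidic_chain,
                 df$acidic_resid)
    df <- df[order(key, df$distance), ]
    df <- df[!duplicated(paste(df$basic_chain, df$basic_resid,
                               df$acidic_chain, df$acidic_resid)), ]
    df$type <- paste0(one_letter[df$basic_resname], "->",
                      one_letter[df$acidic_resname])
    df
  }
  res <- rbind(find(dimer$sel_a, dimer$sel_b), find(dimer$sel_b, dimer$sel_a))
  if (is.null(res))
    res <- data.frame(basic_chain = character(0), basic_resid = integer(0),
                      basic_resname = character(0), acidic_chain = character(0),
                      acidic_resid = integer(0), acidic_resname = character(0),
                      distance = numeric(0), type = character(0))
  res[order(res$basic_chain, res$basic_resid), , drop = FALSE]
}

ring_geometry <- function(st, xyz, ch, rs) {
  a <- st$atoms
  rn <- a$resname[which(a$chain == ch & a$resid == rs)[1]]
  names_need <- RING_ATOMS[[rn]]
  if (is.null(names_need)) return(NULL)
  idx <- vapply(names_need, function(nm) {
    i <- which(a$chain == ch & a$resid == rs & a$name == nm)
    if (length(i)) i[1] else NA_integer_
  }, integer(1))
  if (anyNA(idx)) return(NA)
  ring <- xyz[idx, , drop = FALSE]
  ctr <- colMeans(ring)
  sv <- svd(sweep(ring, 2, ctr))
  list(center = ctr, normal = sv$v[, 3])
}

#' Inter-monomer pi-stacking interactions
#'
#' Aromatic residue pairs (His, Phe, Tyr, Trp) whose ring centroids are
#' within `centroid_cut`; the inter-normal angle (folded to \[0, 90\]) is
#' reported and classified parallel (< 45 degrees) or t-shaped. Residues
#' with incomplete rings are skipped with a warning.
#'
#' @param dimer a `DimerModel`.
#' @param centroid_cut ring-centroid distance cutoff (nm).
#' @param frame frame index.
#' @return data.frame: residue pair, centroid distance, normal angle,
#'   `class`.
#' @export
pi_stacking <- function(dimer, centroid_cut = 0.55, frame = 1) {
  st <- dimer$structure; a <- st$atoms
  xyz <- coords(st, frame)
  aromatic <- function(sel) {
    rt <- unique(data.frame(chain = a$chain[sel], resid = a$resid[sel],
                            resname = a$resname[sel]))
    rt[rt$resname %in% names(RING_ATOMS), , drop = FALSE]
  }
  ra <- aromatic(dimer$sel_a); rb <- aromatic(dimer$sel_b)
  out <- NULL
  for (i in seq_len(nrow(ra))) {
    ga <- ring_geometry(st, xyz, ra$chain[i], ra$resid[i])
    if (is.null(ga)) next
    if (!is.list(ga)) {
      warning("incomplete ring for ", ra$resname[i], ra$resid[i], "; skipped")
      next
    }
    for (j in seq_len(nrow(rb))) {
      gb <- ring_geometry(st, xyz, rb$chain[j], rb$resid[j])
      if (is.null(gb)) next
      if (!is.list(gb)) {
        warning("incomplete ring for ", rb$resname[j], rb$resid[j],
                "; skipped")
        next
      }
      d <- sqrt(sum((ga$center - gb$center)^2))
      if (d > centroid_cut) next
      cosang <- abs(sum(ga$normal * gb$normal))
      ang <- acos(max(-1, min(1, cosang))) * 180 / pi
      out <- rbind(out, data.frame(
        chain_a = ra$chain[i], resid_a = ra$resid[i],
        resname_a = ra$resname[i], chain_b = rb$chain[j],
        resid_b = rb$resid[j], resname_b = rb$resname[j],
        centroid_distance = d, normal_angle = ang,
        class = if (ang < 45) "parallel" else "t-shaped",
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(chain_a = character(0), resid_a = integer(0),
                      resname_a = character(0), chain_b = character(0),
                      resid_b = integer(0), resname_b = character(0),
                      centroid_distance = numeric(0), normal_angle = numeric(0),
                      class = character(0))
  out
}

#' Quasi-symmetry of a homodimer interface
#'
#' Jaccard overlap of the interfacial residue-id sets contributed by the two
#' monomers: 1 for a perfectly two-fold-symmetric interface, 0 when the two
#' monomers contribute disjoint residue sets.
#'
#' @param dimer a `DimerModel` (must be a homodimer: identical residue-name
#'   sequences).
#' @param interface_a,interface_b optional precomputed interfacial residue
#'   ids per monomer; computed via [delta_sasa()] when omitted.
#' @param ... passed to [delta_sasa()].
#' @return fraction in \[0, 1\].
#' @export
quasi_symmetry_score <- function(dimer, interface_a = NULL,
                                 interface_b = NULL, ...) {
  a <- dimer$structure$atoms
  seq_of <- function(sel) {
    k <- paste(a$chain[sel], a$resid[sel], sep = "|")
    a$resname[sel][!duplicated(k)]
  }
  if (!identical(seq_of(dimer$sel_a), seq_of(dimer$sel_b)))
    stop("quasi-symmetry is defined for homodimers only")
  if (is.null(interface_a) || is.null(interface_b)) {
    ds <- delta_sasa(dimer, ...)
    interface_a <- interfacial_residues(ds, "A")
    interface_b <- interfacial_residues(ds, "B")
  }
  u <- union(interface_a, interface_b)
  if (length(u) == 0) return(NA_real_)
  length(intersect(interface_a, interface_b)) / length(u)
}

#' Per-frame series summary with running average
#'
#' Summarizes a per-frame metric series: centred running average of
#' configurable window width (partial windows at the edges), plus global
#' mean and standard deviation. The conventional presentation for
#' trajectory-derived interface metrics.
#'
#' @param values numeric per-frame series.
#' @param window running-average window width in frames.
#' @return list with `series`, `running`, `mean`, `sd`, `window`.
#' @export
ensemble_summary <- function(values, window = 1) {
  n <- length(values)
  if (n < 1) stop("need at least one frame")
  if (window > n) {
    warning("window larger than series; using global mean")
    running <- rep(mean(values), n)
  } else {
    half_lo <- floor((window - 1) / 2); half_hi <- floor(window / 2)
    running <- vapply(seq_len(n), function(i) {
      mean(values[max(1, i - half_lo):min(n, i + half_hi)])
    }, numeric(1))
  }
  list(series = values, running = running, mean = mean(values),
       sd = if (n > 1) sd(values) else 0, window = window)
}

#' Full interface report for a dimer (single frame or ensemble)
#'
#' Computes the five standard descriptors plus interaction typing for each
#' frame: hydrogen bonds, hydrophobic contacts, centre-of-mass distance,
#' relative orientation versus the first frame, buried area, interfacial
#' residues, salt bridges, pi-stacks and the quasi-symmetry score.
#'
#' @param dimer a `DimerModel`.
#' @param frames frame indices (default: all).
#' @param probe_radius,n_sphere_points SASA parameters.
#' @param window running-average window for the per-frame series.
#' @return an `InterfaceReport`: list with `per_frame` (data.frame),
#'   `summary` (mean/sd per metric), and first-frame `salt_bridges`,
#'   `pi_stacks`, `interfacial_residues`, `quasi_symmetry`.
#' @export
interface_report <- function(dimer, frames = NULL, probe_radius = 0.14,
                             n_sphere_points = 960, window = 1) {
  if (is.null(frames)) frames <- seq_len(n_frames(dimer$structure))
  ref <- dimer
  rows <- lapply(frames, function(f) {
    ds <- delta_sasa(dimer, probe_radius, n_sphere_points, frame = f)
    data.frame(
      frame = f,
      d_com = com_distance(dimer, frame = f),
      delta = relative_orientation(dimer, ref, frame = f,
                                   ref_frame = frames[1]),
      dsasa = ds$delta_total,
      hb = nrow(hydrogen_bonds(dimer, frame = f)),
      hc = hydrophobic_contacts(dimer, frame = f)$count)
  })
  per_frame <- do.call(rbind, rows)
  summ <- lapply(per_frame[, -1],
                 function(v) c(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0))
  ds1 <- delta_sasa(dimer, probe_radius, n_sphere_points, frame = frames[1])
  structure(list(
    per_frame = per_frame,
    running = lapply(per_frame[, -1], function(v)
      ensemble_summary(v, min(window, nrow(per_frame)))$running),
    summary = summ,
    salt_bridges = salt_bridges(dimer, frame = frames[1]),
    pi_stacks = pi_stacking(dimer, frame = frames[1]),
    interfacial_residues = list(
      A = interfacial_residues(ds1, "A"), B = interfacial_residues(ds1, "B")),
    quasi_symmetry = quasi_symmetry_score(
      dimer, interfacial_residues(ds1, "A"), interfacial_residues(ds1, "B")),
    provenance = dimer$provenance), class = "InterfaceReport")
}

#' @export
print.InterfaceReport <- function(x, ...) {
  s <- x$summary
  cat(sprintf("InterfaceReport (%d frame(s)): d_COM %.2f nm | dSASA %.2f nm^2 | HB %.1f | HC %.1f | %d salt bridge(s)\n",
              nrow(x$per_frame), s$d_com["mean"], s$dsasa["mean"],
              s$hb["mean"], s$hc["mean"], nrow(x$salt_bridges)))
  invisible(x)
}

#' Write an interface report: per-frame TSV and JSON summary
#' @param report an `InterfaceReport`.
#' @param tsv_path,json_path output paths (`NULL` to skip).
#' @return invisibly, the report.
#' @export
write_interface_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    write.table(report$per_frame, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(json_path)) {
    out <- list(summary = report$summary,
                salt_bridges = report$salt_bridges,
                pi_stacks = report$pi_stacks,
                interfacial_residues = report$interfacial_residues,
                quasi_symmetry = report$quasi_symmetry,
                provenance = report$provenance)
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(report)
}
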