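# Clustering of docked homodimer poses and the three empirical viability
# filters: (i) the interface contains reactive (co-evolving or probe-
# predicted) residues and is not made up solely of flexible loops; (ii) the
# effector-binding loop of each protomer stays solvent exposed; (iii) the
# lipid-anchor attachment of each protomer points to the same membrane face.

#' Pose ensemble container
#'
#' @param poses list of `DimerModel`s sharing one monomer topology.
#' @param scores optional per-pose docking score.
#' @return a `PoseEnsemble`.
#' @export
pose_ensemble <- function(poses, scores = NULL) {
  if (length(poses) > 0) {
    n_a <- length(poses[[1]]$sel_a); n_b <- length(poses[[1]]$sel_b)
    for (p in poses)
      if (length(p$sel_a) != n_a || length(p$sel_b) != n_b)
        stop("all poses must share one monomer topology")
  }
  structure(list(poses = poses, scores = scores), class = "PoseEnsemble")
}

#' @export
print.PoseEnsemble <- function(x, ...) {
  cat(sprintf("PoseEnsemble: %d pose(s)\n", length(x$poses)))
  invisible(x)
}

#' Read a pose ensemble from a multi-model PDB or a directory of PDBs
#' @param path multi-MODEL PDB file, or directory of single-pose PDBs.
#' @param chains_a,chains_b monomer chain ids.
#' @return a `PoseEnsemble`.
#' @export
read_pose_ensemble <- function(path, chains_a = "A", chains_b = "B") {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.pdb$", full.names = TRUE))
    poses <- lapply(files, function(f)
      dimer_model(read_structure(f), chains_a, chains_b, provenance = f))
  } else {
    st <- read_structure(path, frame_policy = "all")
    poses <- lapply(seq_len(n_frames(st)), function(f) {
      sf <- st; sf$xyz <- st$xyz[f]
      dimer_model(sf, chains_a, chains_b,
                  provenance = sprintf("%s#%d", path, f))
    })
  }
  pose_ensemble(poses)
}

pose_ca <- function(pose) {
  a <- pose$structure$atoms
  xyz <- coords(pose$structure, 1)
  list(A = xyz[pose$sel_a[a$name[pose$sel_a] == "CA"], , drop = FALSE],
       B = xyz[pose$sel_b[a$name[pose$sel_b] == "CA"], , drop = FALSE])
}

# interface C-alpha RMSD between two poses: superpose one monomer, measure
# over the other; for homodimers take the minimum over the two label
# assignments
pose_rmsd_pair <- function(ca_p, ca_q) {
  one <- function(pa, pb, qa, qb) {
    tf <- kabsch_superpose(pa, qa)
    b <- apply_transform(pb, tf)
    sqrt(mean(rowSums((b - qb)^2)))
  }
  direct <- one(ca_p$A, ca_p$B, ca_q$A, ca_q$B)
  if (nrow(ca_p$A) == nrow(ca_q$B) && nrow(ca_p$B) == nrow(ca_q$A)) {
    swapped <- one(ca_p$A, ca_p$B, ca_q$B, ca_q$A)
    min(direct, swapped)
  } else direct
}

#' Pairwise pose RMSD matrix
#'
#' For each pose pair, monomer A C-alphas are superposed (Kabsch) and the
#' RMSD taken over monomer B C-alphas; homodimer label symmetry is handled
#' by minimizing over the two monomer assignments.
#'
#' @param ensemble a `PoseEnsemble` with >= 2 poses.
#' @return symmetric matrix of RMSDs (nm).
#' @export
pairwise_pose_rmsd <- function(ensemble) {
  n <- length(ensemble$poses)
  if (n < 2) stop("need at least 2 poses")
  cas <- lapply(ensemble$poses, pose_ca)
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      M[i, j] <- M[j, i] <- pose_rmsd_pair(cas[[i]], cas[[j]])
  M
}

#' Greedy-leader clustering of a pose RMSD matrix
#'
#' Leaders are picked in descending neighbourhood-density order (number of
#' poses within `radius`; ties to the lower index); each leader absorbs all
#' unassigned poses within `radius`. Clusters below `min_enrichment`
#' (fraction of the ensemble) are flagged minor. The representative is the
#' member minimizing the summed intra-cluster RMSD (ties to the lowest pose
#' index).
#'
#' @param rmsd_matrix symmetric pose-RMSD matrix (nm).
#' @param radius cluster radius (nm).
#' @param min_enrichment minor-cluster threshold (clusters at or above it
#'   are "major"; the conventional cutoff is 5%).
#' @return a `ClusterSet`: list with `membership` (integer per pose),
#'   `clusters` (data.frame cluster/size/enrichment/representative/minor),
#'   `radius`, `min_enrichment`.
#' @export
cluster_poses <- function(rmsd_matrix, radius = 0.4, min_enrichment = 0.05) {
  if (radius <= 0) stop("radius must be positive")
  M <- as.matrix(rmsd_matrix)
  if (nrow(M) != ncol(M) || max(abs(M - t(M))) > 1e-9)
    stop("need a square symmetric matrix")
  n <- nrow(M)
  membership <- rep(NA_integer_, n)
  density <- rowSums(M <= radius)      # includes self
  cl <- 0L
  while (anyNA(membership)) {
    un <- which(is.na(membership))
    lead <- un[order(-density[un], un)][1]
    cl <- cl + 1L
    members <- un[M[lead, un] <= radius]
    membership[members] <- cl
  }
  clusters <- do.call(rbind, lapply(seq_len(cl), function(k) {
    mem <- which(membership == k)
    rep_idx <- if (length(mem) == 1) mem else {
      intra <- rowSums(M[mem, mem, drop = FALSE])
      mem[order(intra, mem)][1]
    }
    data.frame(cluster = k, size = length(mem),
               enrichment = length(mem) / n, representative = rep_idx)
  }))
  clusters$minor <- clusters$enrichment < min_enrichment
  structure(list(membership = membership, clusters = clusters,
                 radius = radius, min_enrichment = min_enrichment),
            class = "ClusterSet")
}

#' @export
print.ClusterSet <- function(x, ...) {
  cat(sprintf("ClusterSet: %d cluster(s), %d major (enrichment >= %g)\n",
              nrow(x$clusters), sum(!x$clusters$minor), x$min_enrichment))
  invisible(x)
}

filter_result <- function(pass, reasons = character(0)) {
  list(pass = pass, reasons = reasons)
}

#' Viability filter (i): interface composition
#'
#' Passes when the interfacial residue set overlaps the reactive set
#' (co-evolution hotspots or probe-predicted reactive surfaces) and at least
#' one interfacial residue sits in regular secondary structure (helix or
#' strand) — i.e. the interface is not made up solely of flexible loops.
#'
#' @param pose a `DimerModel`.
#' @param hotspots,reactive_surfaces integer residue ids of reactive
#'   positions (shared monomer numbering).
#' @param ss secondary-structure assignment (from
#'   [assign_secondary_structure()]); computed when omitted.
#' @param dsasa precomputed [delta_sasa()] of the pose (computed when
#'   omitted).
#' @param ... passed to [delta_sasa()].
#' @return list with `pass` and `reasons`.
#' @export
filter_interface_composition <- function(pose, hotspots,
                                         reactive_surfaces = integer(0),
                                         ss = NULL, dsasa = NULL, ...) {
  if (is.null(dsasa)) dsasa <- delta_sasa(pose, ...)
  if (is.null(ss)) ss <- assign_secondary_structure(pose$structure)
  iface <- dsasa$per_residue[dsasa$per_residue$interfacial, , drop = FALSE]
  reasons <- character(0)
  reactive <- union(hotspots, reactive_surfaces)
  if (length(intersect(unique(iface$resid), reactive)) == 0)
    reasons <- c(reasons, "no reactive residue")
  key <- paste(iface$chain, iface$resid, sep = "|")
  ss_iface <- ss$ss[match(key, paste(ss$chain, ss$resid, sep = "|"))]
  if (nrow(iface) == 0 || !any(ss_iface %in% c("helix", "strand"),
                               na.rm = TRUE))
    reasons <- c(reasons, "loop-only")
  filter_result(length(reasons) == 0, reasons)
}

#' Viability filter (ii): effector-loop exposure
#'
#' Passes when the mean relative SASA of the effector-binding loop, computed
#' in the dimer context, is at least `exposure_cut` for both protomers.
#'
#' @param pose a `DimerModel`.
#' @param effector_loop residue-id range of the loop (shared numbering;
#'   the switch I region 25-40 is the conventional default).
#' @param exposure_cut mean relative-SASA threshold.
#' @param ... passed to [residue_exposure()].
#' @return list with `pass`, `reasons`, and per-protomer mean exposure.
#' @export
filter_effector_exposure <- function(pose, effector_loop = 25:40,
                                     exposure_cut = 0.25, ...) {
  st <- pose$structure
  ctx <- c(pose$sel_a, pose$sel_b)
  means <- vapply(list(A = pose$sel_a, B = pose$sel_b), function(sel) {
    loop <- sel[st$atoms$resid[sel] %in% effector_loop]
    if (length(loop) == 0) stop("effector loop outside structure")
    mean(residue_exposure(st, sel = loop, context = ctx, ...)$rel_area)
  }, numeric(1))
  reasons <- character(0)
  if (any(means < exposure_cut))
    reasons <- sprintf("effector loop buried (monomer %s: %.2f)",
                       names(means)[means < exposure_cut],
                       means[means < exposure_cut])
  out <- filter_result(all(means >= exposure_cut), reasons)
  out$exposure <- means
  out
}

#' Viability filter (iii): membrane competence of the lipid anchors
#'
#' Passes when both protomers' anchor-residue C-alphas lie on the same side
#' of the best-fit plane through the dimer's C-alphas (so both anchors can
#' insert into one membrane) and both anchor residues are solvent exposed.
#'
#' @param pose a `DimerModel`.
#' @param anchor_resid residue id of the C-terminal anchor attachment
#'   (shared numbering).
#' @param exposure_cut relative-SASA threshold for the anchor residues.
#' @param ... passed to [residue_exposure()].
#' @return list with `pass`, `reasons`, signed plane distances.
#' @export
filter_membrane_competence <- function(pose, anchor_resid,
                                       exposure_cut = 0.25, ...) {
  st <- pose$structure; a <- st$atoms
  xyz <- coords(st, 1)
  all_ca <- c(pose$sel_a, pose$sel_b)
  all_ca <- all_ca[a$name[all_ca] == "CA"]
  ctr <- colMeans(xyz[all_ca, , drop = FALSE])
  nrm <- svd(sweep(xyz[all_ca, , drop = FALSE], 2, ctr))$v[, 3]
  side <- vapply(list(A = pose$sel_a, B = pose$sel_b), function(sel) {
    i <- sel[a$resid[sel] == anchor_resid & a$name[sel] == "CA"]
    if (length(i) == 0) stop("anchor residue ", anchor_resid, " missing")
    sum((xyz[i[1], ] - ctr) * nrm)
  }, numeric(1))
  ctx <- c(pose$sel_a, pose$sel_b)
  expo <- vapply(list(A = pose$sel_a, B = pose$sel_b), function(sel) {
    anc <- sel[a$resid[sel] == anchor_resid]
    mean(residue_exposure(st, sel = anc, context = ctx, ...)$rel_area)
  }, numeric(1))
  reasons <- character(0)
  if (prod(side) < 0)
    reasons <- c(reasons, "anchors on opposite faces")
  if (any(expo < exposure_cut))
    reasons <- c(reasons, sprintf("anchor buried (monomer %s)",
                                  names(expo)[expo < exposure_cut]))
  out <- filter_result(length(reasons) == 0, reasons)
  out$side <- side; out$exposure <- expo
  out
}

#' Apply the three viability filters to cluster representatives
#'
#' Minor clusters (below the enrichment cutoff) are eliminated outright
#' unless promoted explicitly; each remaining representative pose is run
#' through filters (i)-(iii) and survives only if all pass. The audit table
#' records every cluster, each filter verdict and the reason strings.
#'
#' @param clusters a `ClusterSet`.
#' @param ensemble the `PoseEnsemble` that was clustered.
#' @param hotspots,reactive_surfaces reactive residue ids (filter i).
#' @param effector_loop loop residue ids (filter ii).
#' @param anchor_resid anchor residue id (filter iii).
#' @param promote integer cluster ids to evaluate despite being minor
#'   (the manual promotion used when an independent docking run supports a
#'   minor cluster).
#' @param exposure_cut shared relative-SASA threshold.
#' @param n_sphere_points SASA lattice density for the filters.
#' @return a `FilterAudit`: list with `audit` (data.frame), `survivors`
#'   (cluster ids), `poses` (surviving representative `DimerModel`s).
#' @export
apply_filters <- function(clusters, ensemble, hotspots,
                          reactive_surfaces = integer(0),
                          effector_loop = 25:40, anchor_resid = NULL,
                          promote = integer(0), exposure_cut = 0.25,
                          n_sphere_points = 240) {
  cl <- clusters$clusters
  if (nrow(cl) == 0 || length(ensemble$poses) == 0) {
    return(structure(list(
      audit = data.frame(), survivors = integer(0), poses = list()),
      class = "FilterAudit"))
  }
  rows <- list(); survivors <- integer(0); pose_out <- list()
  for (k in seq_len(nrow(cl))) {
    cid <- cl$cluster[k]
    eligible <- !cl$minor[k] || cid %in% promote
    verdicts <- c(composition = NA, effector = NA, membrane = NA)
    reasons <- character(0)
    if (!eligible) {
      reasons <- sprintf("minor cluster (enrichment %.3f < %.2f)",
                         cl$enrichment[k], clusters$min_enrichment)
    } else {
      pose <- ensemble$poses[[cl$representative[k]]]
      ds <- delta_sasa(pose, n_sphere_points = n_sphere_points)
      f1 <- filter_interface_composition(pose, hotspots, reactive_surfaces,
                                         dsasa = ds)
      f2 <- filter_effector_exposure(pose, effector_loop, exposure_cut,
                                     n_sphere_points = n_sphere_points)
      f3 <- if (is.null(anchor_resid)) filter_result(TRUE) else
        filter_membrane_competence(pose, anchor_resid, exposure_cut,
                                   n_sphere_points = n_sphere_points)
      verdicts <- c(composition = f1$pass, effector = f2$pass,
                    membrane = f3$pass)
      reasons <- c(f1$reasons, f2$reasons, f3$reasons)
      if (all(verdicts)) {
        survivors <- c(survivors, cid)
        pose_out[[length(pose_out) + 1]] <- pose
      }
    }
    rows[[k]] <- data.frame(
      cluster = cid, size = cl$size[k], enrichment = cl$enrichment[k],
      minor = cl$minor[k], representative = cl$representative[k],
      composition = verdicts["composition"], effector = verdicts["effector"],
      membrane = verdicts["membrane"],
      survived = eligible && isTRUE(all(verdicts)),
      reasons = paste(reasons, collapse = "; "),
      stringsAsFactors = FALSE)
  }
  audit <- do.call(rbind, rows)
  rownames(audit) <- NULL
  if (length(survivors) == 0 && all(cl$minor))
    warning("all clusters are minor; zero survivors")
  structure(list(audit = audit, survivors = survivors, poses = pose_out),
            class = "FilterAudit")
}

#' @export
print.FilterAudit <- function(x, ...) {
  cat(sprintf("FilterAudit: %d cluster(s), %d survivor(s)\n",
              nrow(x$audit), length(x$survivors)))
  invisible(x)
}

#' Read a residue-list file (one id per line)
#' @param path file path.
#' @return integer vector.
#' @export
read_residue_list <- function(path) {
  as.integer(readLines(path, warn = FALSE))
}

#' Write a filter audit table as TSV
#' @param audit a `FilterAudit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_audit_tsv <- function(audit, path) {
  write.table(audit$audit, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
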