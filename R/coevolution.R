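# Residue co-evolution scoring from an MSA (mutual information with average
# product correction, z-standardized), reading of precomputed coupling
# tables, and hotspot mapping onto structure. The standardized scale makes a
# ">2.0" hotspot threshold meaningful across alignments.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "-")

new_msa <- function(aln) {
  stopifnot(is.matrix(aln), nrow(aln) >= 1)
  aln <- toupper(aln)
  aln[aln == "."] <- "-"
  aln[!(aln %in% AA_ALPHABET)] <- "-"   # unknowns treated as gaps
  if (is.null(rownames(aln))) rownames(aln) <- sprintf("seq%d", seq_len(nrow(aln)))
  structure(list(ids = rownames(aln), aln = unname(aln)), class = "MSA")
}

#' @export
print.MSA <- function(x, ...) {
  cat(sprintf("MSA: %d sequences x %d columns\n", nrow(x$aln), ncol(x$aln)))
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' Aligned FASTA or Stockholm, auto-detected from the first line (a
#' `# STOCKHOLM` header) unless given. Rows are uppercased and `.` gaps
#' normalized to `-`; Stockholm annotation lines are skipped.
#'
#' @param path alignment file.
#' @param format `"auto"`, `"fasta"` or `"stockholm"`.
#' @return an `MSA`.
#' @export
read_msa <- function(path, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (grepl("^#\\s*STOCKHOLM", first)) "stockholm" else "fasta"
  }
  obj <- tryCatch(
    Biostrings::readAAMultipleAlignment(path, format = format),
    error = function(e) stop("ragged or unreadable alignment in '", path,
                             "': ", conditionMessage(e)))
  rows <- as.character(Biostrings::unmasked(obj))
  m <- do.call(rbind, strsplit(rows, ""))
  rownames(m) <- names(rows)
  new_msa(m)
}

#' Write an MSA as aligned FASTA
#' @param msa an `MSA`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  rows <- apply(msa$aln, 1, paste, collapse = "")
  writeLines(as.vector(rbind(paste0(">", msa$ids), rows)), path)
  invisible(path)
}

#' Co-evolution scores from an MSA (MI + APC, z-standardized)
#'
#' Column-pair mutual information from sequence-weighted frequencies with
#' pseudocounts, corrected by the average-product correction
#' `APC_ij = mean_i(MI) * mean_j(MI) / mean(MI)` and standardized to
#' z-scores over all unmasked pairs. Sequences are weighted by the inverse
#' of their neighbourhood size at the identity threshold; columns with gap
#' fraction above `max_gap` are masked.
#'
#' @param msa an `MSA` (>= 2 sequences).
#' @param seq_id_cutoff identity threshold for sequence weighting.
#' @param pseudocount total pseudocount per symbol (lambda).
#' @param max_gap mask columns with more than this gap fraction.
#' @return a `CoevolutionMap`: list with `score` (z-score matrix), `mi`,
#'   `apc`, `masked` (logical per column), `n_eff`, and an empty residue
#'   mapping to be filled by [map_hotspots()].
#' @export
coevolution_scores <- function(msa, seq_id_cutoff = 0.8, pseudocount = 0.5,
                               max_gap = 0.5) {
  aln <- msa$aln
  n <- nrow(aln); L <- ncol(aln)
  if (n < 2) stop("need at least 2 sequences")
  q <- length(AA_ALPHABET)
  code <- matrix(match(aln, AA_ALPHABET), n, L)

  # one-hot encoding, n x (L*q)
  X <- matrix(0, n, L * q)
  X[cbind(rep(seq_len(n), L),
          (rep(seq_len(L), each = n) - 1) * q + as.vector(code))] <- 1

  # sequence weights: 1 / #neighbours at >= seq_id_cutoff identity
  ident <- tcrossprod(X) / L
  w <- 1 / rowSums(ident >= seq_id_cutoff)
  n_eff <- sum(w)

  gap_frac <- colSums((code == q) * w) / n_eff
  masked <- gap_frac > max_gap
  if (all(masked)) stop("all columns masked (gap fraction > ", max_gap, ")")

  # all pairwise joint counts in one product: (L*q) x (L*q)
  C <- crossprod(X, X * w)
  lam <- pseudocount
  mi <- matrix(NA_real_, L, L)
  for (i in seq_len(L - 1)) {
    if (masked[i]) next
    bi <- ((i - 1) * q + 1):(i * q)
    for (j in (i + 1):L) {
      if (masked[j]) next
      bj <- ((j - 1) * q + 1):(j * q)
      joint <- (C[bi, bj] + lam / q) / (n_eff + lam * q)
      fi <- rowSums(joint); fj <- colSums(joint)
      pos <- joint > 0
      mi[i, j] <- mi[j, i] <-
        sum(joint[pos] * log(joint[pos] / outer(fi, fj)[pos]))
    }
  }

  ok <- !masked
  mi_mean_i <- rowMeans(mi[, ok, drop = FALSE], na.rm = TRUE)
  mi_mean <- mean(mi[ok, ok][upper.tri(mi[ok, ok])], na.rm = TRUE)
  apc <- outer(mi_mean_i, mi_mean_i) / mi_mean
  corrected <- mi - apc
  vals <- corrected[upper.tri(corrected)]
  vals <- vals[!is.na(vals)]
  z <- (corrected - mean(vals)) / sd(vals)
  diag(z) <- NA
  structure(list(score = z, mi = mi, apc = apc, masked = masked,
                 n_eff = n_eff, n_col = L, mapping = NULL),
            class = "CoevolutionMap")
}

#' @export
print.CoevolutionMap <- function(x, ...) {
  cat(sprintf("CoevolutionMap: %d columns (%d masked), top z = %.2f\n",
              x$n_col, sum(x$masked), max(x$score, na.rm = TRUE)))
  invisible(x)
}

#' Top-ranked column pairs of a CoevolutionMap
#' @param cmap a `CoevolutionMap`.
#' @param n number of pairs.
#' @return data.frame `i`, `j`, `score`, descending.
#' @export
top_pairs <- function(cmap, n = 10) {
  sc <- cmap$score
  sc[lower.tri(sc, diag = TRUE)] <- NA
  ord <- order(sc, decreasing = TRUE, na.last = NA)
  ij <- arrayInd(ord[seq_len(min(n, length(ord)))], dim(sc))
  data.frame(i = ij[, 1], j = ij[, 2], score = sc[ij])
}

#' Read a precomputed residue-coupling score table
#'
#' Three-column TSV (`i`, `j`, `score`) of pair scores from an external
#' co-evolution tool. The table is symmetrized; pairs listed in both
#' orientations must agree; missing pairs stay absent (NA), not zero.
#'
#' @param path TSV file (header optional).
#' @param n_col alignment length (default: max index present).
#' @return a `CoevolutionMap` (with `mi`/`apc` absent).
#' @export
read_coupling_table <- function(path, n_col = NULL) {
  first <- strsplit(readLines(path, n = 1), "[[:space:]]+")[[1]]
  has_header <- suppressWarnings(any(is.na(as.numeric(first[1:2]))))
  d <- read.table(path, header = has_header, sep = "")
  names(d)[1:3] <- c("i", "j", "score")
  d$i <- as.integer(d$i); d$j <- as.integer(d$j)
  if (any(d$i < 1) || any(d$j < 1)) stop("indices must be positive")
  L <- if (is.null(n_col)) max(d$i, d$j) else n_col
  if (max(d$i, d$j) > L) stop("index exceeds alignment length ", L)
  sc <- matrix(NA_real_, L, L)
  for (k in seq_len(nrow(d))) {
    i <- d$i[k]; j <- d$j[k]
    if (i == j) next
    if (!is.na(sc[i, j]) && abs(sc[i, j] - d$score[k]) > 1e-9)
      stop("conflicting duplicate entries for pair (", i, ", ", j, ")")
    sc[i, j] <- sc[j, i] <- d$score[k]
  }
  structure(list(score = sc, mi = NULL, apc = NULL,
                 masked = rep(FALSE, L), n_eff = NA_real_, n_col = L,
                 mapping = NULL),
            class = "CoevolutionMap")
}

# ungapped consensus (most frequent non-gap symbol per column)
msa_consensus <- function(msa) {
  apply(msa$aln, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0) return("-")
    names(sort(table(col), decreasing = TRUE))[1]
  })
}

#' Map alignment columns to structure residues
#'
#' Slides the ungapped MSA consensus along the structure's one-letter
#' sequence and picks the offset with the fewest mismatches; more than
#' `max_mismatch` mismatch fraction aborts. An explicit `offset` (structure
#' resid of column 1) skips the search.
#'
#' @param cmap a `CoevolutionMap`.
#' @param structure a `Structure`.
#' @param msa the `MSA` the map came from (for the consensus); not needed
#'   when `offset` is given.
#' @param chain chain to map onto.
#' @param offset author resid corresponding to alignment column 1.
#' @param max_mismatch allowed mismatch fraction in consensus matching.
#' @return the `CoevolutionMap` with `mapping` set (data.frame `column`,
#'   `chain`, `resid`).
#' @export
map_columns <- function(cmap, structure, msa = NULL, chain = NULL,
                        offset = NULL, max_mismatch = 0.05) {
  rt <- residue_table(structure)
  if (!is.null(chain)) rt <- rt[rt$chain == chain, , drop = FALSE]
  if (is.null(offset)) {
    if (is.null(msa)) stop("need the MSA (or an explicit offset) to map columns")
    cons <- msa_consensus(msa)
    seq1 <- bio3d::aa321(rt$resname)
    L <- length(cons)
    if (L > length(seq1)) stop("alignment longer than structure sequence")
    best <- NULL; best_mm <- Inf
    for (s in 0:(length(seq1) - L)) {
      mm <- sum(cons != seq1[(s + 1):(s + L)] & cons != "-")
      if (mm < best_mm) { best_mm <- mm; best <- s }
    }
    if (best_mm / L > max_mismatch)
      stop(sprintf("consensus/structure mismatch %.0f%% exceeds %.0f%%",
                   100 * best_mm / L, 100 * max_mismatch))
    idx <- (best + 1):(best + L)
  } else {
    start <- match(offset, rt$resid)
    if (is.na(start)) stop("offset resid ", offset, " not in structure")
    idx <- start:(start + cmap$n_col - 1)
    if (max(idx) > nrow(rt)) stop("mapping runs past the end of the chain")
  }
  cmap$mapping <- data.frame(column = seq_len(cmap$n_col),
                             chain = rt$chain[idx], resid = rt$resid[idx],
                             stringsAsFactors = FALSE)
  cmap
}

#' Surface co-evolution hotspots mapped onto a structure
#'
#' A residue is a hotspot when its best pair score strictly exceeds
#' `score_cut` and it is solvent exposed (relative SASA at least
#' `exposure_cut`). Unmappable columns are reported in the result, not
#' fatal.
#'
#' @param cmap a `CoevolutionMap` with a column mapping (see
#'   [map_columns()]).
#' @param structure a `Structure`.
#' @param exposure per-residue exposure from [residue_exposure()]; computed
#'   on the full structure when omitted.
#' @param score_cut hotspot score threshold (strict `>`).
#' @param exposure_cut relative-SASA exposure threshold (inclusive).
#' @return data.frame: `column`, `chain`, `resid`, `score` (per-residue max),
#'   `rel_sasa`, `hotspot`.
#' @export
map_hotspots <- function(cmap, structure, exposure = NULL, score_cut = 2.0,
                         exposure_cut = 0.25) {
  if (is.null(cmap$mapping))
    stop("CoevolutionMap has no column mapping; call map_columns() first")
  if (is.null(exposure)) exposure <- residue_exposure(structure)
  per_col <- apply(cmap$score, 1, function(v) {
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  })
  m <- cmap$mapping
  key <- paste(m$chain, m$resid, sep = "|")
  ekey <- paste(exposure$chain, exposure$resid, sep = "|")
  rel <- exposure$rel_area[match(key, ekey)]
  unmapped <- is.na(rel)
  if (any(unmapped))
    message(sum(unmapped), " column(s) could not be mapped to residues")
  data.frame(column = m$column, chain = m$chain, resid = m$resid,
             score = per_col, rel_sasa = rel,
             hotspot = !is.na(per_col) & !unmapped & per_col > score_cut &
               rel >= exposure_cut,
             stringsAsFactors = FALSE)
}

#' Write pair scores and hotspot calls as TSV
#' @param cmap a `CoevolutionMap`.
#' @param hotspots output of [map_hotspots()] (optional).
#' @param pairs_path,hotspots_path output paths (`NULL` to skip).
#' @return invisibly, `NULL`.
#' @export
write_coevolution_tsv <- function(cmap, hotspots = NULL, pairs_path = NULL,
                                  hotspots_path = NULL) {
  if (!is.null(pairs_path)) {
    sc <- cmap$score
    ut <- which(upper.tri(sc) & !is.na(sc), arr.ind = TRUE)
    d <- data.frame(i = ut[, 1], j = ut[, 2], score = sc[ut])
    write.table(d[order(-d$score), ], pairs_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(hotspots) && !is.null(hotspots_path))
    write.table(hotspots, hotspots_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(NULL)
}
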