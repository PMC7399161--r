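## pcc: outer-membrane porin candidates and porin-cytochrome complex (PCC)
## calling.
##
## Porin families are modeled as position-specific log-odds profiles built
## from aligned seed sets (one per family: MtrB, OmbB, ExtB/E, ExtI).
## Candidate calling scores each protein against the profile by local
## alignment with affine gaps and compares the score with a null of
## within-sequence residue shuffles; transmembrane beta-strand counts come
## from an alternating-hydropathy heuristic unless an override table is
## supplied. A PCC is a passing porin with at least one MHC within a small
## gene-neighborhood window on the same scaffold.

#' Build a porin family profile
#'
#' Converts an aligned seed set into per-column log-odds over the 20
#' standard residues, with +1 pseudocount per residue per column. The
#' background is the seed-set mean residue composition mixed 50/50 with the
#' uniform distribution; columns with more than 50% gaps are dropped.
#'
#' @param family family label (e.g. `"MtrB"`, `"OmbB"`, `"ExtB/E"`, `"ExtI"`).
#' @param seed_alignment named character vector of aligned sequences
#'   (equal lengths, `-` for gaps), or a path to an aligned FASTA.
#' @return a `porin_profile`: list with `family`, `pssm` (columns x 20),
#'   `seed_ids`, `seed_self_scores`.
#' @export
build_porin_profile <- function(family, seed_alignment) {
  if (is.character(seed_alignment) && length(seed_alignment) == 1 &&
      file.exists(seed_alignment)) {
    ss <- Biostrings::readBStringSet(seed_alignment)
    seed_alignment <- stats::setNames(toupper(as.character(ss)),
                                      sub("\\s.*$", "", names(ss)))
  }
  if (length(seed_alignment) < 2) stop("need at least 2 aligned seed sequences")
  w <- unique(nchar(seed_alignment))
  if (length(w) != 1) stop("seed sequences are not aligned (ragged lengths)")
  mat <- do.call(rbind, strsplit(seed_alignment, ""))
  keep <- colMeans(mat == "-") <= 0.5
  mat <- mat[, keep, drop = FALSE]
  comp <- table(factor(mat[mat != "-"], levels = AA20))
  bg <- 0.5 * (as.numeric(comp) / sum(comp)) + 0.5 / 20
  pssm <- t(apply(mat, 2, function(col) {
    col <- col[col != "-"]
    cnt <- table(factor(col, levels = AA20))
    p <- (as.numeric(cnt) + 1) / (length(col) + 20)
    log2(p / bg)
  }))
  colnames(pssm) <- AA20
  prof <- structure(list(family = family, pssm = pssm,
                         seed_ids = names(seed_alignment),
                         seed_self_scores = NULL),
                    class = "porin_profile")
  prof$seed_self_scores <- vapply(seed_alignment, function(s)
    profile_score(gsub("-", "", s), prof), 0.0)
  prof
}

#' @export
print.porin_profile <- function(x, ...) {
  cat(sprintf("porin_profile '%s': %d columns, %d seeds (self-scores %.1f-%.1f)\n",
              x$family, nrow(x$pssm), length(x$seed_ids),
              min(x$seed_self_scores), max(x$seed_self_scores)))
  invisible(x)
}

#' Score one protein against a porin profile
#'
#' Best local alignment score of the sequence against the profile, with
#' affine gap penalties.
#'
#' @param residues residue string.
#' @param profile a [build_porin_profile()] object.
#' @param gap_open,gap_ext affine gap penalties.
#' @return numeric score.
#' @export
profile_score <- function(residues, profile, gap_open = 10, gap_ext = 1) {
  .pssm_local_score(aa_encode(residues), profile$pssm, gap_open, gap_ext)
}

#' Search a protein set for porin family homologs
#'
#' A protein is a candidate when its profile score is at least `z_min`
#' standard deviations above the mean score of `n_shuffles` within-sequence
#' residue shuffles (a composition- and length-matched null). TM strand
#' counts are estimated with [estimate_tm_strands()] unless `tm_override`
#' (data.frame or TSV: protein_id, count) supplies them.
#'
#' @param profile a `porin_profile`.
#' @param proteins a [protein_set()].
#' @param n_shuffles shuffles per protein (>= 20).
#' @param z_min z-score threshold.
#' @param rng_seed seed making the shuffle null reproducible.
#' @param tm_override optional TM-strand count table; always wins over the
#'   heuristic.
#' @param tm_min minimum predicted transmembrane beta strands.
#' @param gap_open,gap_ext affine gap penalties.
#' @return data.frame of candidates (protein_id, family, score, shuffle_z,
#'   tm_strands, passes_tm).
#' @export
porin_search <- function(profile, proteins, n_shuffles = 200L, z_min = 6,
                         rng_seed = NULL, tm_override = NULL, tm_min = 14L,
                         gap_open = 10, gap_ext = 1) {
  if (n_shuffles < 20) stop("n_shuffles must be at least 20")
  if (nrow(proteins) == 0)
    return(data.frame(protein_id = character(), family = character(),
                      score = numeric(), shuffle_z = numeric(),
                      tm_strands = integer(), passes_tm = logical()))
  if (!is.null(tm_override)) {
    if (is.character(tm_override)) tm_override <- utils::read.delim(tm_override)
    names(tm_override)[1:2] <- c("protein_id", "count")
  }
  with_seed(rng_seed, {
    rows <- lapply(seq_len(nrow(proteins)), function(i) {
      enc <- aa_encode(proteins$seq[i])
      sc <- .pssm_local_score(enc, profile$pssm, gap_open, gap_ext)
      shuf <- matrix(0L, nrow = n_shuffles, ncol = length(enc))
      for (r in seq_len(n_shuffles)) shuf[r, ] <- sample(enc)
      null <- .pssm_local_scores_batch(shuf, profile$pssm, gap_open, gap_ext)
      s <- stats::sd(null)
      z <- if (is.na(s) || s == 0) ifelse(sc > mean(null), Inf, 0) else (sc - mean(null)) / s
      data.frame(protein_id = proteins$id[i], family = profile$family,
                 score = sc, shuffle_z = z, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[out$shuffle_z >= z_min, , drop = FALSE]
    tm <- integer(nrow(out))
    for (i in seq_len(nrow(out))) {
      ov <- if (!is.null(tm_override)) match(out$protein_id[i], tm_override$protein_id) else NA
      tm[i] <- if (!is.na(ov)) as.integer(tm_override$count[ov])
               else estimate_tm_strands(proteins$seq[match(out$protein_id[i], proteins$id)])
    }
    out$tm_strands <- tm
    out$passes_tm <- out$tm_strands >= tm_min
    rownames(out) <- NULL
    out
  })
}

#' Estimate transmembrane beta-strand count
#'
#' A heuristic stand-in for a dedicated beta-barrel topology predictor:
#' membrane-spanning strands of a barrel alternate lipid-facing hydrophobic
#' and lumen-facing polar residues, so the alternating-hydropathy statistic
#' `A(i)` (mean over a 9-residue window centered at i of normalized
#' Kyte-Doolittle hydropathy times (-1)^offset) is large in magnitude inside
#' strands. Strands are maximal runs of positions with |A| at or above 0.6
#' of length at least 5, merging runs separated by fewer than 3 positions.
#' Supplied override tables should always be preferred on real data.
#'
#' @param residues residue string (length >= 50 for a meaningful count).
#' @return integer strand count; for sequences shorter than 50 the count is
#'   0 with attribute `too_short = TRUE`.
#' @export
estimate_tm_strands <- function(residues) {
  L <- nchar(residues)
  if (L < 50) return(structure(0L, too_short = TRUE))
  h <- KD_HYDROPATHY[strsplit(residues, "")[[1]]]
  h[is.na(h)] <- 0
  centers <- 5:(L - 4)
  signs <- rep_len(c(1, -1), 9)
  A <- vapply(centers, function(i) mean(h[(i - 4):(i + 4)] * signs), 0.0)
  flag <- abs(A) >= 0.6
  if (!any(flag)) return(0L)
  r <- rle(flag)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  merged <- runs[1, , drop = FALSE]
  for (k in seq_len(nrow(runs))[-1]) {
    if (runs$start[k] - merged$end[nrow(merged)] - 1L < 3L)
      merged$end[nrow(merged)] <- runs$end[k]
    else merged <- rbind(merged, runs[k, ])
  }
  sum(merged$end - merged$start + 1L >= 5L)
}

#' Call porin-cytochrome complexes
#'
#' Pairs each TM-passing porin candidate with the MHCs (>= 3 heme motifs)
#' found within `max_intervening` intervening genes on the same scaffold.
#' Strand agreement is not required.
#'
#' @param genes a `gene_calls` table covering porins and MHCs.
#' @param porin_candidates [porin_search()] output (possibly several
#'   families row-bound).
#' @param profiles [mhc_profiles()] for the same proteins.
#' @param max_intervening window: maximum intervening gene count.
#' @return data.frame, one row per cluster: scaffold_id, porin_id, family,
#'   score, shuffle_z, tm_strands, mhc_ids (comma-separated), mhc_hemes
#'   (comma-separated), n_mhc, gene_gap (intervening genes to nearest MHC).
#' @export
call_pcc <- function(genes, porin_candidates, profiles, max_intervening = 2L) {
  empty <- data.frame(scaffold_id = character(), porin_id = character(),
                      family = character(), score = numeric(),
                      shuffle_z = numeric(), tm_strands = integer(),
                      mhc_ids = character(), mhc_hemes = character(),
                      n_mhc = integer(), gene_gap = integer(),
                      stringsAsFactors = FALSE)
  cand <- porin_candidates[porin_candidates$passes_tm, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  gidx <- match(cand$protein_id, genes$gene_id)
  mhc_ids <- profiles$protein_id[profiles$is_mhc]
  mh <- genes[genes$gene_id %in% mhc_ids, , drop = FALSE]
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    gi <- gidx[i]
    if (is.na(gi)) return(NULL)
    near <- mh[mh$scaffold_id == genes$scaffold_id[gi] &
               abs(mh$ordinal - genes$ordinal[gi]) - 1L <= max_intervening &
               mh$gene_id != genes$gene_id[gi], , drop = FALSE]
    if (nrow(near) == 0) return(NULL)
    gaps <- abs(near$ordinal - genes$ordinal[gi]) - 1L
    hemes <- profiles$n_motifs[match(near$gene_id, profiles$protein_id)]
    data.frame(scaffold_id = genes$scaffold_id[gi], porin_id = cand$protein_id[i],
               family = cand$family[i], score = cand$score[i],
               shuffle_z = cand$shuffle_z[i], tm_strands = cand$tm_strands[i],
               mhc_ids = paste(near$gene_id, collapse = ","),
               mhc_hemes = paste(hemes, collapse = ","),
               n_mhc = nrow(near), gene_gap = min(gaps),
               stringsAsFactors = FALSE)
  })
  rbind_rows(rows, empty)
}
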