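## genomeqc: single-copy-gene completeness, bin scoring, N50, pairwise
## genome similarity and de-replication with representative selection.

SCG_UNIVERSE <- c(bacteria = 51L, archaea = 38L)

#' Single-copy-gene inventory
#'
#' @param bin_id bin identifier.
#' @param domain `"bacteria"` (51-marker universe) or `"archaea"` (38).
#' @param present character vector of marker ids found at least once.
#' @param multiplicity named integer vector of copy counts (markers absent
#'   from it count as single-copy).
#' @return an `scg_inventory` list.
#' @export
scg_inventory <- function(bin_id, domain = c("bacteria", "archaea"),
                          present = character(), multiplicity = integer()) {
  domain <- match.arg(domain)
  present <- unique(as.character(present))
  if (length(present) > SCG_UNIVERSE[[domain]])
    stop("more markers than the ", domain, " universe of ", SCG_UNIVERSE[[domain]])
  if (length(multiplicity) && !all(names(multiplicity) %in% present))
    stop("multiplicity keys must be a subset of present markers")
  structure(list(bin_id = bin_id, domain = domain,
                 universe = SCG_UNIVERSE[[domain]],
                 present = present, multiplicity = multiplicity),
            class = "scg_inventory")
}

#' Read marker-hit table into inventories
#'
#' @param x data.frame or TSV path with columns bin_id, marker_id, gene_id;
#'   multiplicity is inferred from repeated markers per bin.
#' @param domain per-bin domain; a single value or named vector by bin_id.
#' @return named list of [scg_inventory()] objects.
#' @export
read_marker_hits <- function(x, domain = "bacteria") {
  if (is.character(x)) x <- utils::read.delim(x, stringsAsFactors = FALSE)
  names(x)[1:3] <- c("bin_id", "marker_id", "gene_id")
  bins <- unique(x$bin_id)
  out <- lapply(bins, function(b) {
    sub <- x[x$bin_id == b, ]
    cnt <- table(sub$marker_id)
    dom <- if (length(domain) == 1) domain else domain[[b]]
    scg_inventory(b, dom, present = names(cnt),
                  multiplicity = stats::setNames(as.integer(cnt), names(cnt)))
  })
  stats::setNames(out, bins)
}

#' Completeness tier of a genome bin
#'
#' Completeness is the fraction of the domain's single-copy marker universe
#' found in the bin; at least 70% is draft quality and at least 90% is
#' near-complete. The integer cutoffs implied for bacteria (51 markers) are
#' 36 and 46, and for archaea (38 markers) 27 and 35 - the smallest counts
#' meeting each fraction.
#'
#' @param inv an [scg_inventory()].
#' @return list: `completeness`, `tier` (`"near_complete"`, `"draft"`,
#'   `"below"`), `n_present`, `universe`.
#' @export
completeness_tier <- function(inv) {
  stopifnot(inherits(inv, "scg_inventory"))
  comp <- length(inv$present) / inv$universe
  tier <- if (comp >= 0.90) "near_complete" else if (comp >= 0.70) "draft" else "below"
  list(completeness = comp, tier = tier,
       n_present = length(inv$present), universe = inv$universe)
}

#' Genome-bin quality score
#'
#' Score = (number of non-redundant single-copy genes) minus twice the
#' number of single-copy genes present in multiple copies. Used as the
#' primary criterion when choosing a de-replication representative; may be
#' negative.
#'
#' @param inv an [scg_inventory()].
#' @return integer score.
#' @export
bin_score <- function(inv) {
  stopifnot(inherits(inv, "scg_inventory"))
  n_multi <- sum(inv$multiplicity >= 2)
  length(inv$present) - 2L * n_multi
}

#' N50 of a set of contig lengths
#'
#' The smallest length, taking contigs in descending order, at which the
#' running sum first reaches half the total assembly length.
#'
#' @param contig_lengths positive integer vector.
#' @return integer N50.
#' @export
n50 <- function(contig_lengths) {
  if (length(contig_lengths) == 0) stop("no contig lengths")
  stopifnot(all(contig_lengths > 0))
  s <- sort(as.numeric(contig_lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

kmers_of <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

## Align one fragment to its best k-mer-anchored location in a target
## scaffold set. Returns c(matches, aln_len) or NULL when unanchored.
anchor_align <- function(frag, target_kmers, target_seqs, k, band) {
  fl <- nchar(frag)
  probes <- seq(1L, fl - k + 1L, by = 50L)
  fk <- substring(frag, probes, probes + k - 1L)
  best <- NULL
  for (s in seq_along(target_kmers)) {
    hit <- match(fk, target_kmers[[s]])
    if (all(is.na(hit))) next
    diag <- hit - probes
    dtab <- table(diag[!is.na(diag)])
    d <- as.integer(names(dtab)[which.max(dtab)])
    if (is.null(best) || max(dtab) > best$votes)
      best <- list(s = s, d = d, votes = max(dtab))
  }
  if (is.null(best)) return(NULL)
  tseq <- target_seqs[[best$s]]
  lo <- max(1L, best$d + 1L - band)
  hi <- min(nchar(tseq), best$d + fl + band)
  window <- substr(tseq, lo, hi)
  .banded_global_stats(nt_encode(frag), nt_encode(window), band, 1, -1, -2)
}

#' Pairwise genome similarity by fragment-seeded banded alignment
#'
#' The query bin's scaffolds are cut into `frag_len` fragments; each
#' fragment is anchored in the target by exact `k`-mer matches (majority
#' diagonal) and aligned with a banded global alignment (band `band`). A
#' fragment counts as aligned when at least 60% of it aligns at >= 70%
#' identity. `identity_pct` is the aligned-length-weighted mean identity
#' over aligned fragments; `aligned_fraction` is aligned bases over the
#' query's total length. Both directions are evaluated.
#'
#' @param binA,binB named character vectors of scaffold sequences (or
#'   single strings).
#' @param frag_len fragment size (bp).
#' @param k anchor k-mer size.
#' @param band alignment band half-width.
#' @return data.frame with rows `A_vs_B` and `B_vs_A`: identity_pct,
#'   aligned_fraction, n_fragments, n_aligned.
#' @export
genome_similarity <- function(binA, binB, frag_len = 1000L, k = 15L, band = 50L) {
  if (is.null(binA) || is.null(binB) || !length(binA) || !length(binB))
    stop("both bins need nucleotide scaffolds (marker-only mode is not available here)")
  one_dir <- function(qry, tgt) {
    tk <- lapply(tgt, kmers_of, k = k)
    tot <- sum(nchar(qry))
    matches <- 0; alen <- 0; aligned_bases <- 0; nfrag <- 0L; nal <- 0L
    for (scaf in qry) {
      n <- nchar(scaf)
      starts <- seq(1L, n, by = frag_len)
      for (st in starts) {
        frag <- substr(scaf, st, min(n, st + frag_len - 1L))
        if (nchar(frag) < k) next
        nfrag <- nfrag + 1L
        st2 <- anchor_align(frag, tk, tgt, k, band)
        if (is.null(st2)) next
        idt <- st2[1] / st2[2]
        if (idt >= 0.70 && st2[2] >= 0.60 * nchar(frag)) {
          matches <- matches + st2[1]; alen <- alen + st2[2]
          aligned_bases <- aligned_bases + nchar(frag)
          nal <- nal + 1L
        }
      }
    }
    c(identity_pct = if (alen > 0) 100 * matches / alen else 0,
      aligned_fraction = aligned_bases / tot,
      n_fragments = nfrag, n_aligned = nal)
  }
  ab <- one_dir(binA, binB)
  ba <- one_dir(binB, binA)
  out <- as.data.frame(rbind(A_vs_B = ab, B_vs_A = ba))
  out
}

#' De-replicate genome bins
#'
#' Single-linkage clustering over bin pairs that are at least `id_min`
#' percent identical across `cov_min` or more of the query length (either
#' direction passing suffices by default; `both_directions = TRUE` requires
#' both). Estimates are compared with the cutoffs at the precision the
#' cutoffs are stated at (a pair whose true identity sits exactly on the
#' cutoff is not split by sampling noise in digits the rule never names). The representative of each cluster is chosen by, in order:
#' largest [bin_score()], largest [n50()], largest total size, and finally
#' lexicographically smallest bin id.
#'
#' @param bins named list; each element has `$scaffolds` (named character
#'   vector) and optionally `$contig_lengths`.
#' @param inventories named list of [scg_inventory()] aligned with `bins`.
#' @param id_min,cov_min pass thresholds (percent identity; fraction).
#' @param both_directions require both directions to pass.
#' @param pairs optional precomputed pair table (bin_a, bin_b,
#'   identity_ab, fraction_ab, identity_ba, fraction_ba); skips alignment.
#' @param ... passed to [genome_similarity()].
#' @return list of clusters: `members`, `representative`, plus a `pairs`
#'   attribute with all pairwise statistics.
#' @export
dereplicate <- function(bins, inventories, id_min = 98.0, cov_min = 0.70,
                        both_directions = FALSE, pairs = NULL, ...) {
  ids <- names(bins) %||% vapply(bins, function(b) b$bin_id, "")
  if (is.null(pairs)) {
    rows <- list()
    if (length(ids) > 1) {
      for (i in 1:(length(ids) - 1)) for (j in (i + 1):length(ids)) {
        sim <- genome_similarity(bins[[i]]$scaffolds, bins[[j]]$scaffolds, ...)
        rows[[length(rows) + 1L]] <- data.frame(
          bin_a = ids[i], bin_b = ids[j],
          identity_ab = sim["A_vs_B", "identity_pct"],
          fraction_ab = sim["A_vs_B", "aligned_fraction"],
          identity_ba = sim["B_vs_A", "identity_pct"],
          fraction_ba = sim["B_vs_A", "aligned_fraction"],
          stringsAsFactors = FALSE)
      }
    }
    pairs <- if (length(rows)) do.call(rbind, rows) else
      data.frame(bin_a = character(), bin_b = character(), identity_ab = numeric(),
                 fraction_ab = numeric(), identity_ba = numeric(), fraction_ba = numeric())
  }
  ## thresholds are applied at the precision they are stated at (98 percent,
  ## 70 percent coverage), so an estimate sitting exactly on the cutoff is
  ## not split by sampling noise in the last unstated digit
  dig <- function(x) {
    s <- sub("0+$", "", sub("^[^.]*\\.?", "", format(x, scientific = FALSE)))
    nchar(s)
  }
  id_est <- function(v) round(v, dig(id_min))
  cov_est <- function(v) round(v, dig(cov_min))
  pass_ab <- id_est(pairs$identity_ab) >= id_min & cov_est(pairs$fraction_ab) >= cov_min
  pass_ba <- id_est(pairs$identity_ba) >= id_min & cov_est(pairs$fraction_ba) >= cov_min
  pairs$pass <- if (both_directions) pass_ab & pass_ba else pass_ab | pass_ba
  g <- igraph::graph_from_data_frame(
    pairs[pairs$pass, c("bin_a", "bin_b"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = ids))
  memb <- igraph::components(g)$membership
  clusters <- lapply(split(names(memb), memb), function(members) {
    score <- vapply(members, function(b) bin_score(inventories[[b]]), 0L)
    nn50 <- vapply(members, function(b) {
      cl <- bins[[b]]$contig_lengths %||% nchar(bins[[b]]$scaffolds)
      as.numeric(n50(cl))
    }, 0.0)
    size <- vapply(members, function(b) {
      cl <- bins[[b]]$contig_lengths %||% nchar(bins[[b]]$scaffolds)
      sum(as.numeric(cl))
    }, 0.0)
    ord <- order(-score, -nn50, -size, members)
    list(members = sort(members), representative = members[ord[1]])
  })
  names(clusters) <- NULL
  attr(clusters, "pairs") <- pairs
  clusters
}
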