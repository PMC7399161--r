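## synthcommunity: generators for proteins, operons, pilins, genome pairs
## and bins with planted ground truth. Every generator is deterministic
## given rng_seed and returns the truth alongside the data, so each
## pipeline stage can be validated by round-trip. Background residue
## distributions are uniform over the permitted alphabet (no codon or GC
## realism) - sufficient for the planted properties exercised here.

## 18 residues: the standard 20 minus C and H, so backgrounds can never
## create or extend heme-binding motifs.
BG18 <- setdiff(AA20, c("C", "H"))
## non-aromatic background for pilins (also excludes C to keep matures inert)
BG_NONAROM <- setdiff(AA20, c(AROMATIC, "C"))

rand_string <- function(n, alphabet) paste(sample(alphabet, n, replace = TRUE), collapse = "")

#' Generate a protein with a planted number of heme-binding motifs
#'
#' Background residues are drawn uniformly from the 18 letters excluding C
#' and H; `n_motifs` motifs C + (2-4 background residues) + C + H are
#' planted at random non-overlapping positions. The construction guarantees
#' the scan recovers exactly `n_motifs` (every H in the sequence terminates
#' a planted motif), and the result is verified by a post-generation scan.
#'
#' @param n_motifs motifs to plant.
#' @param length total protein length (>= 7 * n_motifs).
#' @param rng_seed seed.
#' @param n_x variable-residue counts per motif (2-4; recycled); random
#'   when `NULL`.
#' @return list: `protein` (one-row [protein_set()]), `truth`
#'   (n_motifs, starts, spans).
#' @export
make_mhc_protein <- function(n_motifs, length, rng_seed = NULL, n_x = NULL) {
  if (length < 7 * n_motifs)
    stop("length ", length, " cannot hold ", n_motifs, " motifs (need >= ", 7 * n_motifs, ")")
  if (!is.null(n_x) && !all(n_x %in% 2:4)) stop("n_x must be 2, 3 or 4")
  with_seed(rng_seed, {
    n_x <- if (n_motifs == 0) integer(0)
           else if (!is.null(n_x)) as.integer(rep_len(n_x, n_motifs))
           else sample(2:4, n_motifs, replace = TRUE)
    spans <- n_x + 3L
    slack <- length - sum(spans)
    cuts <- if (n_motifs > 0) sort(sample.int(slack + 1L, n_motifs, replace = TRUE) - 1L)
            else integer(0)
    gaps <- diff(c(0L, cuts))            # background run before each motif
    pieces <- character(0); starts <- integer(0); pos <- 0L
    for (i in seq_len(n_motifs)) {
      pieces <- c(pieces, rand_string(gaps[i], BG18))
      pos <- pos + gaps[i]
      starts <- c(starts, pos + 1L)
      motif <- paste0("C", rand_string(n_x[i], BG18), "CH")
      pieces <- c(pieces, motif)
      pos <- pos + spans[i]
    }
    pieces <- c(pieces, rand_string(length - pos, BG18))
    seqstr <- paste(pieces, collapse = "")
    stopifnot(nchar(seqstr) == length)
    found <- find_heme_motifs(seqstr)
    stopifnot(nrow(found) == n_motifs)
    list(protein = protein_set(seqstr, ids = sprintf("mhc_h%d", n_motifs)),
         truth = list(n_motifs = n_motifs, starts = starts, spans = spans))
  })
}

#' Generate a prepilin with controlled e-pilin criteria
#'
#' Builds a prepilin leader that [detect_prepilin()] cleaves after position
#' 6, followed by a 61-residue mature region with aromatics placed at the
#' key positions 1, 24, 27, 32, 50 and 57 - a configuration that passes
#' every strict criterion. Each element of `violate` then breaks exactly
#' one criterion:
#' `"density"` (window aromatic percentage < 9.8 but full >= 8),
#' `"gap"` (an inter-aromatic gap of 23 with density and flags intact),
#' `"pos1"`, `"pos24"`, `"pos27"`, `"pos50_51"`, `"pos32_57"` (move that
#' aromatic off its key position), `"relaxed"` (density below 8:
#' tier none), `"leader"` (no cleavable prepilin leader).
#'
#' @param violate character vector of criteria to violate (default none).
#' @param rng_seed seed.
#' @return list: `protein` (one-row [protein_set()]), `truth`
#'   (tier, has_leader, aromatic_positions).
#' @export
make_pilin <- function(violate = character(), rng_seed = NULL) {
  bad <- setdiff(violate, c("density", "gap", "pos1", "pos24", "pos27",
                            "pos50_51", "pos32_57", "relaxed", "leader"))
  if (length(bad)) stop("unknown criterion: ", paste(bad, collapse = ", "))
  with_seed(rng_seed, {
    pos <- c(1L, 24L, 27L, 32L, 50L, 57L)
    if ("density" %in% violate) pos <- setdiff(pos, 32L)  # 5/59 = 8.5% < 9.8
    if ("gap" %in% violate) pos <- sort(c(setdiff(pos, c(32L, 50L)), c(8L, 16L, 51L)))
    if ("pos1" %in% violate) pos <- sort(c(setdiff(pos, 1L), 2L))
    if ("pos24" %in% violate) pos <- sort(c(setdiff(pos, 24L), 25L))
    if ("pos27" %in% violate) pos <- sort(c(setdiff(pos, 27L), 28L))
    if ("pos50_51" %in% violate) pos <- sort(c(setdiff(pos, 50L), 52L))
    if ("pos32_57" %in% violate) pos <- sort(c(setdiff(pos, c(32L, 57L)), c(10L, 40L)))
    if ("relaxed" %in% violate) pos <- c(24L, 50L)        # 2/59 = 3.4%
    ## G excluded from the mature background so no spurious cleavage site
    ## can appear when the real leader is absent
    mature <- sample(setdiff(BG_NONAROM, "G"), 61L, replace = TRUE)
    mature[5L] <- "E"                                     # Glu5 of mature pilins
    mature[pos] <- sample(c("F", "W", "Y"), length(pos), replace = TRUE)
    ## mature position 1 must stay compatible with the G|hydrophobic
    ## cleavage heuristic: F when aromatic is required there, L otherwise
    mature[1L] <- if (1L %in% pos) "F" else "L"
    mature <- paste(mature, collapse = "")
    leader <- if ("leader" %in% violate) paste0("M", rand_string(5, c("K", "R", "Q", "N", "D")))
              else "MKKLQG"
    seqstr <- paste0(leader, mature)
    met <- aromatic_metrics(mature)
    tier <- if ("leader" %in% violate) "none"
            else classify_epilin(met, epilin_position_flags(mature))
    list(protein = protein_set(seqstr, ids = paste0("pilin_", paste(c("ok", violate), collapse = "_"))),
         truth = list(tier = tier, has_leader = !("leader" %in% violate),
                      aromatic_positions = met$positions,
                      expected_strict = length(violate) == 0))
  })
}

#' Generate an alternating-hydropathy beta-barrel region
#'
#' Strands are 14 residues alternating hydrophobic (L, V, I, F) and acidic
#' (D, E) residues - the amphipathic pattern of membrane-spanning barrel
#' strands - separated by 8-residue loops of G, N, D, S, T.
#'
#' @param n_strands strand count.
#' @param rng_seed seed.
#' @return residue string.
#' @export
make_tm_barrel <- function(n_strands = 16L, rng_seed = NULL) {
  with_seed(rng_seed, {
    strand <- function() {
      out <- character(14L)
      out[seq(1, 14, 2)] <- sample(c("L", "V", "I", "F"), 7, replace = TRUE)
      out[seq(2, 14, 2)] <- sample(c("D", "E"), 7, replace = TRUE)
      paste(out, collapse = "")
    }
    loop <- function() rand_string(8L, c("G", "N", "D", "S", "T"))
    parts <- character(0)
    for (i in seq_len(n_strands)) {
      parts <- c(parts, strand())
      if (i < n_strands) parts <- c(parts, loop())
    }
    paste(parts, collapse = "")
  })
}

#' Generate a scaffold with a planted porin-cytochrome operon
#'
#' Emits gene calls for a scaffold carrying (in order) filler genes, a
#' porin derived from the first seed of the family alignment (substituted
#' at `mutate_rate`), `gene_gap` filler genes, and `n_mhc` MHC genes. The
#' truth lists the expected cluster membership and the planted TM strand
#' count (feed it to [porin_search()] as `tm_override` when exercising the
#' cluster caller, since the TM heuristic is itself a stand-in).
#'
#' @param family family label; `seed_alignment` as in
#'   [build_porin_profile()].
#' @param seed_alignment aligned seeds the porin is drawn from.
#' @param n_mhc MHC genes planted after the porin.
#' @param tm_strands planted TM strand count (truth; drives pass/fail).
#' @param gene_gap filler genes between porin and first MHC.
#' @param n_filler leading filler genes.
#' @param mhc_motifs motif counts for the MHC genes (recycled).
#' @param mutate_rate substitution rate applied to the seed porin.
#' @param rng_seed seed.
#' @param scaffold_id scaffold name.
#' @return list: `proteins` ([protein_set()]), `genes` (`gene_calls`),
#'   `tm_override` (data.frame), `truth` (porin_id, mhc_ids, expect_cluster,
#'   gene_gap, tm_strands).
#' @export
make_pcc_operon <- function(family, seed_alignment, n_mhc = 1L, tm_strands = 16L,
                            gene_gap = 0L, n_filler = 2L, mhc_motifs = 5L,
                            mutate_rate = 0.10, rng_seed = NULL,
                            scaffold_id = "scaffold_1") {
  if (is.character(seed_alignment) && length(seed_alignment) == 1 &&
      file.exists(seed_alignment)) {
    ss <- Biostrings::readBStringSet(seed_alignment)
    seed_alignment <- stats::setNames(toupper(as.character(ss)),
                                      sub("\\s.*$", "", names(ss)))
  }
  with_seed(rng_seed, {
    porin <- strsplit(gsub("-", "", seed_alignment[[1]]), "")[[1]]
    mut <- stats::runif(length(porin)) < mutate_rate
    porin[mut] <- vapply(which(mut), function(i)
      sample(setdiff(BG18, porin[i]), 1L), "")
    porin <- paste(porin, collapse = "")
    mhc_motifs <- rep_len(mhc_motifs, n_mhc)
    ids <- character(0); seqs <- character(0)
    add <- function(id, s) { ids <<- c(ids, id); seqs <<- c(seqs, s) }
    for (i in seq_len(n_filler)) add(sprintf("%s_f%d", scaffold_id, i), rand_string(200L, BG18))
    porin_id <- paste0(scaffold_id, "_porin")
    add(porin_id, porin)
    for (i in seq_len(gene_gap)) add(sprintf("%s_g%d", scaffold_id, i), rand_string(200L, BG18))
    mhc_ids <- sprintf("%s_mhc%d", scaffold_id, seq_len(n_mhc))
    for (i in seq_len(n_mhc)) {
      mp <- make_mhc_protein(mhc_motifs[i], 60L + 12L * mhc_motifs[i])
      add(mhc_ids[i], mp$protein$seq)
    }
    starts <- 1000L * (seq_along(ids) - 1L) + 1L
    genes <- new_gene_calls(data.frame(
      gene_id = ids, scaffold_id = scaffold_id,
      start = starts, end = starts + 3L * nchar(seqs) - 1L,
      strand = "+", stringsAsFactors = FALSE))
    list(proteins = protein_set(seqs, ids = ids), genes = genes,
         tm_override = data.frame(protein_id = porin_id, count = tm_strands),
         truth = list(porin_id = porin_id, mhc_ids = mhc_ids,
                      expect_cluster = tm_strands >= 14L && n_mhc > 0,
                      gene_gap = gene_gap, tm_strands = tm_strands))
  })
}

#' Generate a genome pair at controlled nucleotide divergence
#'
#' An ancestor sequence uniform over A/C/G/T is copied and mutated per site
#' with probability `d` to a different base (substitutions only); a
#' fraction `f` of the copy can be replaced by unrelated sequence to
#' control the aligned fraction.
#'
#' @param length genome length (bp).
#' @param d per-site substitution probability.
#' @param f fraction of genome B replaced by unrelated sequence.
#' @param rng_seed seed.
#' @return list: `binA`, `binB` (each `list(bin_id, scaffolds,
#'   contig_lengths)`), `truth` (d, f, expected_identity).
#' @export
make_genome_pair <- function(length = 1e5, d = 0.02, f = 0, rng_seed = NULL) {
  with_seed(rng_seed, {
    nt <- c("A", "C", "G", "T")
    anc <- sample(nt, length, replace = TRUE)
    b <- anc
    mut <- stats::runif(length) < d
    b[mut] <- vapply(which(mut), function(i) sample(setdiff(nt, anc[i]), 1L), "")
    if (f > 0) {
      n_rep <- round(f * length)
      b[(length - n_rep + 1L):length] <- sample(nt, n_rep, replace = TRUE)
    }
    a <- paste(anc, collapse = ""); bs <- paste(b, collapse = "")
    list(binA = list(bin_id = "binA", scaffolds = c(sA = a), contig_lengths = length),
         binB = list(bin_id = "binB", scaffolds = c(sB = bs), contig_lengths = length),
         truth = list(d = d, f = f, expected_identity = 100 * (1 - d)))
  })
}

#' Generate a single-copy-gene inventory and bin stub
#'
#' @param domain `"bacteria"` or `"archaea"`.
#' @param n_present markers present (or a character vector of marker ids).
#' @param n_multi how many of the present markers are multi-copy.
#' @param contig_lengths contig lengths for the bin stub.
#' @param bin_id bin name.
#' @param rng_seed seed (which markers are present/multi-copy).
#' @return list: `inventory` ([scg_inventory()]), `bin` (stub with
#'   contig_lengths), `truth` (tier, score, n50).
#' @export
make_bin_inventory <- function(domain = "bacteria", n_present = 40L, n_multi = 0L,
                               contig_lengths = c(50000L, 30000L, 20000L),
                               bin_id = "bin_1", rng_seed = NULL) {
  with_seed(rng_seed, {
    universe <- sprintf("%s_scg_%02d", substr(domain, 1, 3), seq_len(SCG_UNIVERSE[[domain]]))
    present <- if (is.character(n_present)) n_present
               else sample(universe, n_present)
    multi <- sample(present, min(n_multi, length(present)))
    mult <- stats::setNames(rep(2L, length(multi)), multi)
    inv <- scg_inventory(bin_id, domain, present = present, multiplicity = mult)
    list(inventory = inv,
         bin = list(bin_id = bin_id, scaffolds = NULL, contig_lengths = contig_lengths),
         truth = list(tier = completeness_tier(inv)$tier, score = bin_score(inv),
                      n50 = n50(contig_lengths)))
  })
}
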