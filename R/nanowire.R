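## nanowire: type-IV e-pilin screening and OmcS cytochrome homolog filtering.
##
## Conductive "e-pili" carry a high density of aromatic residues (F, W, Y,
## H) in the mature pilin; the strict tier additionally requires tight
## aromatic spacing and aromatics at key mature positions. The prepilin
## cleavage site is found with a class-III signal peptide heuristic
## (G | hydrophobic with E five residues into the mature peptide); an
## override table of cleavage positions is accepted wherever a verified
## call exists.

#' Detect the prepilin cleavage site
#'
#' Returns the leftmost position `i` (6-40) where residue `i` is G, residue
#' `i+1` is small/hydrophobic (F, M, L, I, V, A, S, T), and residue `i+5`
#' is E (the conserved Glu5 of the mature type-IV pilin). The mature pilin
#' starts at `i+1`. `relaxed = TRUE` drops the Glu5 condition.
#'
#' @param residues residue string (length >= 30).
#' @param relaxed drop the E-at-+5 requirement.
#' @return integer cleavage position (last prepilin residue), or `NA` when
#'   no site exists.
#' @export
detect_prepilin <- function(residues, relaxed = FALSE) {
  if (nchar(residues) < 30) return(NA_integer_)
  chars <- strsplit(residues, "")[[1]]
  hyd <- c("F", "M", "L", "I", "V", "A", "S", "T")
  for (i in 6:min(40L, length(chars) - 5L)) {
    if (chars[i] == "G" && chars[i + 1L] %in% hyd &&
        (relaxed || chars[i + 5L] == "E"))
      return(i)
  }
  NA_integer_
}

#' Aromatic metrics of a mature pilin
#'
#' Counts the aromatic residues (F, W, Y, H), computes the aromatic
#' percentage over the assessment window (mature residues 1-59 when the
#' mature sequence is at least 59 residues, otherwise the whole mature
#' sequence), and the largest run of non-aromatic residues strictly between
#' successive aromatics (terminal flanks excluded). With no aromatics the
#' gap is defined as the mature length; with one aromatic it is 0.
#'
#' @param mature mature pilin residue string.
#' @return list: `aromatic_count`, `mature_length`, `aromatic_pct` (window),
#'   `aromatic_pct_full` (whole mature), `max_gap`, `positions` (aromatic
#'   positions).
#' @export
aromatic_metrics <- function(mature) {
  stopifnot(nchar(mature) > 0)
  chars <- strsplit(mature, "")[[1]]
  L <- length(chars)
  pos <- which(chars %in% AROMATIC)
  win <- min(59L, L)
  n_win <- sum(pos <= win)
  gap <- if (length(pos) == 0) L
         else if (length(pos) == 1) 0L
         else max(diff(pos) - 1L)
  list(aromatic_count = length(pos), mature_length = L,
       aromatic_pct = 100 * n_win / win,
       aromatic_pct_full = 100 * length(pos) / L,
       max_gap = gap, positions = pos)
}

#' Key-position aromatic flags
#'
#' Flags for aromatics at unaligned mature positions 1, 24, 27, (50 or 51)
#' and (32 or 57) - the residues essential for conductivity in
#' characterized e-pili. An `offset_map` (named integer vector) can shift
#' positions when alignment-derived coordinates are available.
#'
#' @param mature mature residue string.
#' @param offset_map optional constant shift added to all key positions.
#' @return named logical vector (pos1, pos24, pos27, pos50_51, pos32_57).
#' @export
epilin_position_flags <- function(mature, offset_map = 0L) {
  chars <- strsplit(mature, "")[[1]]
  at <- function(p) {
    p <- p + offset_map
    !is.na(p) & p >= 1 & p <= length(chars) & chars[pmin(pmax(p, 1), length(chars))] %in% AROMATIC
  }
  c(pos1 = at(1L), pos24 = at(24L), pos27 = at(27L),
    pos50_51 = at(50L) || at(51L), pos32_57 = at(32L) || at(57L))
}

#' Classify an e-pilin candidate
#'
#' Strict tier: aromatic percentage over the 1-59 window >= `strict_pct`
#' (9.8), no inter-aromatic gap greater than `max_gap_allow` (22), and all
#' key-position flags. Relaxed tier: whole-mature aromatic percentage >=
#' `relaxed_pct` (8). Otherwise none.
#'
#' @param metrics [aromatic_metrics()] output.
#' @param position_flags [epilin_position_flags()] output.
#' @param strict_pct,relaxed_pct,max_gap_allow thresholds.
#' @return `"strict"`, `"relaxed"`, or `"none"`.
#' @export
classify_epilin <- function(metrics, position_flags,
                            strict_pct = 9.8, relaxed_pct = 8, max_gap_allow = 22L) {
  if (metrics$aromatic_pct >= strict_pct && metrics$max_gap <= max_gap_allow &&
      all(position_flags)) return("strict")
  if (metrics$aromatic_pct_full >= relaxed_pct) return("relaxed")
  "none"
}

#' Screen a protein set for e-pilin candidates
#'
#' Runs prepilin detection (or an override table of cleavage positions),
#' aromatic metrics and tier classification on every protein with a
#' detectable cleavage site.
#'
#' @param proteins a [protein_set()].
#' @param cleavage_override optional data.frame or TSV (protein_id,
#'   cleavage_pos).
#' @param relaxed_leader pass `relaxed` to [detect_prepilin()].
#' @inheritParams classify_epilin
#' @return data.frame, one row per protein with a cleavage site:
#'   protein_id, cleavage_pos, mature_length, aromatic_count, aromatic_pct,
#'   aromatic_pct_full, max_gap, the five position flags, tier.
#' @export
pilin_screen <- function(proteins, cleavage_override = NULL, relaxed_leader = FALSE,
                         strict_pct = 9.8, relaxed_pct = 8, max_gap_allow = 22L) {
  if (!is.null(cleavage_override) && is.character(cleavage_override))
    cleavage_override <- utils::read.delim(cleavage_override)
  rows <- lapply(seq_len(nrow(proteins)), function(i) {
    cp <- NA_integer_
    if (!is.null(cleavage_override)) {
      j <- match(proteins$id[i], cleavage_override[[1]])
      if (!is.na(j)) cp <- as.integer(cleavage_override[[2]][j])
    }
    if (is.na(cp)) cp <- detect_prepilin(proteins$seq[i], relaxed = relaxed_leader)
    if (is.na(cp)) return(NULL)
    mature <- substr(proteins$seq[i], cp + 1L, nchar(proteins$seq[i]))
    if (!nzchar(mature)) return(NULL)
    met <- aromatic_metrics(mature)
    flags <- epilin_position_flags(mature)
    data.frame(protein_id = proteins$id[i], cleavage_pos = cp,
               mature_length = met$mature_length,
               aromatic_count = met$aromatic_count,
               aromatic_pct = met$aromatic_pct,
               aromatic_pct_full = met$aromatic_pct_full,
               max_gap = met$max_gap,
               t(as.data.frame(flags)),
               tier = classify_epilin(met, flags, strict_pct, relaxed_pct, max_gap_allow),
               stringsAsFactors = FALSE)
  })
  out <- rbind_rows(rows)
  if (is.null(out))
    out <- data.frame(protein_id = character(), cleavage_pos = integer(),
                      mature_length = integer(), aromatic_count = integer(),
                      aromatic_pct = numeric(), aromatic_pct_full = numeric(),
                      max_gap = integer(), pos1 = logical(), pos24 = logical(),
                      pos27 = logical(), pos50_51 = logical(), pos32_57 = logical(),
                      tier = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Find OmcS cytochrome homologs
#'
#' Reports local-alignment identity of each protein against an OmcS
#' reference; hits need identity >= `identity_min` and protein length <=
#' `len_max` (long multiheme cytochromes are excluded by the length
#' cutoff). The strict CxxCH (2 variable residues) motif count is reported
#' so six-motif homologs can be flagged.
#'
#' @param proteins a [protein_set()].
#' @param reference reference residue string or FASTA path.
#' @param identity_min minimum percent identity (default 25).
#' @param len_max maximum protein length (default 500).
#' @return data.frame: protein_id, identity_pct, length, n_cxxch,
#'   passes_length, is_hit.
#' @export
find_omcs <- function(proteins, reference, identity_min = 25, len_max = 500L) {
  if (is.character(reference) && length(reference) == 1 && file.exists(reference))
    reference <- read_proteins(reference)$seq[1]
  ref <- Biostrings::AAString(reference)
  rows <- lapply(seq_len(nrow(proteins)), function(i) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(proteins$seq[i]), ref, type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
    ## identity as matched residues over the reference length: a short
    ## high-scoring local block in an unrelated (or very short) protein is
    ## not over-credited, while a full-length homolog scores its true
    ## percent identity
    idt <- 100 * Biostrings::nmatch(aln) / length(ref)
    L <- nchar(proteins$seq[i])
    hits <- find_heme_motifs(proteins$seq[i])
    data.frame(protein_id = proteins$id[i], identity_pct = idt, length = L,
               n_cxxch = sum(hits$n_x == 2L), passes_length = L <= len_max,
               is_hit = idt >= identity_min && L <= len_max,
               stringsAsFactors = FALSE)
  })
  rbind_rows(rows)
}
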