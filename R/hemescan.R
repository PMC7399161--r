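## hemescan: C-x(2,4)-C-H heme-binding-motif detection and multiheme
## c-type cytochrome (MHC) classification.
##
## The scan is leftmost-start, shortest-extension-first, resuming after the
## matched H. Because every occurrence ends at a C,H pair and the leading C
## may sit 4-6 positions before the H, the leftmost match with the shortest
## extension is also the earliest-ending occurrence overall, so this greedy
## returns the maximum number of mutually non-overlapping motifs (classic
## interval scheduling). The ambiguity letter X never matches C or H.

#' Find heme-binding motifs in a protein
#'
#' Scans for C-x(2,4)-C-H, the c-type heme attachment motif with 2-4
#' variable residues, and returns the maximal set of non-overlapping hits.
#'
#' @param residues upper-case residue string (or a 1-row slice of a
#'   [protein_set()]).
#' @return data.frame with columns `start` (1-based position of the leading
#'   C), `span` (matched length, 5-7) and `n_x` (variable residues, 2-4).
#' @examples
#' find_heme_motifs("CATCH")
#' @export
find_heme_motifs <- function(residues) {
  if (inherits(residues, "protein_set")) {
    stopifnot(nrow(residues) == 1)
    residues <- residues$seq
  }
  chars <- strsplit(residues, "")[[1]]
  n <- length(chars)
  starts <- integer(0); spans <- integer(0)
  i <- 1L
  while (i + 4L <= n) {
    if (chars[i] == "C") {
      hit <- 0L
      for (nx in 2:4) {
        j <- i + nx + 1L
        if (j + 1L <= n && chars[j] == "C" && chars[j + 1L] == "H") { hit <- nx; break }
      }
      if (hit) {
        starts <- c(starts, i); spans <- c(spans, hit + 3L)
        i <- i + hit + 3L
        next
      }
    }
    i <- i + 1L
  }
  data.frame(start = starts, span = spans, n_x = spans - 3L)
}

size_class_of <- function(h) {
  ifelse(h >= 3 & h <= 14, "3-14",
    ifelse(h >= 15 & h <= 27, "15-27",
      ifelse(h >= 30 & h <= 53, "30-53", "other")))
}

#' Classify a protein's multiheme-cytochrome status
#'
#' A protein is an MHC when it carries at least `mhc_min` (default 3)
#' heme-binding motifs, and a "large" MHC at `large_min` (default 10).
#' `residues_per_heme` is length/h to one decimal; the heme-size class uses
#' the summary strata 3-14, 15-27 and 30-53 (counts in the unprinted gaps
#' fall in class "other").
#'
#' @param protein_id identifier.
#' @param residues residue string.
#' @param hits optional precomputed [find_heme_motifs()] result.
#' @param mhc_min,large_min motif-count thresholds.
#' @return one-row data.frame (protein_id, n_motifs, length,
#'   residues_per_heme, is_mhc, is_large, size_class, localization, signal).
#' @export
classify_mhc <- function(protein_id, residues, hits = NULL,
                         mhc_min = 3L, large_min = 10L) {
  if (is.null(hits)) hits <- find_heme_motifs(residues)
  h <- nrow(hits)
  L <- nchar(residues)
  data.frame(
    protein_id = protein_id, n_motifs = h, length = L,
    residues_per_heme = if (h > 0) round(L / h, 1) else NA_real_,
    is_mhc = h >= mhc_min, is_large = h >= large_min,
    size_class = size_class_of(h),
    localization = NA_character_, signal = NA,
    stringsAsFactors = FALSE)
}

#' Heme-motif profiles for a whole protein set
#'
#' @param proteins a [protein_set()].
#' @inheritParams classify_mhc
#' @return `mhc_profiles` data.frame, one row per protein.
#' @export
mhc_profiles <- function(proteins, mhc_min = 3L, large_min = 10L) {
  rows <- lapply(seq_len(nrow(proteins)), function(i)
    classify_mhc(proteins$id[i], proteins$seq[i],
                 mhc_min = mhc_min, large_min = large_min))
  out <- rbind_rows(rows, classify_mhc("x", "A")[0, ])
  class(out) <- c("mhc_profiles", "data.frame")
  out
}

read_label_table <- function(x, value_name) {
  if (is.character(x) && length(x) == 1 && file.exists(x))
    x <- utils::read.delim(x, stringsAsFactors = FALSE, header = TRUE)
  if (!is.data.frame(x) || ncol(x) < 2)
    stop(value_name, " table must have columns protein_id, ", value_name)
  names(x)[1:2] <- c("protein_id", value_name)
  bad <- is.na(x$protein_id) | !nzchar(x$protein_id) | is.na(x[[value_name]])
  if (any(bad)) stop("malformed ", value_name, " table row(s): ",
                     paste(which(bad) + 1L, collapse = ", "))
  x <- unique(x[c("protein_id", value_name)])
  dup <- x$protein_id[duplicated(x$protein_id)]
  if (length(dup))
    stop("conflicting ", value_name, " labels for: ", paste(unique(dup), collapse = ", "))
  x
}

#' Attach localization and signal-peptide annotations to MHC profiles
#'
#' Predictor outputs are consumed as tables, not recomputed. Proteins absent
#' from the localization table get `"Unknown"`; signal status stays `NA`
#' when not listed. Table rows for unknown proteins are ignored (their count
#' is recorded in `attr(x, "merge_report")`).
#'
#' @param profiles [mhc_profiles()] output.
#' @param localization TSV path or data.frame (protein_id, label).
#' @param signal TSV path or data.frame (protein_id, 0/1).
#' @return profiles with `localization` and `signal` filled.
#' @export
merge_annotations <- function(profiles, localization = NULL, signal = NULL) {
  unmatched <- 0L
  profiles$localization <- rep("Unknown", nrow(profiles))
  if (!is.null(localization)) {
    tab <- read_label_table(localization, "label")
    hit <- match(profiles$protein_id, tab$protein_id)
    profiles$localization[!is.na(hit)] <- tab$label[hit[!is.na(hit)]]
    unmatched <- unmatched + sum(!tab$protein_id %in% profiles$protein_id)
  }
  if (!is.null(signal)) {
    tab <- read_label_table(signal, "signal")
    if (!all(tab$signal %in% c(0, 1, "0", "1", TRUE, FALSE)))
      stop("signal table values must be 0/1")
    hit <- match(profiles$protein_id, tab$protein_id)
    profiles$signal[!is.na(hit)] <- as.logical(as.integer(tab$signal[hit[!is.na(hit)]]))
    unmatched <- unmatched + sum(!tab$protein_id %in% profiles$protein_id)
  }
  if (unmatched) warning(unmatched, " annotation row(s) had no matching protein")
  attr(profiles, "merge_report") <- list(n_unmatched = unmatched)
  profiles
}

LOC_COLUMNS <- c("Cytoplasm", "Cytoplasmic membrane", "Extracellular",
                 "Periplasm", "Unknown")

#' Subcellular-localization summary matrix for MHCs
#'
#' Builds the localization count/percentage matrix: one row per group (e.g.
#' taxon or genome) plus one row per heme-count stratum (3-14, 15-27,
#' 30-53). Percentages are rounded to integers; each row also reports the
#' fraction of MHCs predicted outside the cytoplasm and cytoplasmic
#' membrane. An "Outer membrane" column appears only when such labels occur.
#'
#' @param profiles annotated [mhc_profiles()]; only rows with `is_mhc` count.
#' @param group vector of group labels aligned with `profiles` rows (or a
#'   column name in `profiles`).
#' @return data.frame with `row_label`, per-column counts (`n_*`),
#'   percentages (`pct_*`), `total` and `pct_non_cm`.
#' @export
localization_summary <- function(profiles, group = NULL) {
  if (is.character(group) && length(group) == 1 && group %in% names(profiles))
    group <- profiles[[group]]
  m <- profiles[profiles$is_mhc, , drop = FALSE]
  if (is.null(group)) grp <- rep("All MHCs", nrow(profiles)) else grp <- as.character(group)
  grp <- grp[profiles$is_mhc]
  loc <- m$localization
  loc[is.na(loc)] <- "Unknown"
  cols <- LOC_COLUMNS
  if (any(loc == "Outer membrane"))
    cols <- append(cols, "Outer membrane", after = 2)
  loc[!loc %in% cols] <- "Unknown"
  strata <- size_class_of(m$n_motifs)
  row_sets <- c(
    stats::setNames(lapply(unique(grp), function(g) grp == g), unique(grp)),
    stats::setNames(lapply(c("3-14", "15-27", "30-53"),
                           function(s) strata == s),
                    paste0("MHCs with ", c("3-14", "15-27", "30-53"), " hemes")))
  rows <- lapply(names(row_sets), function(lab) {
    sel <- row_sets[[lab]]
    counts <- vapply(cols, function(cc) sum(loc[sel] == cc), 0L)
    total <- sum(counts)
    pct <- if (total > 0) as.integer(round(100 * counts / total)) else rep(NA_integer_, length(cols))
    non_cm <- sum(counts[!cols %in% c("Cytoplasm", "Cytoplasmic membrane")])
    out <- data.frame(row_label = lab, stringsAsFactors = FALSE)
    for (k in seq_along(cols)) out[[paste0("n_", gsub(" ", "_", cols[k]))]] <- counts[k]
    for (k in seq_along(cols)) out[[paste0("pct_", gsub(" ", "_", cols[k]))]] <- pct[k]
    out$total <- total
    out$pct_non_cm <- if (total > 0) as.integer(round(100 * non_cm / total)) else NA_integer_
    out
  })
  rbind_rows(rows)
}

#' Signal-peptide fractions by heme-count stratum
#'
#' Splits MHCs into those with 3-20 heme-binding motifs and those with more
#' than 20, and reports the fraction carrying a predicted signal peptide in
#' each stratum and overall. Proteins with unknown signal status are
#' excluded from denominators and counted in `n_unknown`.
#'
#' @param profiles annotated [mhc_profiles()].
#' @return list with `fraction_3_20`, `n_3_20`, `fraction_gt20`, `n_gt20`,
#'   `fraction_overall`, `n_overall`, `n_unknown`.
#' @export
signal_strata <- function(profiles) {
  m <- profiles[profiles$is_mhc, , drop = FALSE]
  known <- !is.na(m$signal)
  lo <- known & m$n_motifs <= 20
  hi <- known & m$n_motifs > 20
  frac <- function(sel) if (any(sel)) mean(m$signal[sel]) else NA_real_
  list(fraction_3_20 = frac(lo), n_3_20 = sum(lo),
       fraction_gt20 = frac(hi), n_gt20 = sum(hi),
       fraction_overall = frac(known), n_overall = sum(known),
       n_unknown = sum(!known))
}
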