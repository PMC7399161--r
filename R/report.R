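## report: pipeline driver and summary products (per-genome EET roster,
## localization matrix, correlation diagnostics).

#' Generate a synthetic community with planted ground truth
#'
#' Each genome spec is a list with (all optional): `bin_id`,
#' `mhc_motif_counts` (integer vector - one protein per entry, planted
#' motif counts), `pilins` (list of `violate` vectors for [make_pilin()]),
#' `operons` (list of [make_pcc_operon()] argument lists; `seed_alignment`
#' filled from `porin_seeds`), `n_omcs` (OmcS homologs derived from
#' `omcs_reference` at `omcs_divergence` substitutions/site), `n_filler`,
#' `abundance`. Localization labels are drawn from `loc_probs` and signal
#' peptides planted per stratum at `signal_frac_3_20` / `signal_frac_gt20`;
#' the planted tables are returned so annotation merging can be exercised.
#'
#' @param genome_specs list of genome specs.
#' @param rng_seed seed (mandatory).
#' @param porin_seeds named list mapping family to aligned seed FASTA path
#'   or named character vector.
#' @param omcs_reference reference residue string or FASTA path.
#' @param loc_probs named probability vector over localization labels.
#' @param signal_frac_3_20,signal_frac_gt20 planted signal-peptide
#'   fractions for MHCs with 3-20 and >20 motifs.
#' @param omcs_divergence substitution rate for OmcS homologs.
#' @return list: `proteins`, `genes`, `membership` (protein_id, bin_id),
#'   `tm_override`, `localization`, `signal`, `abundance`, `truth` (per
#'   genome: n_mhc, max_hemes, n_large, n_strict, n_relaxed, n_operons,
#'   n_omcs).
#' @export
make_community <- function(genome_specs, rng_seed, porin_seeds = NULL,
                           omcs_reference = NULL,
                           loc_probs = c(Cytoplasm = 0.10, `Cytoplasmic membrane` = 0.15,
                                         Extracellular = 0.15, Periplasm = 0.20,
                                         Unknown = 0.40),
                           signal_frac_3_20 = 0.36, signal_frac_gt20 = 0.72,
                           omcs_divergence = 0.20) {
  if (missing(rng_seed) || is.null(rng_seed)) stop("rng_seed is mandatory for simulation")
  if (is.character(omcs_reference) && length(omcs_reference) == 1 &&
      file.exists(omcs_reference))
    omcs_reference <- read_proteins(omcs_reference)$seq[1]
  with_seed(rng_seed, {
    all_prot <- list(); all_genes <- list(); member <- list()
    tm_rows <- list(); truth <- list(); abundance <- c()
    for (gi in seq_along(genome_specs)) {
      spec <- genome_specs[[gi]]
      bid <- spec$bin_id %||% sprintf("bin_%02d", gi)
      ids <- character(0); seqs <- character(0)
      counts <- spec$mhc_motif_counts %||% integer(0)
      for (k in seq_along(counts)) {
        mp <- make_mhc_protein(counts[k], 80L + 13L * counts[k])
        ids <- c(ids, sprintf("%s_p%03d", bid, k)); seqs <- c(seqs, mp$protein$seq)
      }
      n_strict <- 0L; n_relaxed <- 0L
      for (k in seq_along(spec$pilins %||% list())) {
        pl <- make_pilin(spec$pilins[[k]])
        ids <- c(ids, sprintf("%s_pil%02d", bid, k)); seqs <- c(seqs, pl$protein$seq)
        if (pl$truth$tier == "strict") n_strict <- n_strict + 1L
        if (pl$truth$tier == "relaxed") n_relaxed <- n_relaxed + 1L
      }
      n_omcs <- spec$n_omcs %||% 0L
      if (n_omcs > 0) {
        ## heme-binding motifs are conserved in cytochrome homologs:
        ## mutations are confined to inter-motif positions
        ref_chars <- strsplit(omcs_reference, "")[[1]]
        mh <- find_heme_motifs(omcs_reference)
        protected <- unlist(mapply(function(s, sp) s:(s + sp - 1L),
                                   mh$start, mh$span, SIMPLIFY = FALSE))
        for (k in seq_len(n_omcs)) {
          hom <- ref_chars
          mut <- stats::runif(length(hom)) < omcs_divergence
          mut[protected] <- FALSE
          hom[mut] <- vapply(which(mut), function(i) sample(setdiff(AA20, hom[i]), 1L), "")
          ids <- c(ids, sprintf("%s_omcs%02d", bid, k))
          seqs <- c(seqs, paste(hom, collapse = ""))
        }
      }
      for (k in seq_len(spec$n_filler %||% 3L)) {
        ids <- c(ids, sprintf("%s_fil%02d", bid, k)); seqs <- c(seqs, rand_string(150L, BG18))
      }
      starts <- 1200L * (seq_along(ids) - 1L) + 1L
      genes <- data.frame(gene_id = ids, scaffold_id = paste0(bid, "_s1"),
                          start = starts, end = starts + 3L * nchar(seqs) - 1L,
                          strand = "+", stringsAsFactors = FALSE)
      n_operons <- 0L
      for (k in seq_along(spec$operons %||% list())) {
        op_args <- spec$operons[[k]]
        fam <- op_args$family %||% "MtrB"
        op_args$seed_alignment <- op_args$seed_alignment %||% porin_seeds[[fam]]
        if (is.null(op_args$seed_alignment))
          stop("no porin seed alignment supplied for family ", fam)
        op_args$family <- fam
        op_args$scaffold_id <- sprintf("%s_op%d", bid, k)
        op <- do.call(make_pcc_operon, op_args)
        ids <- c(ids, op$proteins$id); seqs <- c(seqs, op$proteins$seq)
        genes <- rbind(genes, as.data.frame(op$genes)[names(genes)])
        tm_rows[[length(tm_rows) + 1L]] <- op$tm_override
        if (op$truth$expect_cluster) n_operons <- n_operons + 1L
      }
      all_prot[[gi]] <- data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE)
      all_genes[[gi]] <- genes
      member[[gi]] <- data.frame(protein_id = ids, bin_id = bid, stringsAsFactors = FALSE)
      abundance[bid] <- spec$abundance %||% NA_real_
      ## OmcS homologs keep the reference's heme-binding motifs, so they
      ## count among the genome's MHCs too
      ref_motifs <- if (n_omcs > 0) nrow(find_heme_motifs(omcs_reference)) else 0L
      all_hemes <- c(counts, operon_hemes(spec), rep(ref_motifs, n_omcs))
      truth[[bid]] <- list(
        n_mhc = sum(counts >= 3L) + count_operon_mhcs(spec) +
                n_omcs * (ref_motifs >= 3L),
        max_hemes = max(c(all_hemes, 0L)),
        n_large = sum(all_hemes >= 10L),
        n_strict = n_strict, n_relaxed = n_relaxed,
        n_operons = n_operons, n_omcs = n_omcs)
    }
    prot_df <- do.call(rbind, all_prot)
    proteins <- protein_set(prot_df$seq, ids = prot_df$id)
    genes <- new_gene_calls(do.call(rbind, all_genes))
    membership <- do.call(rbind, member)
    tm_override <- if (length(tm_rows)) do.call(rbind, tm_rows) else NULL
    ## planted annotations for every MHC-class protein
    prof <- mhc_profiles(proteins)
    m <- prof[prof$is_mhc, ]
    loc <- data.frame(protein_id = m$protein_id,
                      label = sample(names(loc_probs), nrow(m), replace = TRUE,
                                     prob = loc_probs),
                      stringsAsFactors = FALSE)
    sig_p <- ifelse(m$n_motifs > 20, signal_frac_gt20, signal_frac_3_20)
    sig <- data.frame(protein_id = m$protein_id,
                      signal = as.integer(stats::runif(nrow(m)) < sig_p),
                      stringsAsFactors = FALSE)
    list(proteins = proteins, genes = genes, membership = membership,
         tm_override = tm_override, localization = loc, signal = sig,
         abundance = abundance, truth = truth)
  })
}

count_operon_mhcs <- function(spec) {
  sum(vapply(spec$operons %||% list(), function(op) {
    n <- op$n_mhc %||% 1L
    mm <- rep_len(op$mhc_motifs %||% 5L, n)
    sum(mm >= 3L)
  }, 0L))
}

operon_hemes <- function(spec) {
  unlist(lapply(spec$operons %||% list(), function(op)
    rep_len(op$mhc_motifs %||% 5L, op$n_mhc %||% 1L)))
}

#' Rank correlation between genomic MHC content and abundance
#'
#' Spearman rank correlation (average ranks for ties) between per-genome
#' MHC counts and an abundance value per genome.
#'
#' @param mhc_counts named numeric vector (or roster data.frame with
#'   columns bin_id, n_mhc).
#' @param abundance named numeric vector aligned by name.
#' @return list: `rho`, `n`; `rho` is `NA` with fewer than 3 genomes.
#' @export
mhc_abundance_correlation <- function(mhc_counts, abundance) {
  if (is.data.frame(mhc_counts))
    mhc_counts <- stats::setNames(mhc_counts$n_mhc, mhc_counts$bin_id)
  common <- intersect(names(mhc_counts), names(abundance))
  common <- common[!is.na(abundance[common])]
  if (length(common) < 3) return(list(rho = NA_real_, n = length(common)))
  list(rho = stats::cor(mhc_counts[common], abundance[common], method = "spearman"),
       n = length(common))
}

#' Per-genome EET roster
#'
#' Summarizes every stage into one row per genome: MHC totals, maximum
#' heme count, large-MHC count, fraction of MHCs predicted outside
#' cytoplasm/cytoplasmic membrane, PCC counts per porin family, e-pilin
#' tier counts and OmcS hit count.
#'
#' @param membership data.frame (protein_id, bin_id).
#' @param profiles annotated [mhc_profiles()].
#' @param pcc [call_pcc()] output (or NULL).
#' @param pilins [pilin_screen()] output (or NULL).
#' @param omcs [find_omcs()] output (or NULL).
#' @param abundance optional named abundance vector.
#' @return roster data.frame, one row per bin.
#' @export
eet_roster <- function(membership, profiles, pcc = NULL, pilins = NULL,
                       omcs = NULL, abundance = NULL) {
  bins <- unique(membership$bin_id)
  if (!length(bins)) {
    empty <- data.frame(bin_id = character(), n_mhc = integer(), max_hemes = integer(),
                        n_large = integer(), frac_non_cm = numeric(),
                        pcc_MtrB = integer(), pcc_OmbB = integer(), pcc_ExtBE = integer(),
                        pcc_ExtI = integer(), n_pcc = integer(), n_strict_pilin = integer(),
                        n_relaxed_pilin = integer(), n_omcs = integer(),
                        abundance = numeric(), stringsAsFactors = FALSE)
    return(empty)
  }
  prof_bin <- membership$bin_id[match(profiles$protein_id, membership$protein_id)]
  rows <- lapply(bins, function(b) {
    p <- profiles[!is.na(prof_bin) & prof_bin == b, , drop = FALSE]
    m <- p[p$is_mhc, , drop = FALSE]
    loc <- m$localization; loc[is.na(loc)] <- "Unknown"
    fam_counts <- stats::setNames(integer(4), c("MtrB", "OmbB", "ExtB/E", "ExtI"))
    if (!is.null(pcc) && nrow(pcc)) {
      pb <- membership$bin_id[match(pcc$porin_id, membership$protein_id)]
      for (f in names(fam_counts)) fam_counts[f] <- sum(pb == b & pcc$family == f, na.rm = TRUE)
    }
    tier_count <- function(t) {
      if (is.null(pilins) || !nrow(pilins)) return(0L)
      pb <- membership$bin_id[match(pilins$protein_id, membership$protein_id)]
      sum(pb == b & pilins$tier == t, na.rm = TRUE)
    }
    n_omcs <- 0L
    if (!is.null(omcs) && nrow(omcs)) {
      ob <- membership$bin_id[match(omcs$protein_id, membership$protein_id)]
      n_omcs <- sum(ob == b & omcs$is_hit, na.rm = TRUE)
    }
    data.frame(
      bin_id = b, n_mhc = nrow(m),
      max_hemes = if (nrow(p)) max(p$n_motifs) else 0L,
      n_large = sum(m$is_large),
      frac_non_cm = if (nrow(m)) mean(!loc %in% c("Cytoplasm", "Cytoplasmic membrane"))
                    else NA_real_,
      pcc_MtrB = fam_counts[["MtrB"]], pcc_OmbB = fam_counts[["OmbB"]],
      pcc_ExtBE = fam_counts[["ExtB/E"]], pcc_ExtI = fam_counts[["ExtI"]],
      n_pcc = sum(fam_counts),
      n_strict_pilin = tier_count("strict"), n_relaxed_pilin = tier_count("relaxed"),
      n_omcs = n_omcs,
      abundance = if (!is.null(abundance)) unname(abundance[b]) else NA_real_,
      stringsAsFactors = FALSE)
  })
  rbind_rows(rows)
}

roster_schema <- list(
  bin_id = "character", n_mhc = "integer", max_hemes = "integer",
  n_large = "integer", frac_non_cm = "numeric:4", pcc_MtrB = "integer",
  pcc_OmbB = "integer", pcc_ExtBE = "integer", pcc_ExtI = "integer",
  n_pcc = "integer", n_strict_pilin = "integer", n_relaxed_pilin = "integer",
  n_omcs = "integer", abundance = "numeric:4")

profile_schema <- list(
  protein_id = "character", n_motifs = "integer", length = "integer",
  residues_per_heme = "numeric:1", is_mhc = "logical", is_large = "logical",
  size_class = "character", localization = "character", signal = "logical")

#' Run the full screening pipeline
#'
#' Drives all stages in dependency order and writes TSV outputs plus a JSON
#' run manifest to `config$outdir`. The config (a list, or a path to a
#' YAML/JSON file) either names input files (`proteins`, `gene_calls`,
#' optional `localization`, `signal`, `tm_override`, `porin_seeds`,
#' `omcs_reference`, `membership`) or a `simulate` block (list of genome
#' specs for [make_community()]; `rng_seed` then mandatory). Thresholds
#' live under `thresholds` with the screening defaults (MHC >= 3 motifs,
#' large >= 10, TM >= 14, shuffle z >= 6, window 2, strict 9.8% / gap 22 /
#' relaxed 8%, OmcS identity >= 25% / length <= 500).
#'
#' @param config list or YAML/JSON path.
#' @return invisibly, a list with the roster and all stage tables.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  outdir <- config$outdir %||% stop("config$outdir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  th <- utils::modifyList(list(
    mhc_min = 3L, large_min = 10L, tm_min = 14L, z_min = 6, n_shuffles = 100L,
    max_intervening = 2L, strict_pct = 9.8, relaxed_pct = 8, max_gap = 22L,
    omcs_identity_min = 25, omcs_len_max = 500L,
    derep_id_min = 98.0, derep_cov_min = 0.70), config$thresholds %||% list())
  seed <- config$rng_seed
  warn_count <- 0L

  ## --- inputs -------------------------------------------------------------
  sim <- NULL
  if (!is.null(config$simulate)) {
    if (is.null(seed)) stop("rng_seed is mandatory when simulation is requested")
    fams <- c("MtrB", "OmbB", "ExtB/E", "ExtI")
    porin_seeds <- config$porin_seeds %||%
      stats::setNames(lapply(fams, eetscan_fixture_seed), fams)
    omcs_ref <- config$omcs_reference %||% eetscan_fixture("synthetic_omcs_reference.faa")
    sim <- make_community(config$simulate, rng_seed = seed,
                          porin_seeds = porin_seeds, omcs_reference = omcs_ref)
    proteins <- sim$proteins; genes <- sim$genes; membership <- sim$membership
    localization <- sim$localization; signal <- sim$signal
    tm_override <- sim$tm_override
    porin_seed_sets <- porin_seeds
    omcs_reference <- omcs_ref
    abundance <- sim$abundance
  } else if (!is.null(config$proteins)) {
    for (f in c("proteins", "gene_calls"))
      if (!is.null(config[[f]]) && !file.exists(config[[f]]))
        stop("missing input file: ", config[[f]])
    for (f in c("localization", "signal", "tm_override", "omcs_reference", "membership"))
      if (!is.null(config[[f]]) && is.character(config[[f]]) && !file.exists(config[[f]]))
        stop("missing fixture: ", config[[f]])
    proteins <- read_proteins(config$proteins)
    genes <- if (!is.null(config$gene_calls))
      read_gene_calls(config$gene_calls, proteins = proteins) else NULL
    membership <- if (!is.null(config$membership))
      utils::read.delim(config$membership, stringsAsFactors = FALSE)
      else data.frame(protein_id = proteins$id, bin_id = "all", stringsAsFactors = FALSE)
    localization <- config$localization; signal <- config$signal
    tm_override <- config$tm_override
    porin_seed_sets <- config$porin_seeds
    omcs_reference <- config$omcs_reference
    abundance <- unlist(config$abundance) %||% NULL
  } else {
    ## no genomes: empty roster, exit success
    roster <- eet_roster(data.frame(protein_id = character(), bin_id = character()),
                         mhc_profiles(protein_set(character(0), ids = character(0))))
    write_table(roster, file.path(outdir, "roster.tsv"), roster_schema)
    write_manifest(outdir, seed, th, 0L, 0L)
    return(invisible(list(roster = roster)))
  }

  ## --- stages -------------------------------------------------------------
  profiles <- mhc_profiles(proteins, mhc_min = th$mhc_min, large_min = th$large_min)
  profiles <- withCallingHandlers(
    merge_annotations(profiles, localization, signal),
    warning = function(w) { warn_count <<- warn_count + 1L; invokeRestart("muffleWarning") })
  write_table(as.data.frame(profiles), file.path(outdir, "mhc_profiles.tsv"),
              profile_schema)
  loc_sum <- localization_summary(
    profiles, membership$bin_id[match(profiles$protein_id, membership$protein_id)])
  utils::write.table(loc_sum, file.path(outdir, "localization_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  pcc <- NULL
  if (!is.null(porin_seed_sets) && !is.null(genes)) {
    cands <- do.call(rbind, lapply(names(porin_seed_sets), function(fam) {
      prof <- build_porin_profile(fam, porin_seed_sets[[fam]])
      porin_search(prof, proteins, n_shuffles = th$n_shuffles, z_min = th$z_min,
                   rng_seed = if (!is.null(seed)) seed + match(fam, names(porin_seed_sets)),
                   tm_override = tm_override, tm_min = th$tm_min)
    }))
    ## a porin that scores against several family profiles is reported once,
    ## under its best-separated family
    if (!is.null(cands) && nrow(cands)) {
      best <- unlist(lapply(split(seq_len(nrow(cands)), cands$protein_id),
                            function(ix) ix[which.max(cands$shuffle_z[ix])]))
      cands <- cands[sort(best), , drop = FALSE]
    }
    pcc <- call_pcc(genes, cands, profiles, max_intervening = th$max_intervening)
    utils::write.table(pcc, file.path(outdir, "pcc_clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  pilins <- pilin_screen(proteins, strict_pct = th$strict_pct,
                         relaxed_pct = th$relaxed_pct, max_gap_allow = th$max_gap)
  utils::write.table(pilins, file.path(outdir, "pilins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  omcs <- NULL
  if (!is.null(omcs_reference)) {
    omcs <- find_omcs(proteins, omcs_reference,
                      identity_min = th$omcs_identity_min, len_max = th$omcs_len_max)
    utils::write.table(
      cbind(omcs[1], identity_pct = formatC(omcs$identity_pct, format = "f", digits = 2),
            omcs[3:6]),
      file.path(outdir, "omcs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }

  roster <- eet_roster(membership, profiles, pcc, pilins, omcs, abundance)
  write_table(roster, file.path(outdir, "roster.tsv"), roster_schema)
  write_manifest(outdir, seed, th, nrow(proteins), length(unique(membership$bin_id)),
                 warn_count)
  invisible(list(roster = roster, profiles = profiles, localization_summary = loc_sum,
                 pcc = pcc, pilins = pilins, omcs = omcs, truth = sim$truth))
}

write_manifest <- function(outdir, seed, thresholds, n_proteins, n_bins, n_warnings = 0L) {
  manifest <- list(
    package = "eetscan",
    version = as.character(utils::packageVersion("eetscan")),
    rng_seed = seed, thresholds = thresholds,
    n_proteins = n_proteins, n_bins = n_bins, n_warnings = n_warnings)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Path to a packaged fixture
#'
#' @param file file name under the package's `extdata`.
#' @return absolute path.
#' @export
eetscan_fixture <- function(file) {
  p <- system.file("extdata", file, package = "eetscan")
  if (!nzchar(p)) stop("missing fixture: ", file)
  p
}

eetscan_fixture_seed <- function(family) {
  eetscan_fixture(sprintf("synthetic_porin_seeds_%s.afa", gsub("/", "", family)))
}
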