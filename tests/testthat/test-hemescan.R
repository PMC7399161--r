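test_that("heme motif scan matches hand-checked cases", {
  h <- find_heme_motifs("CATCH")
  expect_equal(h$start, 1L)
  expect_equal(h$n_x, 2L)

  expect_equal(nrow(find_heme_motifs("CCH")), 0L)      # too few variable residues
  expect_equal(nrow(find_heme_motifs("")), 0L)

  h <- find_heme_motifs("MCAACHGCTTCHGCLLVVCH")
  expect_equal(h$n_x, c(2L, 2L, 4L))
  expect_equal(h$start, c(2L, 8L, 14L))
  expect_true(classify_mhc("p", "MCAACHGCTTCHGCLLVVCH")$is_mhc)
})

test_that("the ambiguity residue X never anchors a motif", {
  expect_equal(nrow(find_heme_motifs("XATCH")), 0L)    # X as leading C
  expect_equal(nrow(find_heme_motifs("CATXH")), 0L)    # X as second C
  expect_equal(nrow(find_heme_motifs("CATCX")), 0L)    # X as H
  expect_equal(nrow(find_heme_motifs("CXXCH")), 1L)    # X fine as variable residue
})

test_that("scan count equals the brute-force non-overlapping maximum", {
  set.seed(101)
  for (i in 1:300) {
    # C/H-enriched alphabet so overlapping occurrences are common
    s <- random_protein(sample(5:60, 1), include = c("C", "H", "A", "T", "G"))
    expect_equal(nrow(find_heme_motifs(s)), oracle_max_motifs(s), info = s)
  }
})

test_that("motif count is invariant under terminal padding with inert residues", {
  set.seed(55)
  for (i in 1:50) {
    s <- random_protein(sample(10:60, 1), include = c("C", "H", "A", "T"))
    n0 <- nrow(find_heme_motifs(s))
    pad <- random_protein(sample(1:10, 1), include = setdiff(AA, c("C", "H")))
    expect_equal(nrow(find_heme_motifs(paste0(pad, s, pad))), n0)
  }
})

test_that("MHC classification applies thresholds, density and size strata", {
  p <- classify_mhc("p", random_protein(100, include = "A"))
  expect_false(p$is_mhc)

  prof <- classify_mhc("q", make_mhc_protein(4, 100, rng_seed = 3)$protein$seq)
  expect_equal(prof$residues_per_heme, 25.0)
  expect_equal(prof$size_class, "3-14")
  expect_true(prof$is_mhc)
  expect_false(prof$is_large)

  two <- classify_mhc("r", make_mhc_protein(2, 60, rng_seed = 3)$protein$seq)
  expect_false(two$is_mhc)
  expect_equal(two$size_class, "other")

  dense <- classify_mhc("s", make_mhc_protein(24, 538, rng_seed = 3)$protein$seq)
  expect_equal(dense$residues_per_heme, 22.4)
  expect_equal(dense$size_class, "15-27")

  expect_equal(classify_mhc("t", make_mhc_protein(10, 200, rng_seed = 1)$protein$seq)$is_large,
               TRUE)
  expect_equal(classify_mhc("u", make_mhc_protein(29, 400, rng_seed = 1)$protein$seq)$size_class,
               "other")
  expect_equal(classify_mhc("v", make_mhc_protein(54, 600, rng_seed = 1)$protein$seq)$size_class,
               "other")
})

test_that("annotation merging fills labels, defaults and rejects conflicts", {
  ps <- protein_set(c(p1 = make_mhc_protein(3, 60, rng_seed = 1)$protein$seq,
                      p2 = make_mhc_protein(5, 80, rng_seed = 2)$protein$seq))
  prof <- mhc_profiles(ps)
  loc <- data.frame(protein_id = "p1", label = "Extracellular")
  sig <- data.frame(protein_id = c("p1", "p2"), signal = c(1, 0))
  out <- merge_annotations(prof, loc, sig)
  expect_equal(out$localization, c("Extracellular", "Unknown"))
  expect_equal(out$signal, c(TRUE, FALSE))

  bad <- data.frame(protein_id = c("p1", "p1"), label = c("Periplasm", "Cytoplasm"))
  expect_error(merge_annotations(prof, bad), "conflicting")

  stray <- data.frame(protein_id = c("p1", "nope"), label = c("Periplasm", "Cytoplasm"))
  expect_warning(out2 <- merge_annotations(prof, stray), "no matching")
  expect_equal(attr(out2, "merge_report")$n_unmatched, 1L)
})

test_that("localization summary rows count, percent and sum correctly", {
  mk <- function(id, h, loc) {
    p <- classify_mhc(id, make_mhc_protein(h, 40 + 10 * h, rng_seed = nchar(id))$protein$seq)
    p$localization <- loc
    p
  }
  prof <- do.call(rbind, c(
    lapply(1:10, function(i) mk(paste0("e", i), 5, "Extracellular")),
    list(make.row.names = FALSE)))
  s <- localization_summary(prof)
  expect_equal(s$pct_Extracellular[1], 100L)
  expect_equal(s$total[1], 10L)
  expect_equal(s$pct_non_cm[1], 100L)

  prof2 <- do.call(rbind, c(
    lapply(1:2, function(i) mk(paste0("c", i), 4, "Cytoplasm")),
    lapply(1:2, function(i) mk(paste0("p", i), 4, "Periplasm")),
    list(make.row.names = FALSE)))
  s2 <- localization_summary(prof2)
  expect_equal(s2$pct_Cytoplasm[1], 50L)
  expect_equal(s2$pct_Periplasm[1], 50L)
  expect_equal(s2$pct_non_cm[1], 50L)

  prof3 <- do.call(rbind, c(
    lapply(1:5, function(i) mk(paste0("a", i), 3, "Cytoplasm")),
    lapply(1:5, function(i) mk(paste0("b", i), 3, "Cytoplasmic membrane")),
    lapply(1:5, function(i) mk(paste0("c", i), 3, "Extracellular")),
    lapply(1:5, function(i) mk(paste0("d", i), 3, "Periplasm")),
    list(make.row.names = FALSE)))
  s3 <- localization_summary(prof3)
  pct <- unlist(s3[1, grep("^pct_(C|E|P|U)", names(s3))])
  expect_equal(sort(unname(pct)), c(0L, 25L, 25L, 25L, 25L))
  expect_equal(sum(pct), 100L)
})

test_that("localization percentages always sum to 100 within rounding", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    prof <- mhc_profiles(protein_set(
      vapply(seq_len(n), function(i) make_mhc_protein(sample(3:25, 1), 300)$protein$seq, ""),
      ids = paste0("p", seq_len(n))))
    prof$localization <- sample(c("Cytoplasm", "Cytoplasmic membrane", "Extracellular",
                                  "Periplasm", "Unknown"), n, replace = TRUE)
    s <- localization_summary(prof)
    sums <- rowSums(s[grep("^pct_", names(s))[1:5]], na.rm = TRUE) - ifelse(is.na(s$pct_non_cm), 0, 0)
    keep <- s$total > 0
    expect_true(all(abs(rowSums(s[keep, grep("^pct_[^n]", names(s)), drop = FALSE]) - 100) <= 2))
  }
})

test_that("signal strata split at 20 motifs with unknowns excluded", {
  mk <- function(id, h, sig) {
    p <- classify_mhc(id, make_mhc_protein(h, 30 + 12 * h, rng_seed = nchar(id) + h)$protein$seq)
    p$signal <- sig
    p
  }
  prof <- do.call(rbind, c(lapply(1:10, function(i) mk(paste0("s", i), 5, TRUE)),
                           list(make.row.names = FALSE)))
  st <- signal_strata(prof)
  expect_equal(st$fraction_3_20, 1.0)
  expect_true(is.na(st$fraction_gt20))
  expect_equal(st$fraction_overall, 1.0)

  prof2 <- do.call(rbind, c(
    lapply(1:4, function(i) mk(paste0("t", i), 25, i == 1)),
    list(make.row.names = FALSE)))
  expect_equal(signal_strata(prof2)$fraction_gt20, 0.25)

  prof3 <- rbind(prof, mk("unk", 5, NA))
  st3 <- signal_strata(prof3)
  expect_equal(st3$n_unknown, 1L)
  expect_equal(st3$n_3_20, 10L)
})
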