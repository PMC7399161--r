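test_that("completeness tiers use the 70%/90% cutoffs for both domains", {
  mk <- function(domain, n) {
    ids <- sprintf("m%02d", seq_len(n))
    completeness_tier(scg_inventory("b", domain, present = ids))
  }
  expect_equal(mk("bacteria", 36)$tier, "draft")        # 36/51 = 70.6%
  expect_equal(mk("bacteria", 35)$tier, "below")
  expect_equal(mk("bacteria", 46)$tier, "near_complete") # 46/51 = 90.2%
  expect_equal(mk("bacteria", 45)$tier, "draft")
  expect_equal(mk("archaea", 26)$tier, "below")          # 26/38 < 70%
  expect_equal(mk("archaea", 27)$tier, "draft")
  expect_equal(mk("archaea", 35)$tier, "near_complete")
  expect_equal(mk("archaea", 34)$tier, "draft")
})

test_that("tier cutoffs equal ceil(fraction x universe) for both domains", {
  for (dom in c(bacteria = 51L, archaea = 38L)) {
    domain <- names(which(c(bacteria = 51L, archaea = 38L) == dom))
    for (frac in c(0.70, 0.90)) {
      cut <- ceiling(frac * dom)
      tiers <- vapply(seq_len(dom), function(n)
        completeness_tier(scg_inventory("b", domain,
                                        present = sprintf("m%02d", 1:n)))$tier, "")
      reached <- if (frac == 0.70) tiers != "below" else tiers == "near_complete"
      expect_equal(min(which(reached)), cut, info = paste(domain, frac))
    }
  }
})

test_that("bin score is presents minus twice the multi-copy markers", {
  inv <- make_bin_inventory(n_present = 40, n_multi = 3, rng_seed = 1)$inventory
  expect_equal(bin_score(inv), 34L)

  full <- scg_inventory("b", "bacteria", present = sprintf("m%02d", 1:51))
  expect_equal(bin_score(full), 51L)

  all_multi <- scg_inventory("b", "bacteria", present = sprintf("m%02d", 1:10),
                             multiplicity = setNames(rep(3L, 10), sprintf("m%02d", 1:10)))
  expect_equal(bin_score(all_multi), -10L)
})

test_that("marker-hit tables infer multiplicity", {
  tab <- data.frame(bin_id = "b1", marker_id = c("m1", "m2", "m2"),
                    gene_id = c("g1", "g2", "g3"))
  invs <- read_marker_hits(tab)
  expect_equal(bin_score(invs$b1), 0L)   # 2 present - 2*1 multi
  expect_equal(sort(invs$b1$present), c("m1", "m2"))
})

test_that("N50 matches examples and the exhaustive oracle", {
  expect_equal(n50(c(10, 8, 5, 3)), 8)
  expect_equal(n50(7), 7)
  expect_error(n50(numeric(0)), "no contig")

  set.seed(61)
  for (i in 1:50) {
    lens <- sample.int(5000, sample(2:20, 1), replace = TRUE)
    expect_equal(n50(lens), oracle_n50(lens))
    expect_equal(n50(sample(lens)), n50(lens))  # order invariance
  }
})

test_that("genome similarity recovers planted identity and aligned fraction", {
  gp0 <- make_genome_pair(2e4, d = 0, rng_seed = 1)
  s0 <- genome_similarity(gp0$binA$scaffolds, gp0$binB$scaffolds)
  expect_equal(s0["A_vs_B", "identity_pct"], 100)
  expect_gte(s0["A_vs_B", "aligned_fraction"], 0.99)

  gp2 <- make_genome_pair(5e4, d = 0.02, rng_seed = 2)
  s2 <- genome_similarity(gp2$binA$scaffolds, gp2$binB$scaffolds)
  expect_lt(abs(s2["A_vs_B", "identity_pct"] - 98.0), 0.5)

  gpf <- make_genome_pair(5e4, d = 0.01, f = 0.4, rng_seed = 3)
  sf <- genome_similarity(gpf$binA$scaffolds, gpf$binB$scaffolds)
  expect_lt(abs(sf["A_vs_B", "aligned_fraction"] - 0.6), 0.05)

  set.seed(4)
  u1 <- paste(sample(c("A", "C", "G", "T"), 2e4, TRUE), collapse = "")
  u2 <- paste(sample(c("A", "C", "G", "T"), 2e4, TRUE), collapse = "")
  su <- genome_similarity(c(a = u1), c(b = u2))
  expect_lt(su["A_vs_B", "aligned_fraction"], 0.10)

  expect_error(genome_similarity(NULL, c(b = u2)), "marker-only")
})

test_that("de-replication applies the 98%/70% rule with documented tie-breaks", {
  mkinv <- function(id, n, multi = 0, seed = 1)
    make_bin_inventory(n_present = n, n_multi = multi, bin_id = id,
                       rng_seed = seed)$inventory
  pairs <- data.frame(bin_a = c("A", "A", "B"), bin_b = c("B", "C", "C"),
                      identity_ab = c(99, 50, 50), fraction_ab = c(0.85, 0.1, 0.1),
                      identity_ba = c(99, 50, 50), fraction_ba = c(0.85, 0.1, 0.1))
  bins <- list(A = list(contig_lengths = c(12000, 5000)),
               B = list(contig_lengths = c(9000, 8000)),
               C = list(contig_lengths = 7000))
  invs <- list(A = mkinv("A", 40), B = mkinv("B", 40, seed = 2), C = mkinv("C", 30))
  cl <- dereplicate(bins, invs, pairs = pairs)
  expect_equal(length(cl), 2L)
  ab <- cl[[which(vapply(cl, function(x) "A" %in% x$members, TRUE))]]
  expect_equal(ab$members, c("A", "B"))
  expect_equal(ab$representative, "A")   # tie on score: N50 12000 beats 9000

  # coverage below 70% keeps bins apart even at high identity
  pairs2 <- transform(pairs, fraction_ab = c(0.60, 0.1, 0.1),
                      fraction_ba = c(0.60, 0.1, 0.1))
  expect_equal(length(dereplicate(bins, invs, pairs = pairs2)), 3L)

  # score dominates N50
  invs2 <- list(A = mkinv("A", 40, multi = 3), B = mkinv("B", 40, seed = 2), C = invs$C)
  cl2 <- dereplicate(bins, invs2, pairs = pairs)
  ab2 <- cl2[[which(vapply(cl2, function(x) "A" %in% x$members, TRUE))]]
  expect_equal(ab2$representative, "B")

  # total size then lexicographic id break remaining ties
  bins3 <- list(A = list(contig_lengths = c(9000, 1000)),
                B = list(contig_lengths = c(9000, 8000)), C = bins$C)
  cl3 <- dereplicate(bins3, list(A = invs$B, B = invs$B, C = invs$C), pairs = pairs)
  ab3 <- cl3[[which(vapply(cl3, function(x) "A" %in% x$members, TRUE))]]
  expect_equal(ab3$representative, "B")  # same score & N50, larger total size

  bins4 <- list(A = bins$B, B = bins$B, C = bins$C)
  cl4 <- dereplicate(bins4, list(A = invs$B, B = invs$B, C = invs$C), pairs = pairs)
  ab4 <- cl4[[which(vapply(cl4, function(x) "A" %in% x$members, TRUE))]]
  expect_equal(ab4$representative, "A")  # full tie: lexicographic
})

test_that("de-replication partitions the input regardless of pair order", {
  mkinv <- function(id, s) make_bin_inventory(n_present = 40, bin_id = id,
                                              rng_seed = s)$inventory
  ids <- LETTERS[1:6]
  bins <- setNames(lapply(1:6, function(i) list(contig_lengths = 1000 * i)), ids)
  invs <- setNames(lapply(1:6, function(i) mkinv(ids[i], i)), ids)
  set.seed(9)
  pairs <- expand.grid(bin_a = ids, bin_b = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$bin_a < pairs$bin_b, ]
  pairs$identity_ab <- sample(c(99, 60), nrow(pairs), TRUE)
  pairs$fraction_ab <- sample(c(0.9, 0.2), nrow(pairs), TRUE)
  pairs$identity_ba <- pairs$identity_ab
  pairs$fraction_ba <- pairs$fraction_ab
  cl1 <- dereplicate(bins, invs, pairs = pairs)
  cl2 <- dereplicate(bins, invs, pairs = pairs[sample.int(nrow(pairs)), ])
  part <- function(cl) sort(vapply(cl, function(x) paste(x$members, collapse = "+"), ""))
  expect_equal(part(cl1), part(cl2))
  expect_setequal(unlist(lapply(cl1, `[[`, "members")), ids)

  # end-to-end: sequence-level clustering separates diverged pairs
  p1 <- make_genome_pair(3e4, d = 0.01, rng_seed = 21)
  p2 <- make_genome_pair(3e4, d = 0.05, rng_seed = 22)
  sbins <- list(A = p1$binA, B = p1$binB, C = p2$binA, D = p2$binB)
  sinvs <- setNames(lapply(1:4, function(i) mkinv(names(sbins)[i], i)), names(sbins))
  cls <- dereplicate(sbins, sinvs)
  expect_equal(part(cls), c("A+B", "C", "D"))
})
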