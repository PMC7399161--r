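test_that("profile building produces sane log-odds and seed self-scores", {
  seeds <- c(s1 = "AAAWLK", s2 = "AAAWLK")
  prof <- build_porin_profile("MtrB", seeds)
  expect_equal(prof$seed_self_scores[["s1"]], prof$seed_self_scores[["s2"]])
  expect_equal(unname(prof$seed_self_scores["s1"]),
               max(prof$seed_self_scores))
  # column of all A scores A above W
  expect_gt(prof$pssm[1, "A"], prof$pssm[1, "W"])

  expect_error(build_porin_profile("MtrB", c(a = "AAA", b = "AAAA")), "ragged")
  expect_error(build_porin_profile("MtrB", c(a = "AAA")), "at least 2")
})

test_that("gap-heavy alignment columns are dropped", {
  seeds <- c(a = "A-AK", b = "A-AK", c = "AWAK", d = "A-AK")
  prof <- build_porin_profile("OmbB", seeds)
  expect_equal(nrow(prof$pssm), 3L)   # column 2 has 75% gaps
})

test_that("porin search flags seeds, not composition-matched random proteins", {
  prof <- build_porin_profile("MtrB", fixture_seed("MtrB"))
  seeds <- read_proteins(fixture_seed("MtrB"))
  self <- porin_search(prof, protein_set(c(x = gsub("-", "", seeds$seq[1]))),
                       n_shuffles = 50, rng_seed = 1)
  expect_equal(nrow(self), 1L)
  expect_gte(self$shuffle_z, 6)

  # a held-out mutated family member scores far above the shuffle null
  op <- make_pcc_operon("MtrB", fixture_seed("MtrB"), rng_seed = 9)
  held <- porin_search(prof, op$proteins[op$proteins$id == op$truth$porin_id, ],
                       n_shuffles = 50, rng_seed = 2, tm_override = op$tm_override)
  expect_equal(held$protein_id, op$truth$porin_id)
  expect_gt(held$shuffle_z, 6)

  # random proteins of matched composition are rejected
  set.seed(31)
  comp <- table(strsplit(paste(gsub("-", "", seeds$seq), collapse = ""), "")[[1]])
  rand <- protein_set(vapply(1:30, function(i)
    paste(sample(names(comp), 340, replace = TRUE, prob = comp), collapse = ""), ""),
    ids = paste0("r", 1:30))
  rr <- porin_search(prof, rand, n_shuffles = 50, z_min = 6, rng_seed = 3)
  expect_lte(nrow(rr), 0L)

  expect_equal(nrow(porin_search(prof, rand[0, ], n_shuffles = 50)), 0L)
})

test_that("porin search is deterministic and monotone in z_min", {
  prof <- build_porin_profile("OmbB", fixture_seed("OmbB"))
  op <- make_pcc_operon("OmbB", fixture_seed("OmbB"), rng_seed = 4)
  r1 <- porin_search(prof, op$proteins, n_shuffles = 40, rng_seed = 7)
  r2 <- porin_search(prof, op$proteins, n_shuffles = 40, rng_seed = 7)
  expect_identical(r1, r2)

  all_z <- porin_search(prof, op$proteins, n_shuffles = 40, z_min = -Inf, rng_seed = 7)
  for (zmin in c(0, 3, 6, 20)) {
    sub <- porin_search(prof, op$proteins, n_shuffles = 40, z_min = zmin, rng_seed = 7)
    expect_setequal(sub$protein_id, all_z$protein_id[all_z$shuffle_z >= zmin])
  }
})

test_that("TM strand heuristic counts planted barrels and ignores flat sequences", {
  b16 <- make_tm_barrel(16, rng_seed = 5)
  expect_equal(estimate_tm_strands(b16), 16L)
  expect_equal(estimate_tm_strands(make_tm_barrel(20, rng_seed = 6)), 20L)

  expect_equal(estimate_tm_strands(strrep("G", 200)), 0L)

  short <- estimate_tm_strands("ALVIF")
  expect_equal(as.integer(short), 0L)
  expect_true(attr(short, "too_short"))

  # reversal of a barrel preserves the amphipathic signal
  rev16 <- paste(rev(strsplit(b16, "")[[1]]), collapse = "")
  expect_equal(estimate_tm_strands(rev16), 16L)
})

test_that("override tables always win over the TM heuristic", {
  prof <- build_porin_profile("ExtI", fixture_seed("ExtI"))
  seeds <- read_proteins(fixture_seed("ExtI"))
  ps <- protein_set(c(p = gsub("-", "", seeds$seq[1])))
  res <- porin_search(prof, ps, n_shuffles = 30, rng_seed = 1,
                      tm_override = data.frame(protein_id = "p", count = 20))
  expect_equal(res$tm_strands, 20L)
  res12 <- porin_search(prof, ps, n_shuffles = 30, rng_seed = 1,
                        tm_override = data.frame(protein_id = "p", count = 12))
  expect_false(res12$passes_tm)
})

test_that("PCC calling respects the TM threshold and the gene window", {
  op <- make_pcc_operon("MtrB", fixture_seed("MtrB"), n_mhc = 1, tm_strands = 16,
                        gene_gap = 0, rng_seed = 10)
  prof <- mhc_profiles(op$proteins)
  cand <- data.frame(protein_id = op$truth$porin_id, family = "MtrB", score = 500,
                     shuffle_z = 50, tm_strands = 16L, passes_tm = TRUE)
  cl <- call_pcc(op$genes, cand, prof)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$gene_gap, 0L)
  expect_equal(cl$mhc_ids, op$truth$mhc_ids)

  cand12 <- transform(cand, tm_strands = 12L, passes_tm = FALSE)
  expect_equal(nrow(call_pcc(op$genes, cand12, prof)), 0L)

  far <- make_pcc_operon("MtrB", fixture_seed("MtrB"), n_mhc = 1, tm_strands = 16,
                         gene_gap = 3, rng_seed = 11)
  fcand <- data.frame(protein_id = far$truth$porin_id, family = "MtrB", score = 500,
                      shuffle_z = 50, tm_strands = 16L, passes_tm = TRUE)
  expect_equal(nrow(call_pcc(far$genes, fcand, mhc_profiles(far$proteins),
                             max_intervening = 2)), 0L)
  expect_equal(nrow(call_pcc(far$genes, fcand, mhc_profiles(far$proteins),
                             max_intervening = 3)), 1L)
})

test_that("planted operons round-trip with perfect precision and recall", {
  prof <- build_porin_profile("MtrB", fixture_seed("MtrB"))
  n_tp <- 0L; n_fp <- 0L; n_fn <- 0L
  for (s in 1:10) {
    gap <- s %% 4L               # 0..3 intervening genes
    tm <- if (s %% 3 == 0) 12L else 16L
    op <- make_pcc_operon("MtrB", fixture_seed("MtrB"), n_mhc = 1 + s %% 2,
                          tm_strands = tm, gene_gap = gap, rng_seed = 100 + s)
    cands <- porin_search(prof, op$proteins, n_shuffles = 40, rng_seed = 200 + s,
                          tm_override = op$tm_override)
    cl <- call_pcc(op$genes, cands, mhc_profiles(op$proteins), max_intervening = 2)
    expected <- tm >= 14 && gap <= 2
    if (expected && nrow(cl) == 1 && cl$porin_id == op$truth$porin_id) n_tp <- n_tp + 1L
    if (!expected && nrow(cl) > 0) n_fp <- n_fp + 1L
    if (expected && nrow(cl) == 0) n_fn <- n_fn + 1L
  }
  expect_equal(n_fp, 0L)
  expect_equal(n_fn, 0L)
})
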