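# Independent oracles used to validate the scanning and summary code.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Enumerate every C-x(2,4)-C-H occurrence, then find the maximum number of
# mutually non-overlapping occurrences by weighted interval scheduling
# (independent of the greedy scanner under test).
oracle_max_motifs <- function(residues) {
  chars <- strsplit(residues, "")[[1]]
  n <- length(chars)
  occ <- data.frame(start = integer(), end = integer())
  for (a in seq_len(max(0, n - 4))) {
    if (chars[a] != "C") next
    for (nx in 2:4) {
      b <- a + nx + 1L
      if (b + 1L <= n && chars[b] == "C" && chars[b + 1L] == "H")
        occ <- rbind(occ, data.frame(start = a, end = b + 1L))
    }
  }
  if (nrow(occ) == 0) return(0L)
  occ <- occ[order(occ$end), ]
  best <- integer(nrow(occ))            # best count among first i occurrences
  for (i in seq_len(nrow(occ))) {
    compat <- which(occ$end[seq_len(i - 1)] < occ$start[i])
    take <- 1L + if (length(compat)) max(best[compat]) else 0L
    best[i] <- max(take, if (i > 1) best[i - 1] else 0L)
  }
  best[nrow(occ)]
}

random_protein <- function(len, include = AA) {
  paste(sample(include, len, replace = TRUE), collapse = "")
}

# Textbook Spearman rho via explicit average ranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# N50 by scanning every prefix of the sorted lengths.
oracle_n50 <- function(lens) {
  s <- sort(lens, decreasing = TRUE)
  for (i in seq_along(s)) if (sum(s[1:i]) >= sum(s) / 2) return(s[i])
}

fixture_seed <- function(family) {
  eetscan_fixture(sprintf("synthetic_porin_seeds_%s.afa", sub("/", "", family)))
}

demo_community_spec <- function() {
  list(
    list(bin_id = "geo", mhc_motif_counts = c(5, 12, 24, 45, 2),
         pilins = list(character(0), "density"),
         operons = list(list(family = "MtrB", n_mhc = 2, tm_strands = 16,
                             mhc_motifs = c(5, 10))),
         n_omcs = 1, abundance = 30),
    list(bin_id = "mod", mhc_motif_counts = c(3, 8), pilins = list("gap"),
         abundance = 5),
    list(bin_id = "low", mhc_motif_counts = c(1), abundance = 1))
}
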