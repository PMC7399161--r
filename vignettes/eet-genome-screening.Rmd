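---
title: "Screening genomes for extracellular electron transfer potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening genomes for extracellular electron transfer potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eetscan)
```

## The problem

Some microbes respire by moving electrons across the cell envelope to
external acceptors — iron minerals, other cells, or a poised electrode.
This extracellular electron transfer (EET) runs through a small set of
protein systems whose genomic signatures are recognizable: multiheme
c-type cytochromes (MHCs) that chain hemes into molecular wires,
outer-membrane porin–cytochrome complexes (PCCs) that conduct electrons
across the outer membrane, aromatic-dense type-IV pili ("e-pili"), and
polymerizing hexaheme cytochromes of the OmcS type. `eetscan` flags these
signatures in annotated (meta)genomes and, because metagenome-assembled
genomes arrive in redundant, variable-quality bins, it also provides the
accompanying bin bookkeeping: single-copy-gene completeness tiers, a bin
quality score, N50, pairwise genome similarity, and de-replication with
representative selection.

Every detector in the package is paired with a generator that plants the
corresponding feature with known ground truth, so the whole pipeline can be
validated end-to-end on synthetic genomes.

## Heme-binding motif scanning

The heme c attachment motif is C-x(2,4)-C-H: a cysteine, two to four
arbitrary residues, a second cysteine, and a histidine. `find_heme_motifs()`
counts the maximum number of mutually non-overlapping occurrences. The scan
is leftmost-start with the shortest extension first, resuming after each
matched histidine. Because every occurrence ends at a (C, H) pair and the
leading cysteine can sit only 4–6 positions before that pair, the leftmost
match with the shortest extension is also the earliest-ending occurrence,
which makes the greedy optimal for the interval-scheduling problem; the test
suite checks this against a brute-force dynamic program on thousands of
adversarial sequences. The ambiguity letter X never matches C or H, and
whether overlapping motifs should instead be counted cumulatively is a
genuinely open question — the non-overlapping maximum is this package's
documented choice.

A protein with at least 3 motifs is an MHC; at least 10 makes it "large".
`classify_mhc()` also reports residues per heme (protein length over motif
count, one decimal) and a heme-count size class using the summary strata
3–14, 15–27 and 30–53; counts in the unprinted gaps (28–29, above 53) are
reported as "other" rather than silently merged. The length entering the
density ratio is the full stored protein length — signal peptides are not
removed, since which length basis reference densities were computed on is
not stated anywhere authoritative; this is recorded as a package choice.

Subcellular localization and signal-peptide calls are consumed as tables
from external predictors, never recomputed: `merge_annotations()` joins
them, `localization_summary()` builds the count/percentage matrix per group
and per heme stratum, and `signal_strata()` reports signal-peptide fractions
for MHCs with 3–20 versus more than 20 motifs.

## Porin–cytochrome complexes

Porin candidates are found by scoring proteins against per-family
position-specific profiles (families named MtrB, OmbB, ExtB/E and ExtI after
their founding members). `build_porin_profile()` turns an aligned seed set
into per-column log-odds with a +1 pseudocount per residue, against a
background mixing the seed composition 50/50 with uniform; columns with more
than half gaps are dropped. `porin_search()` aligns each protein to the
profile by Smith–Waterman with affine gaps (open 10, extend 1; compiled
code) and declares a candidate when the score is at least `z_min = 6`
standard deviations above the mean of `n_shuffles = 200` within-sequence
residue shuffles — a composition- and length-matched null that replaces an
E-value. This profile-plus-shuffle-null scheme is a deliberately simple,
desk-calibratable stand-in for a full profile HMM.

A β-barrel porin must additionally have at least 14 predicted transmembrane
strands. `estimate_tm_strands()` is a documented heuristic: membrane
strands alternate lipid-facing hydrophobic and lumen-facing polar residues,
so the statistic A(i) — the mean over a 9-residue window of normalized
Kyte–Doolittle hydropathy multiplied by (−1)^offset — is large in magnitude
inside strands. Positions with |A| ≥ 0.6 are flagged; runs of at least 5,
merged across gaps shorter than 3, are counted as strands. This heuristic is
a stand-in for a dedicated topology predictor, and an override table of
strand counts always wins when supplied; that is the recommended path on
real data. The synthetic barrel generator alternates strongly hydrophobic
(L/V/I/F) with acidic (D/E) residues in its strands because that pairing
drives |A| to about 0.8, comfortably above the threshold, whereas milder
polar residues such as serine would not saturate it.

`call_pcc()` then pairs every TM-passing porin with the MHCs found within
`max_intervening = 2` genes on the same scaffold (the published analyses
judged proximity visually; two intervening genes is this package's
quantification, and it is configurable). Strand agreement between porin and
cytochrome is not required, also configurable.

## e-pili and OmcS

Type-IV prepilins are recognized by a class-III signal-peptide heuristic:
the leftmost position i (6–40) with G at i, a small/hydrophobic residue at
i+1 and E at i+5 (the conserved Glu5 of mature pilins); the mature pilin
starts at i+1. An override table of cleavage positions is accepted.

On the mature sequence, `aromatic_metrics()` counts F, W, Y and H, computes
the aromatic percentage over mature residues 1–59 (the whole sequence when
shorter), and the maximum number of consecutive non-aromatic residues
strictly between successive aromatics. Flanks before the first and after
the last aromatic are excluded — with this convention the canonical
1-to-24 aromatic spacing equals exactly the printed bound of 22, which
anchors the definition. A candidate is **strict** when the window density is
at least 9.8%, no inter-aromatic gap exceeds 22, and aromatics occupy mature
positions 1, 24, 27, 50-or-51 and 32-or-57; otherwise **relaxed** when the
whole-mature density is at least 8%; otherwise none. Position flags are
evaluated on unaligned mature coordinates (a constant offset can be
supplied); alignment-based coordinates would differ for gapped pilins.

Tier assignment is monotone in the 61-residue mature regime the criteria
were defined on: adding an aromatic residue never demotes. For much longer
matures that guarantee can fail at the margins — an aromatic added far
downstream of the last existing aromatic creates a new inter-aromatic gap
that the excluded terminal flank previously hid — which is one reason the
strict criteria are interpreted on the canonical short pilin window.

`find_omcs()` reports identity against an OmcS reference as matched residues
over the reference length from a local BLOSUM62 alignment. That denominator
is deliberate: identity over the local alignment alone over-credits short
high-scoring blocks in unrelated proteins, while reference-length
normalization leaves a full-length homolog at its true percent identity.
Hits need at least 25% identity and length at most 500 residues — the
length cutoff screens out the long multiheme cytochromes that would
otherwise dominate the candidate list, and is interpreted as an upper
bound. The strict CxxCH count is reported alongside so hexaheme homologs
can be recognized.

## Bin quality and de-replication

Completeness is the fraction of a domain-specific single-copy marker
universe (51 markers for bacteria, 38 for archaea) present in a bin: at
least 70% is draft quality, at least 90% near-complete. The implied integer
cutoffs — the smallest counts meeting those fractions — are 36 and 46 for
bacteria, 27 and 35 for archaea. The bin score is the number of
non-redundant markers minus twice the number of markers present in multiple
copies, and may be negative.

`genome_similarity()` estimates pairwise nucleotide identity without an
external aligner: the query's scaffolds are cut into 1 kb fragments, each
fragment is anchored in the target by exact 15-mer matches (majority
diagonal over probes every 50 bp), and aligned with a banded semi-global
alignment (band 50, compiled code) whose free end gaps keep window flanks
out of the identity denominator. A fragment counts as aligned when at least
60% of it aligns at 70% identity or better; reported identity is the
aligned-length-weighted mean, and the aligned fraction is aligned bases over
the query length. The fragment, k-mer, band and filter parameters are
calibration choices validated by a parameter-recovery property: across
substitution rates 0.005–0.05 on 100 kb pairs, mean recovered identity is
within 0.5 percentage points of 100(1−d).

`dereplicate()` single-links bins whose pairwise estimates meet at least 98%
identity across at least 70% of the query length. The coverage is evaluated
in both directions with OR semantics by default (configurable to AND), an
interpretation of "70% or more of the total alignment length". Estimates
are compared with the cutoffs *at the precision the cutoffs are stated at*
(98 → integer, 0.70 → one decimal). This matters at the boundary: an
unbiased estimator applied to a pair whose true identity is exactly 98.0%
returns values a few hundredths of a point either side of 98.0, and a strict
`>= 98.0` comparison would make the clustering of such pairs a coin flip;
rounding to the rule's own precision makes it deterministic while leaving
pairs at 95% identity separated by an enormous margin. Representatives are
chosen by bin score, then N50, then total size, with a lexicographic
identifier tie-break added for determinism.

## The synthetic community

Generators under `make_*()` plant every feature the pipeline detects:
proteins with exact heme-motif counts (backgrounds exclude C and H, so a
planted count is provably the non-overlapping maximum), pilins that pass or
violate each strict criterion one at a time, porin operons with controlled
gene gaps and planted TM strand counts, genome pairs at controlled
divergence with an optional unrelated fraction, and marker inventories with
chosen multiplicities. All generators are bit-reproducible given `rng_seed`
and return a truth record beside the data.

Deliberate simplifications, and what they imply: backgrounds are uniform
over the permitted alphabet (no codon or GC structure, no real amino-acid
composition), genome pairs mutate by substitution only (an indel option
exists but recovery tolerances are asserted only for the substitution-only
regime), and synthetic porin seeds, pilin and OmcS references are themselves
generator products shipped as fixtures in `inst/extdata/` with `synthetic_`
names — they are stand-ins for reference sequences, not curated biology.
Passing round-trips therefore demonstrate that the detectors invert the
generators under the stated conditions; they do not demonstrate sensitivity
on real proteins, where composition, domain structure and alignment noise
are harsher. On real data the TM-strand and cleavage-site heuristics should
be overridden with predictor output wherever available.

Problem sizes used by the validation suites were chosen to make sampling
error negligible relative to the asserted tolerances: 1,000 sequences for
the motif-count oracle, 100 datasets per planted feature class, and ten
100 kb genome pairs per substitution rate (binomial sd ≈ 0.04 points at
d = 0.02, against a 0.5-point tolerance).

## Running the pipeline

`run_pipeline()` drives all stages in dependency order from a single config
(list or YAML/JSON): either file inputs (protein FASTA, gene calls as GFF3 /
gene table / Prodigal-style headers, optional annotation and override
tables) or a `simulate` block of genome specs, in which case `rng_seed` is
mandatory. All thresholds live under `thresholds` with the screening
defaults (3, 10, 14, 6, 2, 9.8, 8, 22, 25, 500, 98, 0.70). Outputs are TSVs
plus a JSON manifest recording version, parameters and seeds; re-running
with the same config and seed reproduces every output byte for byte. A thin
command-line wrapper with per-stage subcommands ships in `inst/cli/`.

```{r}
demo <- list(list(bin_id = "demo", mhc_motif_counts = c(5, 24), n_omcs = 1))
out <- run_pipeline(list(rng_seed = 1, outdir = tempfile(), simulate = demo))
out$roster[, c("bin_id", "n_mhc", "max_hemes", "n_large", "n_omcs")]
```

## Known limitations

The porin profile search calibrates significance per protein by shuffling,
which is robust but conservative for short proteins and was tuned only at
desk scale; the TM heuristic knows nothing about signal peptides or
re-entrant loops; pilin key positions assume the canonical mature register;
OmcS identity is reference-length normalized and will under-report homologs
much shorter than the reference; and genome similarity assumes
substitution-dominated divergence — large rearrangements reduce the aligned
fraction rather than identity. None of the detectors claims in-situ EET
activity: the roster flags genomic potential only.
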