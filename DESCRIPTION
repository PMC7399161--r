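Package: eetscan
Title: Screening Genomes for Extracellular Electron Transfer Potential
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Flags microbial genomes with genomic potential for extracellular
    electron transfer (EET). Scans protein sets for C-x(2,4)-C-H heme-binding
    motifs and classifies multiheme c-type cytochromes (MHCs), calls
    porin-cytochrome complexes from MHC-adjacent outer-membrane beta-barrel
    porin candidates found by position-specific profile search, scores type-IV
    pilins for the aromatic density, spacing and key-position criteria of
    conductive e-pili, and filters OmcS cytochrome homologs. Also provides
    genome-bin quality scoring from single-copy marker genes, N50, pairwise
    genome similarity by fragment-seeded banded alignment, and de-replication
    with representative selection, plus generators for synthetic proteins,
    operons, pilins, genome pairs and bins with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
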