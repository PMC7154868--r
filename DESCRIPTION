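Package: rbnsrip
Title: Bind-n-Seq Enrichment, Motif Discovery and RIP-Chip Analysis for
    Chloroplast RNA-Binding Proteins
Version: 0.1.0
Authors@R:
    person("RBNS", "Maintainers", email = "maintainers@rbnsrip.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for mapping the RNA sequence specificity and in
    vivo targets of chloroplast ribonucleoproteins (cpRNPs).  Implements RNA
    Bind-n-Seq (RBNS) k-mer enrichment statistics (R values and z-scores of a
    pulldown library against a random input pool), consensus-motif assembly
    from significant k-mers into a position frequency matrix, strand-aware
    genome scanning of motif derivatives against FASTA/GFF3 annotation,
    two-colour RIP-chip probe enrichment (median-of-ratios with ribosomal-RNA
    supernatant normalization and mutant-control comparison), and quantitative
    dot-blot/fractionation binding metrics.  A synthetic-data module simulates
    every input -- random 40-mer pools selected under a saturating Langmuir
    binding model at several protein concentrations, tiling/oligo array signal
    tables with planted enrichment, and paired pellet/supernatant blots -- so
    the full pipeline is exercisable and testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    jsonlite,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
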