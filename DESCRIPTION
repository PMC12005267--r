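Package: trimspect
Title: Trinucleotide Mutation-Signature Enrichment and Mutagenesis Assay
    Statistics for Yeast Genotoxicity Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of single-nucleotide mutation cohorts from mutagen-treated
    yeast isolates. Curates variant tables (variant-allele-frequency filtering,
    removal of preexisting and shared mutations), builds strand-collapsed
    pyrimidine mutation spectra in 6-class and 96-trinucleotide-context form,
    and quantifies enrichment of a trinucleotide mutation signature (by default
    gCn->A, the acetaldehyde-diagnostic signature) among target-class mutations
    relative to motif density in local sequence windows, with a one-sided
    Fisher's exact test and Benjamini-Hochberg correction across cohorts. Also
    provides plating-assay statistics (canavanine-resistance mutation
    frequency, viability, Mann-Whitney comparisons) and delta-delta-Ct qPCR
    fold changes, plus simulators that generate genomes, signature-spiked
    mutation cohorts, contaminated variant tables, and colony-count data with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
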