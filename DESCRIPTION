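Package: heatmiR
Title: Small RNA and Degradome Sequencing Analysis for Heat-Responsive
    miRNA Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for plant small-RNA sequencing and
    degradome (PARE) analysis. Raw reads are adapter-trimmed, length- and
    junk-filtered, screened against Rfam-style contaminant references, and
    collapsed to unique tags. Tags are classified into conserved miRNAs
    (miRBase-style catalog matching within hairpin arms, at most one
    mismatch) and novel candidates (opposite-arm mapping with an MFEI
    hairpin filter and a minimum normalized copy number). Differential
    expression between libraries uses tags-per-million normalization with
    a dual chi-square / Fisher exact test and a log2 fold-change gate.
    Degradome tags are mapped to transcripts to build target plots;
    miRNA:target duplexes are scored with a seed-region-doubled penalty
    scheme and cleavage sites are classified into categories 0-4.
    Hypergeometric term enrichment of target genes and a synthetic-data
    generator with planted ground truth complete the toolkit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
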