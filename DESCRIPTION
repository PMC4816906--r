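Package: plastovar
Title: Plastome Structure, Variability Profiling, and Tailed-Primer Panel Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of chloroplast genomes in groups of
    closely related plants. Detects the large inverted repeat and partitions a
    plastome into its quadripartite structure (LSC/IRa/SSC/IRb), derives introns
    and intergenic spacers from a gene annotation, calls potentially informative
    characters (PICs) per clade from multi-sample SNP tables, profiles
    variability in non-overlapping windows and per locus, selects variable
    single-copy target regions, and designs locus-specific PCR primers with
    Illumina-complementary 5' tails for amplicon re-sequencing panels. Includes
    a synthetic plastome and divergence simulator with known truth for
    validating every stage, and machine-readable reference tables describing
    plastome variability in Hawaiian endemic mints and their Stachys relatives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
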