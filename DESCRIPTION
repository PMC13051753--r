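Package: msatkin
Title: Microsatellite Diversity, Panel Power and Maximum-Likelihood Kinship
    for Captive Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for codominant microsatellite genotype data in small
    captive (ex situ) populations: genotype table input/output (native and
    GenAlEx-style CSV), allele-encoding schemes for sequence-derived alleles,
    missing-data filtering, per-locus diversity statistics with exact
    Hardy-Weinberg and permutation linkage-disequilibrium tests, parentage
    exclusion and genetic identity panel power with minimal-panel selection,
    and maximum-likelihood pairwise relatedness with simulation-based
    confidence sets, a conservative related/unrelated/ambiguous
    classification rule and Bonferroni-corrected likelihood-ratio
    disambiguation of ambiguous pairs. Includes a pedigree-aware synthetic
    genotype generator for validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    pheatmap
Config/testthat/edition: 3
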