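Package: tasrdiv
Title: Candidate-Gene Population Genomics of Taste Receptor Loci with
    Missing Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Region-stratified nucleotide diversity, synonymous and
    non-synonymous diversity, Hudson-style fixation indices with permutation
    significance, coalescent-based confidence intervals, exploratory
    population structure (PCA and neighbor-joining trees) and Pfaffl qPCR
    normalization for small panels of candidate genes genotyped by shotgun
    resequencing with heavy genotype missingness. Includes a neutral
    multi-deme coalescent simulator with infinite-sites mutations mapped
    onto annotated gene templates, used both for confidence intervals and as
    a source of synthetic study data with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
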