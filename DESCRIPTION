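Package: haploshare
Title: Shared-Haplotype (SPLoSH) Diversity Analysis for SNP Array Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating pairwise relatedness in unphased diploid
    SNP-array data via summed potential lengths of shared haplotypes
    (SPLoSH). Provides SNP quality-control filtering, genetic-map anchoring,
    pairwise shared-haplotype segment detection with centimorgan-scale
    potential lengths, and downstream diversity analyses (Euclidean
    distances, PCA ordination, neighbor-joining trees, exports for
    STRUCTURE and SplitsTree). Includes a diploid pedigree simulator with
    recombination on a genetic map and truth identity-by-descent segments
    for validating the shared-haplotype statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    vegan,
    mclust,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
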