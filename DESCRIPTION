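Package: mhpanel
Title: Construction and Forensic Evaluation of Microhaplotype Marker Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for building and evaluating panels of microhaplotype
    markers (short multi-SNP loci read as phased haplotype alleles) for
    forensic genetics. Implements marker screening from variant tables,
    per-locus and cumulative forensic parameters (effective number of
    alleles, observed heterozygosity, matching probability, power of
    discrimination, power of exclusion), two-person DNA mixture detection
    probabilities, Monte-Carlo exact tests of Hardy-Weinberg equilibrium,
    linkage-disequilibrium permutation tests with multi-allelic r-squared,
    duo paternity indices and combined paternity index classification,
    EM haplotype-frequency estimation from unphased genotypes, pairwise
    Fst and neighbour-joining population trees, plus fully seeded
    synthetic-data generators (Hardy-Weinberg genotypes, Mendelian duos,
    Balding-Nichols subpopulations, two-person mixtures) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    vcfR,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
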