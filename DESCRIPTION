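Package: popsweep
Title: Selective Sweep Scans and Population Genomic Statistics for
    Two-Population Resequencing Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Windowed population-genetic statistics and selective-sweep
    detection for a resequenced cohort split into two populations.
    Reads biallelic SNP genotypes from VCF, applies minor-allele-frequency,
    integrity and SNP-cluster site filters, and computes nucleotide
    diversity, Tajima's D and FST (Hudson or Weir-Cockerham) in sliding
    windows.  Sweep regions are called by combining the between-population
    diversity ratio, with a permutation-derived cut-off, and an FST rule,
    then merged, annotated against GFF3 gene models and tested for pathway
    enrichment with the hypergeometric test.  Companion tools characterise
    linkage-disequilibrium decay, Kimura two-parameter distances with
    neighbour-joining trees, genotype PCA and admixture-based membership
    assignment.  A Balding-Nichols cohort simulator with injected sweeps
    provides ground-truth data for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
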