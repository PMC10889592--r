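Package: affburden
Title: Gene-Set Variant-Burden Association Testing for Case-Control Exome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A case-control pipeline for testing whether patients accumulate
    more genetic variants in a curated gene panel than controls. Reads
    multi-sample or per-sample VCFs into a dosage matrix, restricts variants
    to panel gene intervals, removes group-exclusive variants and sites
    departing from Hardy-Weinberg equilibrium (exact conditional test), and
    compares groups at three levels: per-variant and per-gene Fisher exact
    tests (allele 2x2 and genotype 2x3 tables) with Benjamini-Hochberg FDR,
    and a gene-set chi-squared linear-trend test on binned per-individual
    variant burdens. Gene-level findings can be re-tested against an external
    reference panel cohort restricted to panel-observed variants. Includes a
    seeded synthetic-cohort generator with ground-truth labels for power and
    type-I-error studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
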