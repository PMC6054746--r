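Package: rvburden
Title: Rare-Variant Burden Association Testing with Population Controls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-control rare-variant association analysis for exome cohorts
    tested against population reference controls. Provides heuristic genotype
    and site quality-control filters, classification of variants into likely
    gene-disrupting (LGD) and damaging missense (D-mis) classes, per-gene and
    gene-set binomial burden tests with Bonferroni and Benjamini-Hochberg
    correction and synonymous-variant batch-effect calibration, de novo
    mutation enrichment against trinucleotide-context background rates using
    exact Poisson tests, a permutation test for top-quartile expression
    overlap of variant-carrying gene sets in two tissues, exact 2x2 cohort
    contingency tests, and a synthetic-cohort generator so the full pipeline
    runs without access to protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    Biostrings,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
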