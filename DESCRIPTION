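Package: loopvar
Title: Integration of Chromatin-Loop Topology with GWAS Variants and
    Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating chromatin-loop calls from two cell states
    with GWAS candidate variants and differential-expression tables:
    classification of loops into shared, single-shared-anchor and
    cell-type-unique (differential loop loci), extraction of loop contact
    regions, mapping of candidate variants (sentinels plus LD proxies at
    r-squared > 0.6) into contact regions, trait-versus-control enrichment
    testing, positional clustering of variants with single-linkage chaining,
    multi-window concordance of variants, clusters, differential loops and
    differentially expressed genes, and loop-anchored gene-set
    over-representation with Benjamini-Hochberg correction. Includes a
    seeded synthetic-data generator that plants ground truth for every
    stage, and an end-to-end pipeline driver emitting a single JSON report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
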