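Package: taxodiff
Title: Compare Versions of Biological Taxonomies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating biological taxonomies by comparing two
    versions of a ranked classification. Reads and writes taxonomies as
    flat tables (CSV or JSON), detects and classifies taxonomic changes
    between versions (congruences, splits, merges, moves, renames,
    additions and exclusions) using accepted names and synonym lists,
    generates synthetic taxonomy variants with known ground-truth changes,
    lays the comparison out in four ways (edge drawing, matrix,
    agglomeration, animation) with a consistent colour coding, renders
    static SVG documents, and provides the nonparametric repeated-measures
    statistics used to evaluate such comparison methods (Cochran's Q,
    Friedman, Dunn's test with Bonferroni correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
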