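Package: koreporter
Title: Reporter-Score Pathway Enrichment for Microbiome Functional Profiles
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pathway enrichment for KEGG-orthology (KO) functional profiles
    using the reporter-score algorithm: per-KO P values are transformed with
    the inverse normal cumulative distribution, aggregated per pathway with a
    size-independent 1/sqrt(k) sum, and corrected against a Monte-Carlo (or
    exhaustive) background of random KO sets. The score is undirected -- its
    sign carries no up/down-regulation information -- and the package
    enforces that interpretation throughout, offering a directed
    reporter-feature-style complement based on one-tailed P-value splitting
    and a hypergeometric over-representation comparator. Includes two-group
    differential testing for abundance tables, seeded simulators (including
    a 200-KO/10-pathway replica demonstrating why negative scores mean
    "no evidence", not "down-regulated"), GMT and TSV readers/writers, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
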