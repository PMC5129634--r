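Package: pgdbcompare
Title: Comparison and Accuracy Evaluation of Pathway/Genome Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating and comparing organism-specific metabolic
    pathway/genome databases (PGDBs). Reads and writes a BioCyc-style
    attribute-value flat-file dialect; builds a gene-level gold standard of
    enzyme (EC) annotations by merging reviewed and experimentally verified
    sources, filtering protein alignment hits, and consolidating isoform
    annotations; scores predicted annotation sets with true-positive /
    false-positive / false-negative rules (including false negatives for
    genes missing from a resource) and reports precision, recall and
    F-measure; computes cross-database overlap statistics for annotated
    genes, reaction-mapped proteins, small-molecule compounds, reactions by
    top-level Enzyme Commission class, and pathways; and builds per-pathway
    gene-reaction pairing matrices. A synthetic-data generator plants known
    confusion counts and overlap structure so the whole pipeline is testable
    without external database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
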