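Package: pathwayrules
Title: Class-Association Rule Mining for Metabolic Pathway Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mines class-association rules linking InterPro signatures and
    taxonomic lineage to metabolic pathway annotations in prokaryotic
    protein entries, filters them with a skyline (Pareto dominance)
    operator over four rule-quality metrics (support, confidence, lift,
    G-test p-value), aggregates surviving representative rules into
    per-pathway disjunctive prediction models, applies the models to
    unannotated entries, and evaluates predictions with pair-level
    confusion counting under repeated k-fold cross-validation. Includes a
    synthetic-entry generator with planted rule structure for fully
    offline testing, readers for a tab-separated entry dialect and a
    subset of the UniProtKB flat-file format, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
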