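Package: pathrules
Title: Interpretable Path-Rule Classification of Disease-Causing Gene
    Pairs on Biological Knowledge Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts pathogenic (oligogenic/digenic) gene pairs from
    heterogeneous paths in a typed biological knowledge graph following the
    BOCK schema, and explains every positive prediction with a concrete
    subgraph. Implements weighted Apriori mining of metapath association
    rules with unification constraints and closed-itemset filtering,
    differential-evolution refinement of per-condition path-reliability
    thresholds, and a greedy weighted-set-cover decision-set classifier with
    imbalance-corrected rule probabilities. Includes GraphML/TSV readers and
    writers with schema validation, the edge-scoring formulas used to build
    schema-conformant graphs (functional information, SimGIC, BLAST score
    ratio, tissue co-expression filters), construction of weighted
    positive/neutral gene-pair training sets, a synthetic knowledge-graph
    generator with planted metapath patterns, and evaluation utilities
    (stratified cross-validation, curve averaging, random-walk-with-restart
    baseline, metapath-influence statistics, connectivity ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    jsonlite,
    Matrix
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
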