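Package: repoBench
Title: Benchmarking and Performance Metrics for Drug-Repurposing Rankings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A toolkit for evaluating similarity-based drug-repurposing
    platforms. Drugs are characterized by proteome-wide interaction
    signatures; candidate therapies for an indication are proposed by
    ranking all other drugs by signature similarity (RMSD or cosine
    distance). The package implements the leave-one-out benchmarking
    protocol yielding per-indication accuracy and the average indication
    accuracy (AIA), a full suite of ranking metrics (mean reciprocal rank,
    precision-at-K, average precision, enrichment factor, robust initial
    enhancement, BEDROC, rank-formula and trapezoid AUROC, DCG/NDCG),
    confusion-matrix classification metrics with explicit undefined-value
    handling, theoretical (hypergeometric) and empirical (shuffled or
    uniform-random) null controls, and a synthetic-data generator that
    emulates heavy-tailed drug-indication association standards with a
    tunable planted signal.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'standards-io.R'
    'signatures.R'
    'loo-benchmark.R'
    'rank-metrics.R'
    'classify-metrics.R'
    'null-models.R'
    'synthetic.R'
    'metric-suite.R'
    'pipeline.R'
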