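Package: lepinet
Title: Spectral-Count Co-Expression Networks and Differential Analysis
    for Early Lung Adenocarcinoma Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for label-free proteogenomic comparison of
    early lung adenocarcinoma subtypes (AIS, MIA, LPA) from spectral-count
    matrices: replicate aggregation and presence filtering, pairwise
    G-statistic differential analysis with Williams' continuity correction
    and Benjamini-Hochberg control, weighted co-expression network analysis
    (soft-thresholded adjacency, topological overlap, dynamic tree cut,
    hub eigen-proteins, module-trait correlation), maximal clique
    centrality hub ranking on protein-protein interaction networks,
    copy-number-loss burden comparison, and cohort descriptive statistics.
    A seeded synthetic-cohort generator with planted modules and planted
    differential proteins makes the full pipeline testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    ape,
    yaml,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
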