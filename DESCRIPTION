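Package: trisomap
Title: Trisomy Transcriptome Dissection with Rank-Based Differential
    Expression, Meta-Pathways and Seed Protein Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for panels of segmental-duplication trisomy
    (Down syndrome) mouse models. Implements fold-change rank-ordering
    differential expression (an FCROS-type f-value statistic over all
    test/control sample pairs), trisomic-gene dosage and compensation
    bookkeeping, directional gene-set testing with aggregation into
    meta-pathways, construction and decomposition of minimum connected
    seed protein-interaction networks with betweenness hubs and
    degree-preserving null models, and the quantification formulas for
    qPCR (comparative Ct, geNorm), western blots, MRI morphometry and
    behavioural test batteries. Includes synthetic-data generators that
    emulate overlapping trisomy model panels so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    car,
    cluster,
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
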