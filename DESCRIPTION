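Package: rosetteomics
Title: Integrated Proteome, Transcriptome and Methylome Analysis of
    Embryonal Brain Tumors with Multilayered Rosettes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of an integrated multi-omics
    analysis workflow for embryonal brain tumors (ETMR versus AT/RT and
    medulloblastoma): sample-wise normalization, empirical-Bayes batch
    adjustment and reference-anchored cross-cohort integration,
    subgroup-aware differential ranking, preranked gene set enrichment
    analysis with a permutation null, hypergeometric over-representation
    analysis, information-content semantic-redundancy filtering of
    ontology terms, promoter CpG methylation-protein correlation
    analysis, Monti consensus clustering with Ward.D2 linkage, and
    four-parameter logistic IC50 fitting. A seeded synthetic multi-omics
    generator emulates the study design so that every stage is testable
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm,
    mclust,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    sva,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
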