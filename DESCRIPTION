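Package: tmesig
Title: Immune and Stromal Tumor-Microenvironment Signatures and Scores from
    Bulk Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Trains prognosis-linked immune and stromal gene signatures from a
    gene-by-sample expression matrix and matched survival data, and scores any
    cohort against such signatures. Training isolates latent
    tumor-microenvironment signals by Brunet-style non-negative matrix
    factorization, selects genes jointly predictive of the immune and stromal
    latent activities with an L2,1-regularized multitask linear model solved by
    accelerated proximal gradient, and refines the gene list by two-cluster
    consensus clustering plus moderated differential expression. Scoring
    converts expression to per-sample immune and stromal enrichment scores by
    single-sample gene set enrichment (ssGSEA) and classifies samples into four
    microenvironment subtypes (HH, HL, LH, LL) by cohort median split. Includes
    Kaplan-Meier, log-rank, Cox and concordance-index utilities, marker-ratio
    helpers, and a seeded synthetic-data generator with planted immune and
    stromal modules for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
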