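Package: ctdnatrack
Title: Tumor-Informed ctDNA Panel Design, Tissue-Plasma Concordance, and
    cfDNA Fragmentomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tumor-informed liquid-biopsy analysis workflow for gastric
    cancer. Designs a targeted cfDNA capture panel from tissue somatic calls
    via a five-criterion filter cascade (population allele frequency, coding
    impact, CADD score, cohort ubiquity, strand support), matches tissue and
    plasma variant sets per patient to quantify concordance and mutational
    spectra, integrates capillary-electrophoresis fragment-size profiles into
    total cfDNA yield and nucleosomal size regions, and provides the
    statistical layer used for clinical associations: exact Mann-Whitney tail
    probabilities, 2x2 tests, Spearman correlation, Kaplan-Meier strata with
    log-rank and Cox models, shadow-feature (Boruta-style) importance, and
    ROC discrimination. A synthetic-cohort generator reproduces the
    statistical structure of a matched tissue/plasma study so every stage is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    randomForest,
    vcfR,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
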