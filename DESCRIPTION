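Package: omniblup
Title: Multi-Omic Best Linear Unbiased Prediction for Inbred Line Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Phenotype prediction for panels of inbred lines from genomic,
    transcriptomic, and functional-annotation layers. Builds genomic (GRM),
    transcriptomic (TRM) and Hadamard interaction relationship kernels from
    standardized feature matrices, estimates variance components by
    restricted maximum likelihood for multi-kernel linear mixed models
    (GBLUP, TBLUP, GTBLUP, GTIBLUP), and evaluates prediction accuracy by
    replicated k-fold cross-validation. Includes transcriptome-wide
    association (TWAS) informed gene selection, Gene Ontology partitioned
    kernel models (GO-GBLUP, GO-TBLUP, GO-GTBLUP) with scan diagnostics, a
    Random Forest comparison model, readers for VCF, GFF3 and TSV matrix
    inputs, and a synthetic-data generator that emulates an inbred panel
    with linkage-disequilibrium blocks, eQTL-controlled expression, and
    configurable phenotype architectures with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    randomForest,
    vcfR,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
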