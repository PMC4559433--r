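Package: macrobench
Title: Standardized Evaluation Metrics for Macromolecular Modeling and
    Design Benchmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the evaluation metrics, aggregation rules and
    dataset-curation filters used by standardized macromolecular modeling
    and design benchmarks, so that predictions from any modeling engine
    can be scored against experimental reference data in a uniform,
    testable way.  Covers stability and alanine-scanning ddG metrics
    (Pearson correlation, mean absolute error, stability classification),
    sequence-design metrics (native sequence recovery, Jensen-Shannon
    profile similarity, mutual-information based covariation with
    average-product correction and Zpx normalization, residue burial
    classification), recognition-specificity metrics (Boltzmann-weighted
    position weight matrices, AAD, Frobenius distance, AUC, rank-top),
    loop-reconstruction metrics (Kabsch superposition, loop backbone
    RMSD, per-case and benchmark medians, crystal-contact curation), and
    seeded synthetic-data generators with known ground truth for every
    metric family.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
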