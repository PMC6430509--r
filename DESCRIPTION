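Package: soilSBI
Title: Soil Bacterial Species Balance Index of Crop Productivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives a soil bacterial species balance index of potato
    productivity (SBI-py) from an amplicon sequence variant (ASV) count
    table, soil physico-chemical compositions, daily weather records and
    plot yields. Provides Aitchison-geometry primitives (closure, centred
    and isometric log-ratios over strictly bifurcating balance partitions,
    multiplicative zero replacement), agronomic weather indices (cumulative
    precipitation, rainfall Shannon diversity, growing degree-days),
    ordinary least-squares detrending of yield against environmental
    predictors, a per-ASV correlation screen against residual yield with
    signed selection and the resulting species balance index, alpha
    diversity estimators (Shannon, Pielou, Chao1), redundancy analysis with
    scaling-1 scores and index contour surfaces, and a synthetic
    field-study generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    vegan,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
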