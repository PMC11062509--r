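Package: staygreenr
Title: UAV Spectral-Index Stay-Green Phenotyping and Genetic Dissection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end toolkit for dissecting the stay-green trait in
    cereal field trials from temporal UAV multispectral imagery. Computes
    vegetation indices (NDVI, GNDVI, NDRE, OSAVI) from panel-calibrated
    band rasters, extracts per-plot trajectories through an NDVI threshold
    mask, converts them into thermal-time-corrected relative stay-green
    scores (RSGS), and carries the scores through broad-sense heritability,
    linkage-disequilibrium decay, mixed-linear-model genome-wide
    association with kinship and QTL grouping, windowed Weir-Cockerham
    Fst and a simplified cross-population composite-likelihood sweep scan,
    and haplotype-frequency trend analysis across breeding eras. Includes
    a fully seeded synthetic-data generator (weather, structured
    genotypes, senescence trajectories, rendered orthomosaics, cohort
    labels) with analytically known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    tiff,
    pracma,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
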