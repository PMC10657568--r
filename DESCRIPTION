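Package: morphodelim
Title: Geometric Morphometrics and DNA Barcode Clustering for Cryptic
    Species Delimitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrative species-delimitation toolkit for cryptic
    taxa combining two-dimensional geometric morphometrics with DNA
    barcode clustering.  Provides readers and writers for TPS landmark
    files with slider definitions, generalized Procrustes analysis with
    bending-energy sliding of semilandmarks and a tangent-space
    approximation check, permutation-based Procrustes ANOVA (Goodall's
    F), relative warps, between-group principal components, thin-plate
    spline warps with bending energy and Jacobian deformation grids,
    canonical variates analysis with jackknifed classification, pairwise
    PERMANOVA with Bonferroni correction, uncorrected p-distance
    computation on aligned barcodes with threshold (single-linkage)
    objective clustering, and a synthetic-data generator with known
    ground truth so every stage of the pipeline can be validated at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
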