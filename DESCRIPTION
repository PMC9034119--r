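Package: rsnmap
Title: Single-Subject Mapping of Resting-State Network Alterations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Localizes resting-state network abnormalities in individual
    subjects. Builds stable group template components from a control cohort
    (two-stage PCA, Infomax spatial ICA, ICASSO-style stability clustering),
    back-reconstructs subject-specific components with reference-guided
    one-unit ICA, scores each patient component against the healthy-control
    cosine-similarity distribution with a subsampled permutation test and a
    three-standard-deviation rule, relates altered components to lesion
    anatomy (tumour core, oedema, normal-appearing tissue), and predicts
    cognitive domain scores from component alterations with non-negative
    least squares. Includes a synthetic phantom generator so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    pracma,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
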