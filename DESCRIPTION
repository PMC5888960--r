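Package: namQxE
Title: QTL-by-Environment Genome Scans for Nested Association Mapping Populations
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mixed-linear-model genome scans for multi-parent nested
    association mapping (NAM) panels phenotyped under contrasting
    environments, such as well-watered versus water-limited field trials.
    Provides a BC1S3 population simulator on a genetic map (Haldane map
    function), marker quality filters and allele-sharing kinship, derived
    traits and cross-year adjustment of phenotypes, an EMMA-style REML
    engine with P3D variance-component reuse for per-environment scans,
    a marker-by-environment interaction scan with a shared per-line
    polygenic effect across environments, subsample cross-validation
    detection rates for QTL acceptance, 5-cM window peak calling and
    reaction norms, a YCbCr chroma classifier for canopy senescence
    scoring against a white background, and factorial pot-experiment
    statistics with compact letter displays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    car,
    emmeans,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
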