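Package: rtplankit
Title: Template-Guided Automated Radiotherapy Plan Scaffolding and Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Vendor-independent scaffolding for template-guided automated
    radiotherapy treatment planning, with hippocampal-avoidance whole-brain
    radiotherapy (HA-WBRT) as the packaged use case. Provides voxel geometry
    (contour rasterization, Boolean combination, Euclidean margin expansion,
    rings), clinical-protocol and automation-template parsing with structure
    name matching, declarative derived-structure building (PRVs, rings,
    optimization targets), VMAT plan-skeleton layout (isocenter placement,
    arc fields, jaw fitting), planning integrity checks with a
    parameter-change audit log, dose-volume histogram metrics (Dx%, Dcc,
    VxGy, homogeneity index), prescription normalization, exact Wilcoxon
    signed-rank paired plan comparison, and a seeded synthetic head-phantom
    generator so the full pipeline runs end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
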