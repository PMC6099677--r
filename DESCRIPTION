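Package: fieldqsar
Title: 3D-QSAR Molecular Field Analysis with PLS and External Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative molecular field analysis (CoMFA) and comparative
    molecular similarity index analysis (CoMSIA) descriptors on a regular
    lattice around aligned small molecules, partial least squares (PLS)
    modelling with leave-one-out cross-validation, model selection across
    field combinations, the Golbraikh-Tropsha external-validation battery
    with rm2 metrics, Y-randomization robustness testing, the
    standardization-approach applicability domain, and StDev*Coeff contour
    field export. Includes a synthetic aligned-molecule generator with a
    planted field-activity relationship for end-to-end verification, and
    reference tables from a published beta3-adrenergic agonist study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ChemmineR,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
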