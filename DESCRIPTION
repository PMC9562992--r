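Package: gaavcep
Title: Functional-Assay Calibration and ACMG/AMP Classification of GAA Variants
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying variants in the GAA gene (Pompe disease)
    from in vitro enzyme residual-activity data. Calibrates an expression
    assay against control variants of known classification to establish
    pathogenic and benign activity zones per ClinGen Sequence Variant
    Interpretation (SVI) guidance for PS3/BS3 functional evidence, assigns
    ACMG/AMP evidence codes (PS3/BS3, PM2/BS1, PM3, PM5, PP3/BP4, PP4) at
    Variant Curation Expert Panel (VCEP) strengths, and combines evidence
    into a five-tier classification with a full audit trail. Includes a
    seeded synthetic-data generator for control panels and evidence
    profiles, and an end-to-end pipeline producing tabular reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
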