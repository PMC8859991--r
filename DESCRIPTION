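Package: gcimptrace
Title: Longitudinal DNA Methylation Subtype Dynamics in Diffuse Glioma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for longitudinal Illumina 450K beta-value
    profiles of diffuse gliomas: two-tier random-forest classification into
    the seven pan-glioma DNA methylation subtypes with per-class probability
    indices and the G-CIMP-intermediate index rule, patient-level
    primary-to-recurrence transition tabulation, DNA methylation stemness
    scoring (mDNAsi), supervised differential methylation with delta-beta
    filter presets, genomic-feature odds-ratio enrichment, and a 7-CpG
    recurrence-risk panel with Kaplan-Meier / Cox survival stratification.
    Includes a self-contained synthetic cohort generator with planted
    subtype, transition, enrichment and survival truth for end-to-end
    testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    randomForest,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
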