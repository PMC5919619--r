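Package: lipidmrm
Title: MRM-Profiling Lipidomics: Scan Design, Attribution and Biomarker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Flow-injection shotgun lipidomics by multiple reaction monitoring
    (MRM) profiling, from class-specific discovery scan design (precursor-ion,
    neutral-loss and single-ion monitoring) and screening-method assembly,
    through total-ion-current normalization of per-transition intensities,
    lipid species attribution by monoisotopic mass arithmetic, univariate and
    multivariate discriminant statistics (Holm-Sidak corrected t-tests, volcano
    selection, autoscaled PCA, hierarchical clustering), to ROC-validated
    PLS-DA biomarker panels with blind validation-set prediction. Includes
    internal-standard quantification, calibration-linearity assessment, qPCR
    2^-ddCt fold changes, and a seeded synthetic-cohort generator emulating a
    two-group (wild type vs cpdm dermatitis) mouse epidermis study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    mixOmics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    randomForest,
    withr
Config/testthat/edition: 3
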