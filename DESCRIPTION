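Package: petctdose
Title: Effective-Dose Audit for Conventional and Long Axial FOV PET/CT
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for retrospective radiation-dose audits of whole-body
    FDG PET/CT examinations. Computes per-patient effective dose from the
    PET component using ICRP reference-model dose coefficients, with
    optional scaling to patient weight or to indexed blood volume derived
    from body mass index; converts CT dose-length product to effective
    dose; stratifies cohorts into standard weight categories; and compares
    a conventional and a long axial field-of-view scanner cohort with
    median/IQR summaries, percentage differences and Mann-Whitney U tests.
    A seeded synthetic-cohort generator emulates the statistical structure
    of a hospital audit so the whole pipeline is testable without access
    to patient data. Helper arithmetic for CT exposure settings
    (collimation, table feed, mAs from CTDIvol, male/female model error)
    is included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
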