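Package: ntcplan
Title: NTCP-Guided Assessment of Whole-Brain Radiotherapy Plans
Version: 0.1.0
Authors@R:
    person("ntcplan", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for normal tissue complication probability (NTCP) guided
    assessment of radiotherapy treatment plans. Provides dose-volume
    histogram (DVH) containers with differential/cumulative conversion and
    the usual V_xGy / D_x% metrics, the relative-seriality (Poisson) and
    Lyman-Kutcher-Burman (gEUD/probit) dose-response models with published
    parameter presets for parotid xerostomia and lacrimal dry eye after
    whole-brain radiotherapy, clinical-goal evaluation for hippocampal
    avoidance plans, paired cohort statistics (paired t-tests with
    Bonferroni control, effect sizes, noncentral-t power), and a seeded
    synthetic-cohort generator that emulates per-patient DVH families under
    an original 3D plan, a parotid-blocked 3D re-plan and an IMRT re-plan,
    so the whole pipeline runs end to end without protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    optparse,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
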