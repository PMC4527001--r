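Package: accelq
Title: Validation of Activity Questionnaires Against Wrist Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Processes raw wrist-worn tri-axial accelerometer recordings into
    gravity-subtracted signal vector magnitude (SVM_gs) minute epochs,
    calibrates MET-based intensity cut points from steady-state activity
    bouts, classifies time spent sedentary and in light, moderate and
    vigorous physical activity, scores MET-based activity questionnaires,
    and computes the method-agreement statistics used in validation studies:
    Spearman correlations with bootstrap confidence intervals, Bland-Altman
    limits of agreement, weighted kappa on quartiles, and one-way ANOVA
    intraclass correlation coefficients. Includes a synthetic cohort
    generator with controllable between-method rank correlation, test-retest
    reliability and over-reporting, so the full pipeline can be exercised
    without access to participant data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
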