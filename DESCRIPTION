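Package: perovol
Title: Optoelectronic Leg Volumetry, Reproducibility Analysis and Daytime
    Bias Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for slice-based optoelectronic leg volumetry and the
    statistical assessment of its reproducibility. Converts paired
    front/side silhouette width profiles into elliptical cross-sections,
    detects the ankle (B), calf (C), below-knee (D) and mid-thigh (F)
    landmarks, and integrates lower-leg (B-D) and whole-limb (B-F)
    volumes. Provides a synthetic two-visit, duplicate-measurement cohort
    generator with configurable diurnal drift, orthostatic replicate
    shift, analytical and day-to-day noise; variance-component estimators
    (analytical and within-individual coefficients of variation, one-way
    intraclass correlation); and derivation and application of a linear
    daytime bias-correction formula for between-visit volume changes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
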