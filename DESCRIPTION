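Package: corion
Title: Corneal Iontophoresis Thermal Modelling and Spectroscopic Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled electrical-thermal modelling of the layered cornea under
    applied iontophoretic current, together with the downstream analysis
    stages used in ex vivo transcorneal delivery studies. Provides a
    transient one-dimensional Pennes bioheat solver with Joule heating over
    a four-layer corneal stack (tear film, epithelium, stroma, endothelium),
    thermal-safety classification against ocular baseline, caution and
    damage thresholds, albumin quantification from intrinsic tryptophan
    fluorescence with calibration-curve modelling, an FTIR second-derivative
    band-integration pipeline (baseline correction, Savitzky-Golay
    smoothing, group averaging, band-area percentages, amide-I secondary
    structure assignment), one-way ANOVA with Tukey HSD post-hoc
    comparisons, and seeded synthetic-data generators for every input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    pracma,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
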