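Package: leafheat
Title: Photosynthetic Heat Tolerance Thresholds, Thermal Safety Margins and
    Thylakoid Lipid Saturation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for leaf-level photosynthetic heat tolerance.
    Fits exponential decay curves to chlorophyll-fluorescence (Fv/Fm) versus
    leaf-temperature data, extracts the heat tolerance thresholds Tcrit, T50
    and T95 with leaf-level bootstrap resampling, computes thermal safety
    margins against upper-quartile maximum leaf temperatures, summarises
    thylakoid membrane lipid unsaturation as a double bond index per lipid
    class, and runs the species-mean statistics (ordinary least-squares
    regressions, acclimation slopes, one-way ANOVA with Tukey HSD and compact
    letter display). A synthetic-data generator emulating a multi-site
    common-garden campaign makes every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
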