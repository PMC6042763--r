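Package: troutgrowth
Title: Growth, Condition and Genetic Origin of Supplementation-Stocked Lake Trout
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing the effects of supplementation stocking on
    Lake Trout (Salvelinus namaycush) ecotypes: classification of individual
    genetic origin (local, hybrid, stocked) from admixture proportions and
    their bootstrap standard errors; back-calculation of individual
    length-at-age from otolith annulus radii under the body proportional
    hypothesis; Von Bertalanffy growth model fitting with Ford-Walford
    starting values, nonparametric bootstrap standard errors and
    quality filtering; relative-weight body condition indices; nested
    linear mixed-effects comparisons of growth and condition across
    ecotypes, stocking histories and genetic origins; and a synthetic
    cohort generator that reproduces the statistical structure of a
    two-ecotype, stocked/unstocked lake survey so the full pipeline is
    testable without field data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    nlme,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
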