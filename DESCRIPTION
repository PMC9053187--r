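Package: osteotrial
Title: In Silico Clinical Trial of Personalised Versus Generic High
    Tibial Osteotomy Plates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale in silico clinical trial pipeline for medial
    opening-wedge high tibial osteotomy (HTO) fixation. Generates a
    virtual patient cohort (demographics, parametric proximal tibia
    with a Hounsfield-unit field, planning landmarks), plans the
    opening-wedge correction so the mechanical axis passes through a
    configurable plateau fraction (Fujisawa-type 62.5 percent rule),
    builds parametric generic and surface-conforming personalised
    plate-and-screw constructs, maps CT Hounsfield units to
    heterogeneous bone elastic moduli, registers body-weight-scaled
    physiological activity loads by landmark least squares, solves
    small-deformation linear-elastic tetrahedral finite-element models
    (beam screws) for plate von Mises stress, peri-screw bone strain
    and interfragmentary motion across bone-healing stages, and runs
    the trial statistics: fatigue-limit exceedance contingency tables,
    crude and Haldane-penalised odds ratios, cluster-bootstrap paired
    deltas, per-load-step ANOVA with Bonferroni correction, and a
    power calculator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
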