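Package: thermogate
Title: Allosteric Thermodynamic Models and Analysis of Heat-Activated
    Channel Gating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multi-state allosteric equilibrium models of temperature-,
    sodium- and capsaicin-dependent open probability for heat-activated
    ion channels (TRPV1-style gating), together with the analysis
    pipeline that turns macroscopic current-temperature recordings into
    open-probability-temperature relations: van 't Hoff equilibrium
    constants with optional heat-capacity terms, Arrhenius correction for
    open-channel conduction, absolute open-probability scaling,
    successive-difference non-stationary noise analysis, Hill
    dose-response and Goldman-Hodgkin-Katz current-voltage fitting, an
    empirical model of irreversible temperature-dependent inactivation,
    and a seeded synthetic-data generator emulating the recording
    protocols the analysis assumes.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
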