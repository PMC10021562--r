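Package: dcekit
Title: Design, Estimation and Reporting for Discrete Choice Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for stated-preference discrete choice experiments (DCEs)
    built around a study of partnership preferences among Gambian men who
    work with tourists. Generates effects-coded, D-efficient choice designs
    by coordinate exchange; estimates multinomial logit (MNL) and mixed
    multinomial logit (MMNL) models by maximum (simulated) likelihood with
    Halton draws; computes willingness-to-accept ratios with Krinsky-Robb
    intervals; scores WHO-5 wellbeing, Household Hunger Scale and HIV
    knowledge instruments; fits multivariable logistic regressions of risk
    behaviours with complete-separation handling; and provides a calibrated
    synthetic-data generator for Monte Carlo parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
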