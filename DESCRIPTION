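Package: apsweep
Title: Multi-Channel Ion-Block Action-Potential Simulation for Cardiac
    Safety Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Integrates multi-ion-channel screening data (IC50 or pIC50
    per channel, with optional Hill coefficients) into whole-cell cardiac
    action-potential predictions. Compound potencies are converted into
    fractional conductance block via Hill concentration-response curves,
    applied to an ordinary-differential-equation cell model, and the model
    is paced to pseudo-steady state with an adaptive solver. Reports APD90
    and related biomarkers across a concentration sweep, flags alternans
    and depolarisation or repolarisation failure, and exports spreadsheet
    summaries. Ships a self-contained six-current demonstration ventricular
    cell model.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    optparse,
    yaml,
    graphics,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
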