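Package: fetalkp
Title: Prediction of Fetal Exposure to Placental P-gp Substrate Drugs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts the fetal-to-maternal unbound plasma exposure ratio
    (Kp,uu) of drugs effluxed by placental P-glycoprotein. Reduces
    bidirectional Transwell transport measurements to apparent
    permeabilities and efflux ratios with sampled-volume correction and
    QC gating, scales the P-gp-mediated efflux ratio to tissue with a
    proteomics-based relative expression factor (REF), and propagates
    uncertainty to a Kp,uu point estimate with a 90% interval. A compact
    maternal-fetal PBPK simulator estimates in vivo Kp,uu from umbilical
    vein to maternal plasma concentration ratios by AAFE-minimizing
    optimization of the placental efflux clearance, and extrapolates
    predictions to earlier gestational ages via surface-area and
    transporter-abundance scaling with perfusion capping. Includes
    synthetic-data generators (event-driven Transwell kinetics, sparse
    maternal-fetal dyad sampling) so the whole pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    Matrix,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
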