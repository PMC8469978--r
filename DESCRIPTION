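Package: opbias
Title: Operational Model Fitting and Agonist Bias Quantification for
    GPCR Concentration-Response Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits radioligand saturation and competition binding curves
    (with Cheng-Prusoff correction and one- versus two-site model
    selection), Hill concentration-response curves, and the operational
    model of agonism by the two-step procedure with a globally shared
    system maximum. Computes relative intrinsic activities (RAi),
    transduction coefficients log(tau/KA), and delta-delta-log bias
    factors across receptor panels, with ANOVA/Tukey significance flags.
    Includes a synthetic-experiment generator emulating radioligand
    binding and inositol-phosphate accumulation assays in CHO cells
    expressing muscarinic receptor-Galpha16 fusion proteins, so the whole
    pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
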