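Package: mapkcross
Title: Mechanistic Modeling of FGF and VEGF Crosstalk in MAPK/ERK Signaling
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.com")
Description: Mass-action kinetic modeling of endothelial MAPK signaling driven by
    FGF and VEGF. Provides a generic reaction-network/ODE layer, a reconstructed
    FGF-FGFR1-HSGAG / VEGF-VEGFR2 signaling model with receptor trafficking and a
    heparin competition extension, stiff ODE simulation of stimulation protocols,
    scalar pERK response metrics (maximum, time-to-peak T1, super-half-maximum
    duration T2, combination ratio R), extended Fourier Amplitude Sensitivity
    Test (eFAST) global sensitivity analysis, particle swarm optimization (PSO)
    calibration against normalized phospho-protein time courses, a synthetic-data
    generator emulating the training datasets, and drivers for in-silico
    perturbation experiments (heparin, VEGFR2 density, trafficking swaps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Rcpp,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
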