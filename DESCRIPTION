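Package: cardiolpm
Title: Patient-Specific Lumped-Parameter Modelling of the Left Heart and
    Systemic Circulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lumped-parameter (zero-dimensional) simulator of the left
    atrium, left ventricle, aortic and mitral valves, and the systemic and
    pulmonary circulations, calibrated per patient from non-invasive
    Doppler-echocardiography and brachial cuff-pressure measurements.
    Chamber contraction is driven by a double-Hill time-varying elastance;
    valves use net-pressure-gradient formulations with energy-loss
    coefficients and diode switching, including regurgitant branches graded
    from colour-Doppler severity. A two-stage response optimization fits the
    pulmonary inflow amplitude to the measured forward LVOT stroke volume
    and the systemic resistance/compliances to cuff pressures. The package
    computes full pressure, flow and volume waveforms, pressure-volume loop
    stroke work, transvalvular gradients, and counterfactual one-at-a-time
    workload breakdowns of valvular disease constituents for intervention
    planning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
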