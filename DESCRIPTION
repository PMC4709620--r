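Package: chromaPK
Title: HPLC-UV Bioanalytical Method Validation and One-Compartment
    Pharmacokinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Computational companion to HPLC-UV plasma assays of the kind
    used to quantify clopidogrel, its carboxylic acid metabolite, and
    atorvastatin: simulation of multi-peak chromatograms and Bateman-shaped
    plasma concentration-time profiles with known ground truth; peak
    detection and integration with pharmacopeial system-suitability metrics
    (plate count, tailing factor, resolution, signal-to-noise);
    internal-standard ratio calibration with signal-to-noise based LOD and
    LLOQ; accuracy, precision, stability and robustness summaries under the
    +/-15 percent bioanalytical acceptance rule; and one-compartment oral
    pharmacokinetic parameter estimation (terminal log-linear slope, method
    of residuals, trapezoidal AUC with extrapolation to infinity). A single
    seeded pipeline ties the stages together so every result is reproducible
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
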