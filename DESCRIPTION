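Package: finmotor
Title: Pectoral Fin Muscle Function from Electromyography and Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for comparing pectoral fin muscle function
    between aquatic and terrestrial gaits in amphibious fishes. Implements
    EMG conditioning (baseline centering, 40-4000 Hz bandpass, wavelet
    empirical-Bayes denoising), moving-RMS burst detection with a
    physiological on/off rate filter, normalized per-cycle burst metrics
    (duty factor, rectified integrated area, maximum amplitude), 3D
    stroke-cycle kinematics with polar event timing, a circular-statistics
    decision tree (Kuiper von Mises check, Rayleigh, Hermans-Rasson,
    Watson-Williams, Watson U2), linear mixed-effects comparison tables
    with estimated marginal means and Bonferroni contrasts, and Evans Blue
    fluorescence analysis. A synthetic-data generator with known ground
    truth makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nlme,
    emmeans,
    signal,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
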