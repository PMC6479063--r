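Package: rootlignin
Title: Predicting Fine-Root Lignin Content from Near-Infrared Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric workflow for estimating acetyl-bromide-extracted
    lignin content of ground fine-root samples from FT-NIR absorbance
    spectra. Provides the wet-chemistry arithmetic (specific absorption
    coefficient, calibration curve, replicate pooling), the standard
    spectral pre-processing transforms (standard normal variate,
    multiplicative scatter correction, asymmetric and reweighted
    penalized-least-squares baseline removal, Savitzky-Golay
    derivatives), a NIPALS PLS1 regression engine with ten-fold
    cross-validated latent-variable selection, competitive adaptive
    reweighted sampling (CARS) wavelength selection, a repeated
    hold-out validation engine reporting RMSEP, SEP, BIAS, R2 and RPD,
    and a Beer-Lambert mixture simulator that generates spectra and
    reference tables with the statistical structure of real root
    datasets so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
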