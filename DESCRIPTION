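Package: raffmap
Title: Myocardial TRAFF2 Mapping: RAFF2 Pulses, Bloch Simulation, and
    Rotating-Frame Relaxometry Fitting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for quantitative rotating-frame relaxometry of the
    myocardium with RAFF2 (Relaxation Along a Fictitious Field in the
    2nd rotating frame) preparations. Synthesizes sine/cosine
    amplitude- and frequency-modulated RAFF2 radio-frequency pulses and
    preparation trains, propagates magnetization through the
    five-contrast preparation sequence with a Bloch simulator under B0
    off-resonance and B1 transmit scaling, generates digital vial and
    short-axis left-ventricle phantoms with seeded Gaussian or Rician
    noise, fits the three-parameter exponential signal model voxel-wise
    to produce TRAFF2 maps with residual-based standard-deviation maps,
    and computes repeatability, precision, reproducibility and
    inter-subject variability statistics with AHA 16-segment
    aggregation, Bland-Altman analysis and two-standard-deviation scar
    masking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    RNifti,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
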