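Package: puffsd
Title: Fluctuation Analysis of Calcium Imaging Movies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Resolves localized calcium puffs hidden within large global
    cytosolic calcium elevations in fluorescence imaging movies.  Implements
    pixel-wise temporal standard-deviation (running SD) analysis with photon
    shot-noise calibration and correction, a spatial difference-of-Gaussians
    fluctuation cross-check, delta-F/F0 trace metrics (binned SD scatter,
    activity integrals, rise/fall kinetics), and reconstruction of the
    instantaneous calcium release flux from whole-cell traces via a
    first-order removal model.  Includes a ground-truthed synthetic movie
    simulator (EMCCD camera noise model) so the entire pipeline can be
    validated without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    tiff,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
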