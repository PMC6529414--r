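Package: tomomorph
Title: 3D Morphometry of Synchrotron Micro-CT Volumes at the Neural Probe-Tissue Interface
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative 3D morphometry for reconstructed synchrotron
    micro-CT volumes of brain tissue with implanted neural probes. Provides
    TIFF volume-stack input/output with physical voxel-size bookkeeping,
    block binning and bit-depth reduction, grayscale-threshold segmentation
    of probe metal, calcifications, blood vessels, cells and the cavity
    sheath, artifact-exclusion masking around the probe, anisotropy-aware
    Euclidean distance transforms, local thickness by maximal inscribed
    spheres (with a brute-force reference implementation), vessel-diameter
    and nearest-vessel-distance distributions, volume fractions, and a
    reporting pipeline. A seeded synthetic phantom generator with voxel
    ground truth stands in for tomograms that are not publicly archived.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tiff,
    jsonlite,
    yaml,
    tibble,
    generics,
    rlang,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
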