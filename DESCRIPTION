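Package: pcidose
Title: Quantitative UV-C Dosimetry from Photochromic Indicators
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying ultraviolet-C (UV-C) dose from the color
    change of photochromic indicators (PCIs), supporting informed design and
    in-process validation of UV-C decontamination systems (e.g. N95
    respirator treatment). Implements CIEDE2000 and companion color-difference
    metrics, reaction-kinetics calibration curves with full delta-method
    uncertainty propagation and inverse dose prediction, image-based color
    readout with white-balance correction, radiometer irradiance-log dose
    integration and lamp stability characterization, spatial dose mapping,
    and optical-attenuator dynamic-range extension. A synthetic-fixture
    generator with known ground truth makes the whole workflow testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
Suggests:
    farver,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
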