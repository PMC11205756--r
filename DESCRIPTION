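Package: algadens
Title: Spectroscopy-Based Estimation of Algal Density
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for calibrating and applying UV-Vis optical-density
    measurements of microalgal suspensions (developed around Chlorella
    vulgaris). Provides per-wavelength correlation scanning to locate
    optimal calibration wavelengths, linear and saturating (Box-Lucas)
    absorbance-concentration models with an inverse biomass estimator,
    derived-quantity calculators (magnesium content, chlorophyll a from
    magnesium, single-cell weight), a counting-chamber image cytometry
    pipeline, and synthetic-data generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    png,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
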