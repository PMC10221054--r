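Package: greensail
Title: Partitioning Canopy FPAR into Green and Non-Photosynthetic
    Components with a Multi-Layer SAIL Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A four-stream SAIL canopy radiative-transfer model for
    vertically layered canopies in which every layer holds a single
    component (green leaves or woody branches).  Solves the coupled
    direct, diffuse-down, diffuse-up and viewer-direction fluxes per
    wavelength, converts boundary fluxes into per-layer absorbed
    fractions, and partitions the fraction of absorbed
    photosynthetically active radiation (FPAR, 400-700 nm) between
    photosynthetic vegetation (green FPAR) and non-photosynthetic
    vegetation.  Includes a synthetic generator for component
    reflectance/transmittance spectra, MODIS-like band convolution with
    NDVI, EVI, EVI2 and SAVI vegetation indices, simulation grids over
    plant area index and green-component proportion, and linear
    inversion models relating green FPAR to vegetation indices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
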