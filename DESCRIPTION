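Package: blanchspec
Title: Hyperspectral Assessment of Enzymatic Browning in Blanched Potato Slices
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and chemometric analysis of VIS/NIR (600-1000 nm)
    hyperspectral images of blanched potato slices for enzymatic-browning
    assessment. Generates synthetic macro (HSI) and microscopy (HMI) raw frame
    stacks with known polyphenol-oxidase (PPO) and total-phenolic (TPC) ground
    truth, calibrates reflectance against dark and white references, segments
    the sample by PCA-based region-of-interest detection, fits and
    cross-validates partial least squares regression (NIPALS PLS1) models with
    RMSEC/RMSECV/RMSEP/RPD evaluation, selects significant wavelengths from
    beta coefficients, renders pixel-wise chemical distribution maps, and
    quantifies storage browning via CIELAB colour differences (CIE76 delta E).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    yaml,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
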