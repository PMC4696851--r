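Package: restainr
Title: Digital Re-Staining and Perceptual Color-Map Optimization for
    Brightfield Histology Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to extract the bivariate color map inherent in a
    two-stain brightfield histology image (e.g. Hematoxylin-DAB
    immunohistochemistry), to unmix the stains with an unsupervised,
    PCA-optimized variant of color deconvolution, to design perceptually
    linear replacement color maps in CIELAB space, and to digitally
    re-stain images pixel by pixel. Includes phantom-image based
    perceptual-contrast evaluation, Otsu-based foreground/background
    contrast measurement, dichromacy (color-vision-deficiency)
    simulation, and a deterministic generator of synthetic two-stain
    images with ground-truth stain concentrations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    Matrix,
    jsonlite,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
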