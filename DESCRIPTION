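Package: hsifuse
Title: Pixel-Level Fusion of Hyperspectral Datacubes and Seal-Fault Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reducing near-infrared hyperspectral datacubes of
    heat-sealed food trays to single 2-D images by pixel-level fusion
    (band average, minimum, maximum, PCA projection, and transform-domain
    fusion with the discrete wavelet transform, its shift-invariant
    variant, the dual-tree complex wavelet transform, and the Laplacian
    pyramid with max-magnitude coefficient selection), and for classifying
    the fused seal images as normal or faulty with four classifier
    families (a small convolutional network, a sparse stacked autoencoder,
    a deep belief network of restricted Boltzmann machines, and an extreme
    learning machine).  Includes ENVI-format datacube I/O, a synthetic
    seal-ROI generator with class-dependent spectral signatures, a
    stratified split / five-fold cross-validation protocol, a confusion
    matrix metric suite (accuracy, precision, recall, F-measure, Cohen's
    kappa), and an experiment-grid runner sweeping fusion-by-classifier
    combinations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    tiff,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
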