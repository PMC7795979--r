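Package: seedtex
Title: Texture-Based Detection of Seed Contamination in Machine-Vision Frames
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for classifying cereal seed quality
    classes (select kernels, screenings, chaff) from machine-vision frames of
    seeds in pneumatic transport. Provides a synthetic frame generator that
    emulates seed-flow imagery at several airstream speeds, Kirsch compass
    edge detection, grey-level co-occurrence matrix (GLCM) texture descriptors
    (angular second moment, entropy, contrast, correlation, inverse difference
    moment), training-table assembly with stratified 2:1:1 splits, a
    multilayer-perceptron classifier trained by backpropagation followed by
    conjugate-gradient refinement, and correlation/principal-component
    statistics with the Kaiser retention criterion.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
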