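Package: sfdigan
Title: Synthetic Spatial Frequency Domain Imaging and Conditional GAN
    Optical Property Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic spatial-frequency-domain-imaging (SFDI)
    datasets for flat and cylindrical (lumen) sample geometries using a
    diffusion-approximation forward model of diffuse reflectance, pairs
    fringe-illuminated input images with pure-colour ground-truth optical
    property maps, and trains a conditional generative adversarial network
    (modified U-Net generator, patch discriminator with spectral
    normalisation and a history buffer) to recover per-pixel absorption and
    reduced scattering maps from a single fringe image. Includes a
    single-snapshot-of-optical-properties (SSOP) demodulation baseline with
    lookup-table inversion, and normalised-mean-absolute-error evaluation
    with experiment runners for validation scatter, spatial-frequency
    robustness and factor-range grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    grDevices,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
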