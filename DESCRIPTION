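Package: profilecomp
Title: Geometric Compensation of Fluorescence Intensity Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of fluorescence microscopy images of
    morphologically heterogeneous cell populations. Extracts internuclear (IN)
    and radial (RD) intensity profiles over a Delaunay network of nucleus
    centroids and estimates a population-representative "ideal profile" by
    elastic geometric compensation: a Bayesian non-rigid alignment of the
    profile stack with a sinc interpolation basis, smoothness and tension
    regularization, a Poisson or Gaussian noise model, and automatic outlier
    rejection. Includes a seeded synthetic-image simulator (confluent
    elliptical cells with membrane, cytoplasmic or perinuclear-organelle
    marker patterns and Poisson noise) used as ground truth throughout, plus
    reporting utilities (compensated maps, mean +/- SD curves, virtual cell
    reconstructions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
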