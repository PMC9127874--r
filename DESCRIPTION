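Package: nanodyn
Title: Single-Particle Dynamics of Plasma-Membrane Nanodomains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for variable-angle TIRF microscopy of
    plasma-membrane nanodomain proteins: sub-pixel spot detection and
    quantification, nearest-neighbour trajectory linking with gap closing,
    mean-square-displacement diffusion estimation with characteristic-peak
    (log-binned Gaussian-mixture) subpopulation decomposition, membrane
    dwell-time analysis, object-based two-channel colocalization,
    Voronoi localization-density segmentation, FRAP recovery kinetics, and
    FCS autocorrelation-based surface-density estimation.  Includes a
    ground-truthed synthetic movie/trace generator so that every stage of
    the pipeline can be validated without raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    deldir,
    igraph,
    minpack.lm,
    tiff
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
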