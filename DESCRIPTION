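Package: cryoPXCT
Title: Simulation and Quantitative Reconstruction for Cryogenic
    Ptychographic X-Ray Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, desk-scale implementation of the computational
    chain of cryogenic ptychographic X-ray computed tomography (cryo-PXCT)
    of thick vitrified tissue: voxelized tissue phantoms with quantitative
    electron density, far-field diffraction simulation with Fermat-spiral
    scanning and Poisson counting noise, ptychographic phase retrieval by
    difference-map iterations followed by maximum-likelihood conjugate
    gradient refinement, sinogram alignment by vertical mass-profile
    consistency and tomographic reprojection consistency, filtered
    back-projection formulated for phase-derivative projections, and
    quantitative analysis: Fourier shell correlation resolution with the
    half-bit criterion, surface dose estimation, density-band segmentation,
    and conversion of refractive-index decrement to electron and mass
    density.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    igraph,
    yaml,
    tiff
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
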