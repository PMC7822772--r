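Package: elastogen
Title: Generative Modelling of Brain-Tissue Strain Energy Density Functions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for probabilistic modelling of soft-tissue elasticity.
    Implements closed-form hyperelastic strain energy density families
    (neo-Hookean, Mooney-Rivlin, one-term Ogden) with stability checks, a
    synthetic literature-corpus generator, multi-task Gaussian process
    regression (intrinsic coregionalisation model) over log energy curves,
    stability-constrained meta-model calibration by bounded least squares,
    an invertible tetrahedral finite element solver for compressible
    neo-Hookean materials with implicit backward Euler integration, a
    brain-phantom mesh generator, and an inverse pipeline that recovers
    tissue elastic parameters from observed deformation by sampling the
    generative model and scoring candidates by surface RMSE.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
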