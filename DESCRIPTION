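Package: gletraj
Title: Generalized Langevin Analysis and Classification of Cell Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models two-dimensional cell-center trajectories with the
    generalized Langevin equation (GLE). Estimates velocity autocorrelation
    functions and mean-squared displacements, extracts the effective memory
    (friction) kernel by discrete Volterra inversion, fits a parametric
    delta-plus-damped-oscillation kernel including finite sampling step and
    localization noise, and classifies cells by unbiased X-means clustering of
    the per-cell parameters. A Markovian-embedding simulator generates
    synthetic trajectories with exactly known memory kernels, providing ground
    truth for every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    minpack.lm,
    lhs,
    withr,
    data.table,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
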