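Package: perturbOT
Title: Single-Cell Perturbation Response Prediction via Optimal Transport
Version: 0.1.0
Authors@R: person("perturbOT", "Developers", email = "perturbot@example.org", role = c("aut", "cre"))
Description: Predicts single-cell transcriptional responses to perturbations
    from unpaired control/stimulated scRNA-seq data and generalizes to
    held-out cell types. Combines a maximum-mean-discrepancy (MMD)
    regularized variational autoencoder, exact earth-mover's-distance
    alignment of the latent control and stimulated populations, and
    similarity-weighted transfer of per-cell perturbation deltas.
    Includes quality filtering, library-size normalization,
    highly-variable-gene selection, a negative-binomial simulator with
    ground-truth response programs, and evaluation by gene-wise
    mean/variance regression and top differentially-expressed-gene overlap.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
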