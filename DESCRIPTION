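Package: crnmf
Title: Co-Regularized Non-Negative Matrix Factorization for
    lincRNA-Disease Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts associations between long intergenic non-coding RNAs
    (lincRNAs) and diseases by factorizing the known association matrix
    under two graph co-regularizers: a normalized-Laplacian penalty that
    makes latent lincRNA representations respect a co-expression network,
    and a path penalty that couples the reconstruction to
    lincRNA-gene-gene-network-disease paths through a gene genetic
    interaction network. Includes multiplicative-update optimization with
    guaranteed non-negativity, label-propagation and plain NMF baselines,
    leave-one-disease-out and temporal external validation protocols with
    MAE/Accuracy/RMSE/RSS metrics, parameter-sweep drivers, a synthetic
    heterogeneous-network generator with planted low-rank structure, and a
    command-line pipeline over TSV inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
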