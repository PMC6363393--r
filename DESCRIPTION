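Package: convnmf
Title: Convolutional Non-Negative Matrix Factorization for Temporal
    Sequence Discovery
Version: 0.1.0
Authors@R:
    person("convnmf", "developers", email = "convnmf@example.org",
           role = c("aut", "cre"))
Description: Unsupervised discovery of repeated temporal sequences in
    nonnegative time-series matrices (neural population recordings,
    spectrograms, calcium imaging traces) by convolutional non-negative
    matrix factorization with a cross-orthogonality penalty that
    suppresses redundant factors.  Includes multiplicative-update
    solvers with a menu of orthogonality and sparsity penalties,
    masked-entry cross-validation, held-out factor significance testing
    based on overlap skewness, penalty-weight selection by cost-curve
    crossover, stability-based selection of the number of factors,
    a "sequenciness" score quantifying how much of a dataset's structure
    is sequential rather than synchronous, a synthetic sequence
    generator with four noise models, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
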