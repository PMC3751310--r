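Package: gscca
Title: Group Sparse Canonical Correlation Analysis for Paired Omics Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Penalized canonical correlation analysis for integrating two
    high-dimensional omics matrices (e.g. SNP genotypes and gene
    expression) measured on the same samples. Implements the regularized
    singular value decomposition formulation of CCA with a sparse group
    lasso penalty, solved by block cyclic coordinate descent, together
    with its lasso, elastic net and group lasso special cases. Includes
    k-fold cross-validation on the train/test correlation difference for
    penalty tuning, permutation tests for canonical correlations,
    ROC-style support-recovery evaluation, a latent-factor simulation
    framework with grouped autoregressive covariance and Hardy-Weinberg
    SNP discretization, and utilities for k-nearest-neighbour imputation
    and correlation-based feature grouping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, MASS, jsonlite
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'solver.R'
    'model_selection.R'
    'simulate.R'
    'metrics.R'
    'io.R'
    'cli.R'
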