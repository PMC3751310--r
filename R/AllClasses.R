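#' @import methods
#' @importFrom stats cor sd quantile runif rnorm setNames hclust cutree as.dist
#' @importFrom utils read.table write.table
NULL

## ---------------------------------------------------------------------------
## PairedMatrices
## ---------------------------------------------------------------------------

#' Paired sample-aligned data matrices
#'
#' Container for two numeric matrices \code{X} (n samples x p features) and
#' \code{Y} (n samples x q features) measured on the same samples, e.g. SNP
#' genotypes and gene expression. Rows are aligned: row i of \code{X} and row
#' i of \code{Y} belong to the same sample.
#'
#' @slot X numeric matrix, n x p.
#' @slot Y numeric matrix, n x q.
#' @slot standardized logical; \code{TRUE} once every column of both matrices
#'   has mean 0 and standard deviation 1 (see [standardizeColumns()]).
#'
#' @seealso [PairedMatrices()], [standardizeColumns()], [crossProductMatrix()]
#' @export
setClass("PairedMatrices",
  representation(X = "matrix", Y = "matrix", standardized = "logical"),
  prototype(standardized = FALSE))

setValidity("PairedMatrices", function(object) {
  msg <- character()
  if (!is.numeric(object@X) || !is.numeric(object@Y))
    msg <- c(msg, "X and Y must be numeric matrices")
  if (nrow(object@X) != nrow(object@Y))
    msg <- c(msg, sprintf("sample counts differ: nrow(X) = %d, nrow(Y) = %d",
                          nrow(object@X), nrow(object@Y)))
  if (length(object@standardized) != 1L)
    msg <- c(msg, "standardized must be a single logical")
  if (isTRUE(object@standardized)) {
    bad <- function(M) {
      mu <- colMeans(M)
      any(abs(mu) > 1e-8) || any(abs(apply(M, 2L, sd) - 1) > 1e-6)
    }
    if (bad(object@X) || bad(object@Y))
      msg <- c(msg, "standardized = TRUE but columns are not mean 0 / sd 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PairedMatrices object
#'
#' @param X,Y numeric matrices with one row per sample; must have the same
#'   number of rows. Data frames are coerced.
#' @param standardized logical; set to \code{TRUE} only if the columns are
#'   already standardized (mean 0, sd 1). Usually left \code{FALSE} and
#'   [standardizeColumns()] is applied later (the solver does this
#'   automatically).
#' @return A [PairedMatrices-class] object.
#' @examples
#' pd <- PairedMatrices(matrix(rnorm(20), 10), matrix(rnorm(30), 10))
#' nSamples(pd)
#' @export
PairedMatrices <- function(X, Y, standardized = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!is.numeric(X) || !is.numeric(Y))
    stop("X and Y must be numeric matrices", call. = FALSE)
  storage.mode(X) <- "double"; storage.mode(Y) <- "double"
  new("PairedMatrices", X = X, Y = Y, standardized = standardized)
}

## ---------------------------------------------------------------------------
## GroupPartition
## ---------------------------------------------------------------------------

#' Disjoint feature groups
#'
#' Assigns every feature of one data side to exactly one group. Because the
#' assignment is a plain label-per-feature vector, groups are disjoint and
#' cover all features by construction. Each group l of size s_l carries the
#' weight w_l = sqrt(s_l) used by the group penalty to adjust for group size.
#'
#' @slot labels character vector, one group label per feature.
#' @seealso [GroupPartition()], [groupSizes()], [groupWeights()]
#' @export
setClass("GroupPartition", representation(labels = "character"))

setValidity("GroupPartition", function(object) {
  if (length(object@labels) < 1L) return("at least one feature is required")
  if (anyNA(object@labels)) return("group labels must not be NA")
  TRUE
})

#' Construct a GroupPartition
#'
#' @param labels vector (coerced to character) giving the group label of each
#'   feature, in feature order.
#' @return A [GroupPartition-class] object.
#' @examples
#' gp <- GroupPartition(rep(c("g1", "g2"), c(3, 2)))
#' groupSizes(gp)
#' groupWeights(gp)
#' @export
GroupPartition <- function(labels) {
  new("GroupPartition", labels = as.character(labels))
}

#' Every feature in its own group
#'
#' With singleton groups and weights 1 the group penalty acts like an extra
#' lasso, so this is the natural default when no grouping is known.
#'
#' @param p number of features.
#' @return A [GroupPartition-class] with \code{p} singleton groups.
#' @export
singletonGroups <- function(p) GroupPartition(sprintf("f%d", seq_len(p)))

## ---------------------------------------------------------------------------
## PenaltySpec
## ---------------------------------------------------------------------------

.gsccaVariants <- c("l1", "elastic_net", "group", "sparse_group")

#' Penalty specification for sparse CCA
#'
#' Selects one of the four penalized CCA variants and its parameters. For the
#' sparse group variant the X-side penalty is
#' \deqn{\lambda_1(1-\tau_1)\sum_l \omega_l \|u_l\|_2 + \lambda_1\tau_1\|u\|_1}
#' (and symmetrically for the Y side with \eqn{\lambda_2, \tau_2}). Setting
#' \eqn{\tau = 0} recovers the pure group lasso variant, \eqn{\tau = 1} the
#' pure lasso. The elastic net variant uses
#' \eqn{\lambda(1-\tau)\|u\|_2^2 + \lambda\tau\|u\|_1}; because the canonical
#' vectors are constrained to unit norm, the ridge term only rescales and the
#' elastic net solution coincides with the lasso solution at threshold
#' \eqn{\lambda\tau}.
#'
#' @slot variant one of \code{"l1"}, \code{"elastic_net"}, \code{"group"},
#'   \code{"sparse_group"}.
#' @slot lambda1,lambda2 nonnegative sparsity levels for the X and Y sides.
#' @slot tau1,tau2 balance parameters in \[0, 1\] between group and individual
#'   sparsity (ignored by \code{"l1"} and \code{"group"}).
#' @export
setClass("PenaltySpec",
  representation(variant = "character",
                 lambda1 = "numeric", lambda2 = "numeric",
                 tau1 = "numeric", tau2 = "numeric"))

setValidity("PenaltySpec", function(object) {
  msg <- character()
  if (!(object@variant %in% .gsccaVariants))
    msg <- c(msg, sprintf("unknown variant '%s'", object@variant))
  for (s in c("lambda1", "lambda2"))
    if (length(slot(object, s)) != 1L || slot(object, s) < 0)
      msg <- c(msg, sprintf("%s must be a single nonnegative number", s))
  for (s in c("tau1", "tau2"))
    if (length(slot(object, s)) != 1L || slot(object, s) < 0 ||
        slot(object, s) > 1)
      msg <- c(msg, sprintf("%s must lie in [0, 1]", s))
  if (length(msg)) msg else TRUE
})

#' Construct a PenaltySpec
#'
#' @param variant model variant; see [PenaltySpec-class].
#' @param lambda1,lambda2 nonnegative sparsity parameters (X side / Y side).
#' @param tau1,tau2 group-vs-individual balance in \[0, 1\]; defaults 0.5.
#'   Forced to 0 for \code{variant = "group"} and to 1 for
#'   \code{variant = "l1"}.
#' @return A [PenaltySpec-class] object.
#' @examples
#' PenaltySpec("sparse_group", lambda1 = 0.2, lambda2 = 0.2, tau1 = 0.5)
#' @export
PenaltySpec <- function(variant = c("sparse_group", "group", "l1",
                                    "elastic_net"),
                        lambda1 = 0, lambda2 = 0, tau1 = 0.5, tau2 = 0.5) {
  variant <- match.arg(variant)
  if (variant == "group") { tau1 <- 0; tau2 <- 0 }
  if (variant == "l1")    { tau1 <- 1; tau2 <- 1 }
  new("PenaltySpec", variant = variant, lambda1 = lambda1, lambda2 = lambda2,
      tau1 = tau1, tau2 = tau2)
}

## ---------------------------------------------------------------------------
## CrossProduct
## ---------------------------------------------------------------------------

#' Cross-product matrix K
#'
#' The p x q matrix K = X'Y / (n - 1) of sample covariances between the
#' standardized columns of X and Y. Under the diagonal-covariance treatment of
#' high-dimensional CCA, the canonical vectors are penalized singular vectors
#' of K: with no penalty the leading singular triple of K is the solver's
#' fixed point.
#'
#' @slot K numeric p x q matrix.
#' @slot divisor the scalar divisor applied to X'Y (\code{n - 1}), recorded so
#'   the scale convention travels with the object.
#' @seealso [crossProductMatrix()]
#' @export
setClass("CrossProduct",
  representation(K = "matrix", divisor = "numeric"))

setValidity("CrossProduct", function(object) {
  if (!is.numeric(object@K)) return("K must be numeric")
  if (length(object@divisor) != 1L || object@divisor <= 0)
    return("divisor must be a single positive number")
  TRUE
})

## ---------------------------------------------------------------------------
## CanonicalPair
## ---------------------------------------------------------------------------

#' One canonical pair
#'
#' One estimated triple (u, v, d): unit-norm loading vectors for the X and Y
#' sides plus the singular-value analogue d = u' K v, with convergence
#' diagnostics. Under the identity-covariance treatment the CCA loading
#' vectors alpha, beta coincide with u, v.
#'
#' @slot u,v numeric unit vectors (length p and q).
#' @slot d nonnegative scalar, d = tr(K v u') = u' K v.
#' @slot sampleCorrelation Pearson correlation of Xu and Yv on the fitting
#'   data (NA when the pair was fitted from K alone).
#' @slot nIterations number of alternating iterations used.
#' @slot converged logical.
#' @slot objectiveTrace penalized objective \eqn{-u'Kv + \Psi(u) + \Phi(v)}
#'   recorded after every half-update; non-increasing.
#' @export
setClass("CanonicalPair",
  representation(u = "numeric", v = "numeric", d = "numeric",
                 sampleCorrelation = "numeric", nIterations = "integer",
                 converged = "logical", objectiveTrace = "numeric"))

setValidity("CanonicalPair", function(object) {
  msg <- character()
  for (s in c("u", "v")) {
    x <- slot(object, s)
    n2 <- sqrt(sum(x^2))
    if (n2 > 0 && abs(n2 - 1) > 1e-8)
      msg <- c(msg, sprintf("nonzero %s must have unit l2 norm", s))
  }
  if (length(object@d) != 1L) msg <- c(msg, "d must be a scalar")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## SparseCCAFit
## ---------------------------------------------------------------------------

#' Fitted sparse CCA model
#'
#' Result of [sparseCCA()]: one or more canonical pairs extracted by
#' rank-one deflation, together with the penalty and group structure used.
#'
#' @slot pairs list of [CanonicalPair-class] objects in extraction order.
#' @slot penalty the [PenaltySpec-class] used.
#' @slot groupsX,groupsY the [GroupPartition-class] of each side.
#' @slot featureNamesX,featureNamesY column names of X and Y.
#' @seealso [sparseCCA()], [loadings()], [correlations()]
#' @export
setClass("SparseCCAFit",
  representation(pairs = "list", penalty = "PenaltySpec",
                 groupsX = "GroupPartition", groupsY = "GroupPartition",
                 featureNamesX = "character", featureNamesY = "character"))

## ---------------------------------------------------------------------------
## Simulation classes
## ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Parameters of the latent-factor generative model used throughout the
#' simulation studies: a shared latent factor gamma ~ N(0, sigmaGamma^2) per
#' sample drives the truly correlated features of both sides through the
#' effect vectors thetaX, thetaY; rows are drawn as
#' x_i ~ N(thetaX * gamma_i, sigmaE^2 Sigma_p) and
#' y_i ~ N(thetaY * gamma_i, sigmaE^2 Sigma_q). The covariance Sigma has
#' autoregressive structure rho^|i-j| between correlated features within a
#' group, a Unif(betweenRange) correlation between correlated features of
#' different groups, and Unif(irrelevantRange) covariance among noise
#' features. Optionally the Y side is discretized into three-level SNP
#' genotypes under Hardy-Weinberg proportions with MAF ~ Unif(mafRange).
#'
#' @slot n,p,q sample and feature counts.
#' @slot gX,gY number of (equal-size) groups per side.
#' @slot thetaX,thetaY effect vectors; nonzero entries mark the true
#'   correlated features.
#' @slot sigmaGamma,sigmaE latent and noise standard deviations.
#' @slot rho within-group autoregressive base correlation.
#' @slot betweenRange,irrelevantRange,mafRange numeric length-2 ranges.
#' @slot snpSide \code{"none"} or \code{"Y"}.
#' @slot sweep named list of sweep values for the multi-condition studies
#'   (may be empty).
#' @seealso [simConfig()], [simPreset()], [simulateCCAData()]
#' @export
setClass("SimConfig",
  representation(n = "integer", p = "integer", q = "integer",
                 gX = "integer", gY = "integer",
                 thetaX = "numeric", thetaY = "numeric",
                 sigmaGamma = "numeric", sigmaE = "numeric", rho = "numeric",
                 betweenRange = "numeric", irrelevantRange = "numeric",
                 snpSide = "character", mafRange = "numeric",
                 sweep = "list"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (length(object@thetaX) != object@p || length(object@thetaY) != object@q)
    msg <- c(msg, "theta vectors must have lengths p and q")
  if (object@p %% object@gX != 0L || object@q %% object@gY != 0L)
    msg <- c(msg, "p and q must be multiples of the group counts")
  if (object@rho < 0 || object@rho >= 1)
    msg <- c(msg, "rho must lie in [0, 1)")
  if (object@sigmaGamma <= 0 || object@sigmaE <= 0)
    msg <- c(msg, "sigmaGamma and sigmaE must be positive")
  if (!(object@snpSide %in% c("none", "Y")))
    msg <- c(msg, "snpSide must be 'none' or 'Y'")
  for (s in c("betweenRange", "irrelevantRange", "mafRange")) {
    r <- slot(object, s)
    if (length(r) != 2L || r[1] > r[2])
      msg <- c(msg, sprintf("%s must be an ordered length-2 range", s))
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated dataset
#'
#' Records everything needed to score a fitted model against the generating
#' mechanism: the true supports, the group layout, and the generating
#' parameters.
#'
#' @slot supportX,supportY integer indices of the truly correlated features.
#' @slot groupsX,groupsY [GroupPartition-class] per side.
#' @slot thetaX,thetaY generating effect vectors.
#' @slot sigmaGamma,sigmaE,rho generating scalars.
#' @seealso [simulateCCAData()], [confusionCounts()]
#' @export
setClass("SimTruth",
  representation(supportX = "integer", supportY = "integer",
                 groupsX = "GroupPartition", groupsY = "GroupPartition",
                 thetaX = "numeric", thetaY = "numeric",
                 sigmaGamma = "numeric", sigmaE = "numeric", rho = "numeric"))

setValidity("SimTruth", function(object) {
  okX <- identical(sort(object@supportX), which(object@thetaX != 0))
  okY <- identical(sort(object@supportY), which(object@thetaY != 0))
  if (!okX || !okY) "supports must equal the nonzero theta indices" else TRUE
})

## ---------------------------------------------------------------------------
## Cross-validation result
## ---------------------------------------------------------------------------

#' Cross-validation result
#'
#' Output of [cvSparseCCA()]: the parameter grid with the mean train/test
#' correlation difference (Delta-corr) per cell, the chosen cell, and the
#' per-fold correlations.
#'
#' @slot grid data.frame with columns lambda1, lambda2, tau1, tau2.
#' @slot meanDeltaCorr numeric vector, one value per grid row; \code{Inf}
#'   marks cells with a degenerate (all-zero) fit in some fold.
#' @slot trainCorr,testCorr matrices (grid rows x folds) of per-fold
#'   canonical correlations.
#' @slot best integer row index of the chosen cell.
#' @slot k fold count.
#' @slot seed seed used for the fold assignment.
#' @slot variant model variant tuned.
#' @seealso [cvSparseCCA()], [bestPenalty()]
#' @export
setClass("CCACrossValidation",
  representation(grid = "data.frame", meanDeltaCorr = "numeric",
                 trainCorr = "matrix", testCorr = "matrix",
                 best = "integer", k = "integer", seed = "integer",
                 variant = "character"))
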