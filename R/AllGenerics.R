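## Generics, accessors and show methods.

#' @describeIn PairedMatrices-class number of samples
#' @param object,x a \code{PairedMatrices} object.
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @export
setMethod("nSamples", "PairedMatrices", function(object) nrow(object@X))

#' Accessors for PairedMatrices
#'
#' @param object a [PairedMatrices-class] object.
#' @return \code{xMatrix}/\code{yMatrix} return the stored matrices;
#'   \code{isStandardized} the standardization flag.
#' @export
setGeneric("xMatrix", function(object) standardGeneric("xMatrix"))

#' @rdname xMatrix
#' @export
setGeneric("yMatrix", function(object) standardGeneric("yMatrix"))

#' @rdname xMatrix
#' @export
setGeneric("isStandardized", function(object) standardGeneric("isStandardized"))

#' @export
setMethod("xMatrix", "PairedMatrices", function(object) object@X)
#' @export
setMethod("yMatrix", "PairedMatrices", function(object) object@Y)
#' @export
setMethod("isStandardized", "PairedMatrices",
          function(object) object@standardized)

#' Standardize columns to mean 0, sd 1
#'
#' Centers and scales every column of both matrices. Constant columns cannot
#' be standardized and raise an error naming the offenders.
#'
#' @param object a [PairedMatrices-class] object.
#' @return A standardized [PairedMatrices-class] object.
#' @export
setGeneric("standardizeColumns",
           function(object) standardGeneric("standardizeColumns"))

#' @export
setMethod("standardizeColumns", "PairedMatrices", function(object) {
  std <- function(M, side) {
    s <- apply(M, 2L, sd)
    if (any(s == 0 | !is.finite(s))) {
      bad <- which(s == 0 | !is.finite(s))
      stop(sprintf("constant column(s) in %s cannot be standardized: %s",
                   side, paste(head(bad, 10L), collapse = ", ")),
           call. = FALSE)
    }
    scale(M)[, , drop = FALSE]
  }
  X <- std(object@X, "X"); Y <- std(object@Y, "Y")
  attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
  attr(Y, "scaled:center") <- attr(Y, "scaled:scale") <- NULL
  new("PairedMatrices", X = X, Y = Y, standardized = TRUE)
})

setMethod("show", "PairedMatrices", function(object) {
  cat(sprintf("PairedMatrices: %d samples; X %d features, Y %d features%s\n",
              nrow(object@X), ncol(object@X), ncol(object@Y),
              if (object@standardized) " (standardized)" else ""))
})

## GroupPartition accessors ---------------------------------------------------

#' Group sizes and weights
#'
#' \code{groupSizes} returns the size s_l of each group; \code{groupWeights}
#' the weights w_l = sqrt(s_l) used by the group penalty; \code{nGroups} the
#' group count; \code{groupLabels} the per-feature label vector.
#'
#' @param object a [GroupPartition-class] object.
#' @return named numeric/integer vectors, in order of first appearance of each
#'   group label.
#' @export
setGeneric("groupSizes", function(object) standardGeneric("groupSizes"))
#' @rdname groupSizes
#' @export
setGeneric("groupWeights", function(object) standardGeneric("groupWeights"))
#' @rdname groupSizes
#' @export
setGeneric("nGroups", function(object) standardGeneric("nGroups"))
#' @rdname groupSizes
#' @export
setGeneric("groupLabels", function(object) standardGeneric("groupLabels"))

#' @export
setMethod("groupSizes", "GroupPartition", function(object) {
  lv <- unique(object@labels)
  setNames(as.integer(table(factor(object@labels, levels = lv))), lv)
})
#' @export
setMethod("groupWeights", "GroupPartition",
          function(object) sqrt(groupSizes(object)))
#' @export
setMethod("nGroups", "GroupPartition",
          function(object) length(unique(object@labels)))
#' @export
setMethod("groupLabels", "GroupPartition", function(object) object@labels)

setMethod("show", "GroupPartition", function(object) {
  cat(sprintf("GroupPartition: %d features in %d disjoint groups\n",
              length(object@labels), nGroups(object)))
})

setMethod("show", "PenaltySpec", function(object) {
  cat(sprintf(
    "PenaltySpec: variant = %s, lambda1 = %g, lambda2 = %g, tau1 = %g, tau2 = %g\n",
    object@variant, object@lambda1, object@lambda2, object@tau1, object@tau2))
})

## CrossProduct ---------------------------------------------------------------

#' @describeIn CrossProduct-class extract the K matrix
#' @param object a \code{CrossProduct} object.
#' @export
setGeneric("kMatrix", function(object) standardGeneric("kMatrix"))
#' @export
setMethod("kMatrix", "CrossProduct", function(object) object@K)

setMethod("show", "CrossProduct", function(object) {
  cat(sprintf("CrossProduct: %d x %d, K = X'Y / %g\n",
              nrow(object@K), ncol(object@K), object@divisor))
})

## Fit accessors --------------------------------------------------------------

#' Extract loading matrices from a fit
#'
#' @param object a [SparseCCAFit-class] object.
#' @param side \code{"x"} or \code{"y"}.
#' @return \code{loadings}: features x pairs matrix of loadings;
#'   \code{correlations}: per-pair sample canonical correlations;
#'   \code{singularValues}: the d of each pair;
#'   \code{nCanonicalPairs}: number of extracted pairs;
#'   \code{selectedFeatures}: list with the integer indices of features with
#'   nonzero loading in the given pair.
#' @export
setGeneric("loadings", function(object, side = c("x", "y"))
  standardGeneric("loadings"))

#' @export
setMethod("loadings", "SparseCCAFit", function(object, side = c("x", "y")) {
  side <- match.arg(side)
  vecs <- lapply(object@pairs, function(p) if (side == "x") p@u else p@v)
  M <- do.call(cbind, vecs)
  rownames(M) <- if (side == "x") object@featureNamesX else object@featureNamesY
  colnames(M) <- sprintf("pair%d", seq_along(vecs))
  M
})

#' @rdname loadings
#' @export
setGeneric("correlations", function(object) standardGeneric("correlations"))
#' @export
setMethod("correlations", "SparseCCAFit", function(object)
  vapply(object@pairs, function(p) p@sampleCorrelation, numeric(1)))

#' @rdname loadings
#' @export
setGeneric("singularValues", function(object) standardGeneric("singularValues"))
#' @export
setMethod("singularValues", "SparseCCAFit", function(object)
  vapply(object@pairs, function(p) p@d, numeric(1)))

#' @rdname loadings
#' @export
setGeneric("nCanonicalPairs",
           function(object) standardGeneric("nCanonicalPairs"))
#' @export
setMethod("nCanonicalPairs", "SparseCCAFit",
          function(object) length(object@pairs))

#' @rdname loadings
#' @param pair index of the canonical pair.
#' @export
setGeneric("selectedFeatures", function(object, pair = 1L)
  standardGeneric("selectedFeatures"))
#' @export
setMethod("selectedFeatures", "SparseCCAFit", function(object, pair = 1L) {
  p <- object@pairs[[pair]]
  list(x = which(p@u != 0), y = which(p@v != 0))
})

#' @rdname loadings
#' @export
setGeneric("canonicalPair", function(object, pair = 1L)
  standardGeneric("canonicalPair"))
#' @export
setMethod("canonicalPair", "SparseCCAFit",
          function(object, pair = 1L) object@pairs[[pair]])

setMethod("show", "CanonicalPair", function(object) {
  cat(sprintf(
    "CanonicalPair: d = %.4g, cor = %s, %d/%d nonzero (u/v), %d iterations%s\n",
    object@d,
    if (is.na(object@sampleCorrelation)) "NA"
    else sprintf("%.4f", object@sampleCorrelation),
    sum(object@u != 0), sum(object@v != 0), object@nIterations,
    if (object@converged) "" else " (not converged)"))
})

setMethod("show", "SparseCCAFit", function(object) {
  cat(sprintf("SparseCCAFit (%s): %d canonical pair(s)\n",
              object@penalty@variant, length(object@pairs)))
  for (i in seq_along(object@pairs)) {
    cat(sprintf("  [%d] ", i)); show(object@pairs[[i]])
  }
})

## CV accessors ---------------------------------------------------------------

#' Chosen penalty from a cross-validation run
#'
#' @param object a [CCACrossValidation-class] object.
#' @return A [PenaltySpec-class] at the grid cell minimizing the mean
#'   Delta-corr (ties broken toward the sparsest model).
#' @export
setGeneric("bestPenalty", function(object) standardGeneric("bestPenalty"))
#' @export
setMethod("bestPenalty", "CCACrossValidation", function(object) {
  row <- object@grid[object@best, ]
  PenaltySpec(object@variant, lambda1 = row$lambda1, lambda2 = row$lambda2,
              tau1 = row$tau1, tau2 = row$tau2)
})

setMethod("show", "CCACrossValidation", function(object) {
  b <- object@grid[object@best, ]
  cat(sprintf(
    "CCACrossValidation (%s, %d folds, %d cells): best Delta-corr = %.4f at lambda1 = %g, lambda2 = %g, tau1 = %g, tau2 = %g\n",
    object@variant, object@k, nrow(object@grid),
    object@meanDeltaCorr[object@best],
    b$lambda1, b$lambda2, b$tau1, b$tau2))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: n = %d, p = %d (%d groups), q = %d (%d groups), |supp X| = %d, |supp Y| = %d, sigmaGamma = %g, sigmaE = %g, rho = %g, snpSide = %s\n",
    object@n, object@p, object@gX, object@q, object@gY,
    sum(object@thetaX != 0), sum(object@thetaY != 0),
    object@sigmaGamma, object@sigmaE, object@rho, object@snpSide))
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: |supp X| = %d of %d, |supp Y| = %d of %d\n",
              length(object@supportX), length(object@thetaX),
              length(object@supportY), length(object@thetaY)))
})
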