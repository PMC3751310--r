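## Readers/writers and the preprocessing utilities: delimited matrix input
## with sample matching, kNN imputation, correlation-based feature grouping,
## loadings round-trip.

#' Read two delimited matrices and align their samples
#'
#' Reads two delimited text files (first row feature identifiers, first
#' column sample identifiers), intersects the sample identifiers, and
#' returns the matrices aligned in a common sample order. Samples present in
#' only one file are dropped with a message. Standardization is deferred to
#' the solver.
#'
#' @param pathX,pathY file paths.
#' @param sep field separator (default tab; use \code{","} for CSV).
#' @param naStrings strings treated as missing (default empty cell and
#'   \code{"NA"}).
#' @return An unstandardized [PairedMatrices-class] with dimnames.
#' @export
readPairedMatrices <- function(pathX, pathY, sep = "\t",
                               naStrings = c("", "NA")) {
  rd <- function(path) {
    df <- read.table(path, header = TRUE, sep = sep, row.names = NULL,
                     na.strings = naStrings, check.names = FALSE,
                     stringsAsFactors = FALSE)
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
      stop(sprintf("duplicate sample identifiers in %s", path),
           call. = FALSE)
    M <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(M))
      stop(sprintf("non-numeric cells in %s", path), call. = FALSE)
    rownames(M) <- ids
    M
  }
  X <- rd(pathX); Y <- rd(pathY)
  common <- intersect(rownames(X), rownames(Y))
  if (!length(common))
    stop("no samples shared between the two files", call. = FALSE)
  dropped <- length(union(rownames(X), rownames(Y))) - length(common)
  if (dropped > 0)
    message(sprintf("dropped %d sample(s) missing from one file", dropped))
  PairedMatrices(X[common, , drop = FALSE], Y[common, , drop = FALSE])
}

#' Read a two-column feature-to-group mapping
#'
#' @param path TSV file with columns feature_id, group_label (no header
#'   required; a header row is detected and skipped when its first field is
#'   \code{"feature_id"}).
#' @param featureNames feature identifiers in matrix column order; every
#'   feature must be mapped.
#' @return A [GroupPartition-class] in \code{featureNames} order.
#' @export
readGroupFile <- function(path, featureNames) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE,
                   col.names = c("feature_id", "group_label"))
  if (nrow(df) && df$feature_id[1L] == "feature_id") df <- df[-1L, ]
  m <- match(featureNames, df$feature_id)
  if (anyNA(m))
    stop(sprintf("features without a group assignment: %s",
                 paste(head(featureNames[is.na(m)], 5L), collapse = ", ")),
         call. = FALSE)
  GroupPartition(df$group_label[m])
}

#' k-nearest-neighbour imputation of missing entries
#'
#' Features (columns) with more than \code{maxMissing} missing values are
#' dropped first. Each remaining missing entry is replaced by the
#' inverse-distance-weighted average of the value in the k nearest rows,
#' where distance is the Euclidean distance over the columns observed in
#' both rows (scaled to a per-coordinate basis so rows with different
#' overlap are comparable). Rows at distance zero get all the weight.
#'
#' @param M numeric matrix with NAs.
#' @param k number of neighbours (default 16).
#' @param maxMissing per-column missingness cap as a fraction (default
#'   0.15); offending columns are dropped with a message.
#' @return The imputed matrix (possibly with fewer columns).
#' @export
knnImpute <- function(M, k = 16L, maxMissing = 0.15) {
  M <- as.matrix(M)
  frac <- colMeans(is.na(M))
  if (any(frac > maxMissing)) {
    message(sprintf("dropping %d column(s) with > %.0f%% missing values",
                    sum(frac > maxMissing), 100 * maxMissing))
    M <- M[, frac <= maxMissing, drop = FALSE]
  }
  miss <- which(rowSums(is.na(M)) > 0L)
  if (!length(miss)) return(M)
  out <- M
  for (i in miss) {
    obsI <- !is.na(M[i, ])
    cand <- setdiff(seq_len(nrow(M)), i)
    d <- vapply(cand, function(r) {
      shared <- obsI & !is.na(M[r, ])
      if (!any(shared)) return(NA_real_)
      sqrt(mean((M[i, shared] - M[r, shared])^2))
    }, numeric(1))
    for (j in which(is.na(M[i, ]))) {
      ok <- cand[!is.na(d) & !is.na(M[cand, j])]
      if (length(ok) < k)
        stop(sprintf(
          "row %d: fewer than k = %d usable neighbours for column %d",
          i, k, j), call. = FALSE)
      dk <- d[match(ok, cand)]
      nn <- ok[order(dk)[seq_len(k)]]
      dnn <- dk[order(dk)[seq_len(k)]]
      if (any(dnn == 0)) {
        out[i, j] <- mean(M[nn[dnn == 0], j])
      } else {
        w <- (1 / dnn) / sum(1 / dnn)
        out[i, j] <- sum(w * M[nn, j])
      }
    }
  }
  out
}

#' Group features by hierarchical clustering of absolute correlations
#'
#' Clusters the columns of \code{M} with distance 1 - |Pearson r| and cuts
#' the tree at height 1 - threshold, so merges happen only while the linkage
#' distance corresponds to |r| >= threshold. Returns disjoint groups
#' covering all features.
#'
#' @param M numeric matrix (samples x features).
#' @param threshold absolute-correlation threshold in (0, 1); default 0.2.
#' @param linkage agglomeration method for [stats::hclust()] (default
#'   \code{"average"}).
#' @return A [GroupPartition-class] over the columns of \code{M}.
#' @export
correlationGroups <- function(M, threshold = 0.2, linkage = "average") {
  M <- as.matrix(M)
  if (ncol(M) < 2L) stop("at least two features are required", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  s <- apply(M, 2L, sd)
  if (any(s == 0)) {
    stop(sprintf("constant column(s) have undefined correlation: %s",
                 paste(head(which(s == 0), 10L), collapse = ", ")),
         call. = FALSE)
  }
  D <- as.dist(1 - abs(cor(M)))
  hc <- hclust(D, method = linkage)
  cl <- cutree(hc, h = 1 - threshold)
  GroupPartition(sprintf("c%d", cl))
}

#' Write and read loading tables
#'
#' Loadings are written as TSV with columns \code{feature_id}, \code{side},
#' \code{pair_index}, \code{weight} at full double precision, so a
#' write/read round trip reproduces the values exactly.
#'
#' @param fit a [SparseCCAFit-class].
#' @param path output file path.
#' @return \code{writeLoadings} returns \code{path} invisibly;
#'   \code{readLoadings} returns the data.frame.
#' @export
writeLoadings <- function(fit, path) {
  stopifnot(is(fit, "SparseCCAFit"))
  rows <- lapply(seq_along(fit@pairs), function(j) {
    p <- fit@pairs[[j]]
    rbind(
      data.frame(feature_id = fit@featureNamesX, side = "x",
                 pair_index = j, weight = p@u),
      data.frame(feature_id = fit@featureNamesY, side = "y",
                 pair_index = j, weight = p@v))
  })
  df <- do.call(rbind, rows)
  df$weight <- sprintf("%.17g", df$weight)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLoadings
#' @export
readLoadings <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c("character", "character", "integer", "numeric"))
}

#' Write pair summaries as JSON
#'
#' @param fit a [SparseCCAFit-class].
#' @param path output file path.
#' @param seed optional seed to record for provenance.
#' @return \code{path}, invisibly.
#' @export
writePairSummaries <- function(fit, path, seed = NULL) {
  stopifnot(is(fit, "SparseCCAFit"))
  pen <- fit@penalty
  out <- list(
    variant = pen@variant,
    penalty = list(lambda1 = pen@lambda1, lambda2 = pen@lambda2,
                   tau1 = pen@tau1, tau2 = pen@tau2),
    seed = seed,
    pairs = lapply(fit@pairs, function(p) list(
      d = p@d, correlation = p@sampleCorrelation,
      iterations = p@nIterations, converged = p@converged,
      nonzeroU = sum(p@u != 0), nonzeroV = sum(p@v != 0))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
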