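## Penalty tuning by k-fold cross-validation on the train/test correlation
## difference, permutation tests, train/test split evaluation and ROC sweeps.

## Evaluate expr under a temporary seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Mean train/test correlation difference
#'
#' The cross-validation criterion: the mean over folds of the absolute
#' difference between the canonical correlation on the training subset and on
#' the held-out subset. Zero iff the two sequences match exactly; penalty
#' parameters are chosen to minimize it, favouring models whose correlation
#' generalizes.
#'
#' @param trainCorrs,testCorrs numeric vectors of equal length (one entry per
#'   fold).
#' @return A single nonnegative number.
#' @examples
#' deltaCorr(c(0.9, 0.8), c(0.7, 0.8))  # 0.1
#' @export
deltaCorr <- function(trainCorrs, testCorrs) {
  if (length(trainCorrs) != length(testCorrs))
    stop("trainCorrs and testCorrs must have the same length", call. = FALSE)
  if (length(trainCorrs) < 1L) stop("at least one fold is required",
                                    call. = FALSE)
  mean(abs(trainCorrs - testCorrs))
}

#' Build a penalty parameter grid
#'
#' Expands the supplied value sequences into a data.frame of grid cells. The
#' default lambda sequence 0.04, 0.08, ..., 0.4 matches the 10-value grid
#' used in the simulation studies; the default tau sequence is 10 equally
#' spaced values 0.05, ..., 0.95. Two-parameter variants (\code{"l1"},
#' \code{"group"}) should pass singleton tau values.
#'
#' @param lambda1,lambda2 nonnegative value sequences.
#' @param tau1,tau2 sequences in \[0, 1\].
#' @return data.frame with columns lambda1, lambda2, tau1, tau2.
#' @export
penaltyGrid <- function(lambda1 = seq(0.04, 0.4, by = 0.04),
                        lambda2 = lambda1,
                        tau1 = 0.5, tau2 = tau1) {
  stopifnot(length(lambda1) > 0, length(lambda2) > 0,
            length(tau1) > 0, length(tau2) > 0,
            all(lambda1 >= 0), all(lambda2 >= 0),
            all(tau1 >= 0 & tau1 <= 1), all(tau2 >= 0 & tau2 <= 1))
  expand.grid(lambda1 = lambda1, lambda2 = lambda2,
              tau1 = tau1, tau2 = tau2, KEEP.OUT.ATTRS = FALSE)
}

## Standardize train columns and apply the train center/scale to test rows.
## Standardization parameters come from the training fold only, so no
## information leaks from the held-out samples.
.foldStandardize <- function(X, trainIdx) {
  Xtr <- X[trainIdx, , drop = FALSE]
  mu <- colMeans(Xtr)
  s <- apply(Xtr, 2L, sd)
  if (any(s == 0 | !is.finite(s)))
    stop("constant column in a training fold; cannot standardize",
         call. = FALSE)
  list(train = scale(Xtr, center = mu, scale = s),
       test = scale(X[-trainIdx, , drop = FALSE], center = mu, scale = s))
}

#' Tune penalties by k-fold cross-validation
#'
#' For every grid cell, fits the first canonical pair on each training fold
#' and scores the cell by [deltaCorr()] between the training correlation
#' cor(X_train u, Y_train v) and the held-out correlation
#' cor(X_test u, Y_test v). Standardization parameters are estimated on each
#' training fold and applied to its test fold. Cells where some fold's fit is
#' degenerate (a penalty zeroing a whole side) receive an infinite score and
#' are never chosen. Ties on the minimal score are broken toward the
#' sparsest model (largest lambda1 + lambda2, then largest tau1 + tau2).
#' Fold assignment is a uniform random partition, deterministic given
#' \code{seed}.
#'
#' @param data a [PairedMatrices-class] object (unstandardized is fine).
#' @param grid data.frame from [penaltyGrid()].
#' @param variant model variant, see [PenaltySpec()].
#' @param groupsX,groupsY optional [GroupPartition-class] per side.
#' @param k number of folds (>= 2; n must be at least 2k).
#' @param seed integer seed for the fold assignment.
#' @param tol,maxIter solver settings for the fold fits.
#' @return A [CCACrossValidation-class] object.
#' @export
cvSparseCCA <- function(data, grid, variant = "sparse_group",
                        groupsX = NULL, groupsY = NULL,
                        k = 5L, seed = 1L, tol = 1e-5, maxIter = 200L) {
  stopifnot(is(data, "PairedMatrices"), is.data.frame(grid),
            all(c("lambda1", "lambda2", "tau1", "tau2") %in% names(grid)))
  n <- nSamples(data)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (n < 2L * k) stop("need at least 2 samples per fold", call. = FALSE)
  X <- xMatrix(data); Y <- yMatrix(data)
  p <- ncol(X); q <- ncol(Y)
  if (is.null(groupsX)) groupsX <- singletonGroups(p)
  if (is.null(groupsY)) groupsY <- singletonGroups(q)
  folds <- .withSeed(seed, sample(rep(seq_len(k), length.out = n)))
  nc <- nrow(grid)
  trainCorr <- matrix(NA_real_, nc, k)
  testCorr <- matrix(NA_real_, nc, k)
  for (fold in seq_len(k)) {
    trIdx <- which(folds != fold)
    sx <- .foldStandardize(X, trIdx)
    sy <- .foldStandardize(Y, trIdx)
    Ktr <- crossprod(sx$train, sy$train) / (length(trIdx) - 1)
    init <- .leadingPair(Ktr)
    for (i in seq_len(nc)) {
      pen <- PenaltySpec(variant, lambda1 = grid$lambda1[i],
                         lambda2 = grid$lambda2[i],
                         tau1 = grid$tau1[i], tau2 = grid$tau2[i])
      pair <- tryCatch(
        fitCanonicalPair(Ktr, pen, groupsX, groupsY,
                         initU = init$u, initV = init$v,
                         tol = tol, maxIter = maxIter),
        gsccaDegenerateError = function(e) NULL)
      if (is.null(pair)) next
      aTr <- drop(sx$train %*% pair@u); bTr <- drop(sy$train %*% pair@v)
      aTe <- drop(sx$test %*% pair@u); bTe <- drop(sy$test %*% pair@v)
      if (sd(aTr) > 0 && sd(bTr) > 0)
        trainCorr[i, fold] <- cor(aTr, bTr)
      if (sd(aTe) > 0 && sd(bTe) > 0)
        testCorr[i, fold] <- cor(aTe, bTe)
    }
  }
  score <- vapply(seq_len(nc), function(i) {
    tr <- trainCorr[i, ]; te <- testCorr[i, ]
    if (anyNA(tr) || anyNA(te)) Inf else deltaCorr(tr, te)
  }, numeric(1))
  finite <- which(is.finite(score))
  if (!length(finite))
    stop("every grid cell produced a degenerate fit; reduce the lambdas",
         call. = FALSE)
  best <- finite[score[finite] <= min(score[finite]) + 1e-12]
  if (length(best) > 1L) {
    sparsity <- grid$lambda1[best] + grid$lambda2[best]
    best <- best[sparsity == max(sparsity)]
    if (length(best) > 1L) {
      tsum <- grid$tau1[best] + grid$tau2[best]
      best <- best[which.max(tsum)]
    }
  }
  new("CCACrossValidation", grid = grid, meanDeltaCorr = score,
      trainCorr = trainCorr, testCorr = testCorr,
      best = as.integer(best[1L]), k = as.integer(k),
      seed = as.integer(seed), variant = variant)
}

#' Permutation p-value for a canonical correlation
#'
#' Holds the loading vectors (hence the selected features) fixed, permutes
#' the sample order of one matrix \code{nPerm} times, and recomputes
#' cor(Xu, Y_perm v) each time to approximate the null distribution of the
#' canonical correlation. The p-value is reported with add-one smoothing,
#' (#\{perm >= observed\} + 1) / (nPerm + 1), which can never be exactly
#' zero; the raw proportion is returned alongside.
#'
#' @param data a [PairedMatrices-class] object.
#' @param u,v loading vectors (selected features stay fixed under
#'   permutation).
#' @param nPerm number of permutations (>= 1).
#' @param seed integer seed.
#' @param permute which matrix's rows to permute (default \code{"Y"}).
#' @return A list with elements \code{pValue} (add-one estimate),
#'   \code{rawProportion}, \code{observed} and \code{permCorrelations}.
#' @export
permutationPValue <- function(data, u, v, nPerm = 1000L, seed = 1L,
                              permute = c("Y", "X")) {
  stopifnot(is(data, "PairedMatrices"))
  permute <- match.arg(permute)
  if (nPerm < 1L) stop("nPerm must be at least 1", call. = FALSE)
  a <- drop(xMatrix(data) %*% u)
  b <- drop(yMatrix(data) %*% v)
  if (sd(a) == 0 || sd(b) == 0)
    stop("zero-variance canonical variate; correlation undefined",
         call. = FALSE)
  observed <- cor(a, b)
  n <- length(a)
  perms <- .withSeed(seed, {
    vapply(seq_len(nPerm), function(i) {
      idx <- sample.int(n)
      if (permute == "Y") cor(a, b[idx]) else cor(a[idx], b)
    }, numeric(1))
  })
  exceed <- sum(perms >= observed)
  list(pValue = (exceed + 1) / (nPerm + 1),
       rawProportion = exceed / nPerm,
       observed = observed, permCorrelations = perms)
}

#' Repeated train/test split evaluation
#'
#' Repeatedly divides the samples into a training and a held-out set, tunes
#' the penalties on the training set by [cvSparseCCA()], refits on the
#' training set, and records the held-out correlation and the selected
#' features. Feature stability is summarized as the set of features selected
#' in more than \code{stabilityThreshold} of the repeats.
#'
#' @param data a [PairedMatrices-class] object.
#' @param nTrain training set size (< n).
#' @param nRepeats number of random splits.
#' @param grid penalty grid (see [penaltyGrid()]).
#' @param variant model variant.
#' @param groupsX,groupsY optional [GroupPartition-class] per side.
#' @param k CV folds within each training set.
#' @param seed integer seed controlling splits and fold assignments.
#' @param stabilityThreshold fraction of repeats a feature must exceed to
#'   count as stable (default 2/3).
#' @param tol,maxIter solver settings.
#' @return A list with \code{correlations} (held-out correlation per repeat,
#'   NA for degenerate repeats), \code{selectedX}, \code{selectedY} (lists of
#'   index vectors), \code{stableX}, \code{stableY} (stable feature indices)
#'   and \code{chosen} (data.frame of chosen penalties per repeat).
#' @export
splitEvaluate <- function(data, nTrain, nRepeats, grid,
                          variant = "sparse_group",
                          groupsX = NULL, groupsY = NULL, k = 5L, seed = 1L,
                          stabilityThreshold = 2 / 3,
                          tol = 1e-5, maxIter = 200L) {
  stopifnot(is(data, "PairedMatrices"))
  n <- nSamples(data)
  if (nTrain >= n) stop("nTrain must be smaller than the sample count",
                        call. = FALSE)
  X <- xMatrix(data); Y <- yMatrix(data)
  p <- ncol(X); q <- ncol(Y)
  corrs <- rep(NA_real_, nRepeats)
  selX <- vector("list", nRepeats); selY <- vector("list", nRepeats)
  chosen <- vector("list", nRepeats)
  .withSeed(seed, {
    for (r in seq_len(nRepeats)) {
      trIdx <- sort(sample.int(n, nTrain))
      foldSeed <- sample.int(.Machine$integer.max, 1L)
      train <- PairedMatrices(X[trIdx, , drop = FALSE],
                              Y[trIdx, , drop = FALSE])
      res <- tryCatch({
        cv <- cvSparseCCA(train, grid, variant, groupsX, groupsY,
                          k = k, seed = foldSeed, tol = tol,
                          maxIter = maxIter)
        pen <- bestPenalty(cv)
        fit <- sparseCCA(train, pen, groupsX, groupsY, nPairs = 1L,
                         tol = tol, maxIter = maxIter)
        pair <- canonicalPair(fit)
        sx <- .foldStandardize(X, trIdx)
        sy <- .foldStandardize(Y, trIdx)
        aTe <- drop(sx$test %*% pair@u); bTe <- drop(sy$test %*% pair@v)
        list(corr = if (sd(aTe) > 0 && sd(bTe) > 0) cor(aTe, bTe)
                    else NA_real_,
             selX = which(pair@u != 0), selY = which(pair@v != 0),
             pen = data.frame(lambda1 = pen@lambda1, lambda2 = pen@lambda2,
                              tau1 = pen@tau1, tau2 = pen@tau2))
      }, gsccaDegenerateError = function(e) NULL, error = function(e) NULL)
      if (!is.null(res)) {
        corrs[r] <- res$corr
        selX[[r]] <- res$selX; selY[[r]] <- res$selY
        chosen[[r]] <- res$pen
      } else {
        selX[[r]] <- integer(); selY[[r]] <- integer()
      }
    }
  })
  countX <- tabulate(unlist(selX), nbins = p)
  countY <- tabulate(unlist(selY), nbins = q)
  list(correlations = corrs, selectedX = selX, selectedY = selY,
       stableX = which(countX > stabilityThreshold * nRepeats),
       stableY = which(countY > stabilityThreshold * nRepeats),
       chosen = do.call(rbind, chosen))
}

#' ROC curve for support recovery over a penalty sweep
#'
#' For each replicate, simulates a dataset from \code{config}, tunes the
#' penalties by cross-validation on \code{grid}, then varies one parameter
#' across \code{varyValues} while holding the others at their tuned values,
#' scoring the selected support of the first canonical pair against the
#' simulation truth. Points are averaged over replicates and sorted by total
#' false positive rate. Degenerate fits during the sweep select nothing and
#' contribute the (0, 0) corner.
#'
#' @param config a [SimConfig-class] object.
#' @param variant model variant.
#' @param grid penalty grid used for the tuning step.
#' @param vary name of the swept parameter (\code{"lambda1"},
#'   \code{"lambda2"}, \code{"tau1"} or \code{"tau2"}).
#' @param varyValues values to sweep; defaults to the distinct values of
#'   \code{vary} in \code{grid}.
#' @param nReplicates number of simulated replicates to average over.
#' @param k CV folds.
#' @param seed integer seed.
#' @param tol,maxIter solver settings.
#' @return data.frame with columns \code{value}, \code{tfpr}, \code{ttpr}
#'   (replicate means), sorted by \code{tfpr}.
#' @export
rocCurve <- function(config, variant, grid,
                     vary = c("lambda1", "lambda2", "tau1", "tau2"),
                     varyValues = NULL, nReplicates = 5L, k = 5L, seed = 1L,
                     tol = 1e-5, maxIter = 200L) {
  stopifnot(is(config, "SimConfig"))
  vary <- match.arg(vary)
  if (is.null(varyValues)) varyValues <- sort(unique(grid[[vary]]))
  nv <- length(varyValues)
  ttprM <- matrix(NA_real_, nReplicates, nv)
  tfprM <- matrix(NA_real_, nReplicates, nv)
  seeds <- .withSeed(seed,
                     sample.int(.Machine$integer.max, 2L * nReplicates))
  for (r in seq_len(nReplicates)) {
    sim <- simulateCCAData(config, seed = seeds[r])
    cv <- cvSparseCCA(sim$data, grid, variant,
                      sim$truth@groupsX, sim$truth@groupsY,
                      k = k, seed = seeds[nReplicates + r],
                      tol = tol, maxIter = maxIter)
    base <- bestPenalty(cv)
    for (i in seq_len(nv)) {
      pen <- base
      slot(pen, vary) <- varyValues[i]
      if (pen@variant == "group") { pen@tau1 <- 0; pen@tau2 <- 0 }
      if (pen@variant == "l1")    { pen@tau1 <- 1; pen@tau2 <- 1 }
      sel <- tryCatch({
        fit <- sparseCCA(sim$data, pen, sim$truth@groupsX,
                         sim$truth@groupsY, nPairs = 1L,
                         tol = tol, maxIter = maxIter)
        selectedFeatures(fit)
      }, gsccaDegenerateError = function(e) list(x = integer(),
                                                 y = integer()))
      cc <- confusionCounts(sel$x, sel$y, sim$truth)
      ttprM[r, i] <- ttpr(cc)
      tfprM[r, i] <- tfpr(cc)
    }
  }
  out <- data.frame(value = varyValues,
                    tfpr = colMeans(tfprM), ttpr = colMeans(ttprM))
  out[order(out$tfpr, out$ttpr), , drop = FALSE]
}
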