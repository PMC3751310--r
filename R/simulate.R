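## Latent-factor simulation framework: grouped covariance construction,
## paired data generation, SNP discretization and the four study presets.

#' Construct a SimConfig
#'
#' @param n,p,q sample and feature counts.
#' @param gX,gY group counts (groups have equal size p/gX and q/gY).
#' @param thetaX,thetaY effect vectors of lengths p and q; nonzero entries
#'   define the truly correlated features.
#' @param sigmaGamma,sigmaE latent and noise standard deviations.
#' @param rho within-group autoregressive base correlation in \[0, 1).
#' @param betweenRange range of the between-group correlation among true
#'   features (default Unif(0.2, 0.4)).
#' @param irrelevantRange range of the covariance among irrelevant features
#'   (default Unif(0, 0.2)).
#' @param snpSide \code{"none"} or \code{"Y"}: discretize the Y side into
#'   three-level SNP genotypes.
#' @param mafRange minor allele frequency range (default Unif(0.2, 0.4)).
#' @param sweep optional named list of sweep values for multi-condition
#'   studies.
#' @return A [SimConfig-class] object.
#' @seealso [simPreset()], [simulateCCAData()]
#' @export
simConfig <- function(n, p, q, gX, gY, thetaX, thetaY,
                      sigmaGamma = 1, sigmaE = 0.5, rho = 0.5,
                      betweenRange = c(0.2, 0.4),
                      irrelevantRange = c(0, 0.2),
                      snpSide = "none", mafRange = c(0.2, 0.4),
                      sweep = list()) {
  new("SimConfig", n = as.integer(n), p = as.integer(p), q = as.integer(q),
      gX = as.integer(gX), gY = as.integer(gY),
      thetaX = as.numeric(thetaX), thetaY = as.numeric(thetaY),
      sigmaGamma = sigmaGamma, sigmaE = sigmaE, rho = rho,
      betweenRange = betweenRange, irrelevantRange = irrelevantRange,
      snpSide = snpSide, mafRange = mafRange, sweep = sweep)
}

## Effect vector with trueGroups leading groups each holding truePerGroup
## true features (placed at the group head; noise features are exchangeable,
## so deterministic placement is statistically equivalent to random
## placement within the group). Magnitude pattern: a quarter at +1, half at
## -1, a quarter at +1.5 on the X side, mirrored on the Y side.
.makeTheta <- function(p, groupSize, trueGroups, truePerGroup, side) {
  nTrue <- trueGroups * truePerGroup
  n1 <- round(nTrue / 4); n3 <- round(nTrue / 4); n2 <- nTrue - n1 - n3
  mags <- if (side == "X") c(rep(1, n1), rep(-1, n2), rep(1.5, n3))
          else c(rep(-1, n1), rep(-1.5, n3), rep(1, n2))
  theta <- numeric(p)
  for (g in seq_len(trueGroups)) {
    idx <- (g - 1L) * groupSize + seq_len(truePerGroup)
    theta[idx] <- mags[(g - 1L) * truePerGroup + seq_len(truePerGroup)]
  }
  theta
}

#' Configurations of the four simulation studies
#'
#' Returns the generating configuration of each study:
#' \describe{
#'   \item{sim1}{support recovery: n = 100, p = 400 (20 groups of 20),
#'     q = 500 (25 groups of 20), 60 true features per side in 4 groups
#'     (15 true + 5 noise each), sigmaGamma = 1, sigmaE = 0.5; thetaX has
#'     15 entries at 1, 30 at -1, 15 at 1.5, thetaY has 15 at -1, 15 at
#'     -1.5, 30 at 1.}
#'   \item{sim2}{group-size effect: p = 400 (40 groups of 10), q = 500
#'     (50 groups of 10), 40 true features per side, sigmaE = 0.3; the sweep
#'     distributes them over (4, 5, 8, 10, 20, 40) groups holding
#'     (10, 8, 5, 4, 2, 1) true features each.}
#'   \item{sim3}{sample-size effect: p = 400 (40 groups of 10), q = 500
#'     (50 groups of 10), 60 true features per side evenly in 6 groups;
#'     sweep n = 50, 100, ..., 500.}
#'   \item{sim4}{noise effect: p = 200 (20 groups of 10), q = 250 (25 groups
#'     of 10), 20 true features in X and 30 in Y; sweep sigmaE = 0.1, ...,
#'     1.0.}
#' }
#' Sweep values are carried in the \code{sweep} slot; the returned config
#' holds the first sweep condition. Use [sweepConfig()] to materialize the
#' others.
#'
#' @param name one of \code{"sim1"}, \code{"sim2"}, \code{"sim3"},
#'   \code{"sim4"}.
#' @return A [SimConfig-class] object.
#' @examples
#' cfg <- simPreset("sim1")
#' sum(cfg@thetaX != 0)  # 60
#' @export
simPreset <- function(name = c("sim1", "sim2", "sim3", "sim4")) {
  name <- match.arg(name)
  switch(name,
    sim1 = simConfig(
      n = 100, p = 400, q = 500, gX = 20, gY = 25,
      thetaX = .makeTheta(400, 20, 4, 15, "X"),
      thetaY = .makeTheta(500, 20, 4, 15, "Y"),
      sigmaGamma = 1, sigmaE = 0.5),
    sim2 = simConfig(
      n = 100, p = 400, q = 500, gX = 40, gY = 50,
      thetaX = .makeTheta(400, 10, 4, 10, "X"),
      thetaY = .makeTheta(500, 10, 4, 10, "Y"),
      sigmaGamma = 1, sigmaE = 0.3,
      sweep = list(trueGroups = c(4, 5, 8, 10, 20, 40),
                   truePerGroup = c(10, 8, 5, 4, 2, 1))),
    sim3 = simConfig(
      n = 100, p = 400, q = 500, gX = 40, gY = 50,
      thetaX = .makeTheta(400, 10, 6, 10, "X"),
      thetaY = .makeTheta(500, 10, 6, 10, "Y"),
      sigmaGamma = 1, sigmaE = 0.5,
      sweep = list(n = seq(50, 500, by = 50))),
    sim4 = simConfig(
      n = 100, p = 200, q = 250, gX = 20, gY = 25,
      thetaX = .makeTheta(200, 10, 2, 10, "X"),
      thetaY = .makeTheta(250, 10, 3, 10, "Y"),
      sigmaGamma = 1, sigmaE = 0.1,
      sweep = list(sigmaE = seq(0.1, 1, by = 0.1))))
}

#' Materialize one condition of a preset's sweep
#'
#' @param config a [SimConfig-class] with a non-empty \code{sweep} slot.
#' @param index which sweep condition to instantiate.
#' @return A [SimConfig-class] for that condition.
#' @export
sweepConfig <- function(config, index) {
  stopifnot(is(config, "SimConfig"), length(config@sweep) > 0)
  sw <- config@sweep
  if (!is.null(sw$n)) config@n <- as.integer(sw$n[index])
  if (!is.null(sw$sigmaE)) config@sigmaE <- sw$sigmaE[index]
  if (!is.null(sw$trueGroups)) {
    tg <- sw$trueGroups[index]; tpg <- sw$truePerGroup[index]
    config@thetaX <- .makeTheta(config@p, config@p %/% config@gX, tg, tpg,
                                "X")
    config@thetaY <- .makeTheta(config@q, config@q %/% config@gY, tg, tpg,
                                "Y")
  }
  validObject(config)
  config
}

#' Grouped covariance matrix with autoregressive support blocks
#'
#' Builds the feature covariance of one side: truly correlated features
#' within the same group get the autoregressive correlation rho^|i-j| (i, j
#' their positions among the group's true features); true features of
#' different groups get one correlation drawn from Unif(betweenRange) per
#' group pair; irrelevant feature pairs get independent Unif(irrelevantRange)
#' covariances; diagonal 1, true-by-irrelevant entries 0. Because this
#' piecewise construction is not guaranteed positive semi-definite, the
#' result is repaired by clipping negative eigenvalues at zero and rescaling
#' back to unit diagonal (set \code{strict = TRUE} to error instead).
#'
#' @param groups a [GroupPartition-class] (or label vector).
#' @param support integer indices of the true features.
#' @param rho autoregressive base correlation in \[0, 1).
#' @param betweenRange,irrelevantRange length-2 ranges.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @param strict error instead of repairing when the raw matrix has an
#'   eigenvalue below -1e-8.
#' @return A covariance matrix with attributes \code{minEigenRaw} and
#'   \code{repaired}.
#' @export
simGroupCovariance <- function(groups, support, rho,
                               betweenRange = c(0.2, 0.4),
                               irrelevantRange = c(0, 0.2),
                               seed = NULL, strict = FALSE) {
  if (!is(groups, "GroupPartition")) groups <- GroupPartition(groups)
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  lab <- groupLabels(groups)
  p <- length(lab)
  support <- sort(unique(as.integer(support)))
  stopifnot(all(support >= 1 & support <= p))
  build <- function() {
    Sigma <- diag(p)
    suppByGroup <- split(support, lab[support])
    ## AR blocks within each group's true features
    for (idx in suppByGroup) {
      pos <- seq_along(idx)
      Sigma[idx, idx] <- rho^abs(outer(pos, pos, "-"))
    }
    ## one between-group correlation per group pair
    gl <- names(suppByGroup)
    if (length(gl) > 1L) {
      for (a in seq_len(length(gl) - 1L)) for (b in (a + 1L):length(gl)) {
        val <- runif(1, betweenRange[1], betweenRange[2])
        Sigma[suppByGroup[[a]], suppByGroup[[b]]] <- val
        Sigma[suppByGroup[[b]], suppByGroup[[a]]] <- val
      }
    }
    ## irrelevant block: independent symmetric Unif draws
    irr <- setdiff(seq_len(p), support)
    ni <- length(irr)
    if (ni > 1L) {
      up <- which(upper.tri(matrix(0, ni, ni)))
      B <- matrix(0, ni, ni)
      B[up] <- runif(length(up), irrelevantRange[1], irrelevantRange[2])
      B <- B + t(B)
      diag(B) <- 1
      Sigma[irr, irr] <- B
    }
    Sigma
  }
  Sigma <- if (is.null(seed)) build() else .withSeed(seed, build())
  e <- eigen(Sigma, symmetric = TRUE)
  minEig <- min(e$values)
  repaired <- FALSE
  if (minEig < -1e-8) {
    if (strict)
      stop(sprintf(
        "covariance construction is not PSD (min eigenvalue %.3g)", minEig),
        call. = FALSE)
    vals <- pmax(e$values, 0)
    Sigma <- e$vectors %*% (vals * t(e$vectors))
    Sigma <- stats::cov2cor(Sigma)
    Sigma <- (Sigma + t(Sigma)) / 2
    repaired <- TRUE
  }
  structure(Sigma, minEigenRaw = minEig, repaired = repaired)
}

#' Discretize continuous columns into SNP genotypes
#'
#' Converts each column into three genotype levels \{-1, 0, 1\} under
#' Hardy-Weinberg proportions: with a minor allele frequency p drawn from
#' \code{mafRange} per column, the lowest p^2 fraction of values (by rank)
#' becomes -1, the next 2p(1-p) fraction 0, and the top (1-p)^2 fraction 1.
#' The rank-based cut preserves the ordering of the underlying continuous
#' values, so the SNP side stays correlated with the latent factor.
#'
#' @param Y numeric matrix.
#' @param mafRange minor allele frequency range, a subset of (0, 0.5\].
#' @param seed integer seed for the per-column MAF draws, or NULL to use the
#'   current RNG state.
#' @return Integer matrix with values in \{-1, 0, 1\} and attribute
#'   \code{maf} (the per-column MAF used).
#' @export
discretizeSNP <- function(Y, mafRange = c(0.2, 0.4), seed = NULL) {
  Y <- as.matrix(Y)
  if (length(mafRange) != 2L || mafRange[1] <= 0 || mafRange[2] > 0.5 ||
      mafRange[1] > mafRange[2])
    stop("mafRange must be an ordered range within (0, 0.5]", call. = FALSE)
  run <- function() {
    n <- nrow(Y)
    maf <- runif(ncol(Y), mafRange[1], mafRange[2])
    G <- matrix(0L, n, ncol(Y), dimnames = dimnames(Y))
    for (j in seq_len(ncol(Y))) {
      pj <- maf[j]
      r <- rank(Y[, j], ties.method = "first")
      n1 <- round(n * pj^2)
      n2 <- round(n * (pj^2 + 2 * pj * (1 - pj)))
      G[, j] <- ifelse(r <= n1, -1L, ifelse(r <= n2, 0L, 1L))
    }
    structure(G, maf = maf)
  }
  if (is.null(seed)) run() else .withSeed(seed, run())
}

#' Simulate a paired dataset from the latent-factor model
#'
#' Draws a latent factor gamma_i ~ N(0, sigmaGamma^2) per sample and
#' generates rows x_i ~ N(thetaX gamma_i, sigmaE^2 Sigma_p) and
#' y_i ~ N(thetaY gamma_i, sigmaE^2 Sigma_q), with the grouped covariances
#' from [simGroupCovariance()]. The latent factor is shared between the two
#' sides, which is what induces the cross-correlation. When
#' \code{config@snpSide == "Y"} the Y side is discretized by
#' [discretizeSNP()]. Deterministic given \code{seed}.
#'
#' @param config a [SimConfig-class].
#' @param seed integer seed.
#' @return A list with \code{data} (unstandardized
#'   [PairedMatrices-class]), \code{truth} (a [SimTruth-class]) and
#'   \code{maxCorrelation}, a reference-only estimate of the highest
#'   attainable canonical correlation under the generating model (computed
#'   with loading directions proportional to thetaX, thetaY).
#' @examples
#' sim <- simulateCCAData(simPreset("sim1"), seed = 7)
#' sim$truth
#' @export
simulateCCAData <- function(config, seed) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  groupsX <- GroupPartition(rep(sprintf("g%d", seq_len(config@gX)),
                                each = config@p %/% config@gX))
  groupsY <- GroupPartition(rep(sprintf("g%d", seq_len(config@gY)),
                                each = config@q %/% config@gY))
  suppX <- which(config@thetaX != 0)
  suppY <- which(config@thetaY != 0)
  out <- .withSeed(seed, {
    SigmaX <- simGroupCovariance(groupsX, suppX, config@rho,
                                 config@betweenRange,
                                 config@irrelevantRange)
    SigmaY <- simGroupCovariance(groupsY, suppY, config@rho,
                                 config@betweenRange,
                                 config@irrelevantRange)
    gamma <- rnorm(config@n, 0, config@sigmaGamma)
    X <- outer(gamma, config@thetaX) +
      MASS::mvrnorm(config@n, mu = numeric(config@p),
                    Sigma = config@sigmaE^2 * SigmaX)
    Y <- outer(gamma, config@thetaY) +
      MASS::mvrnorm(config@n, mu = numeric(config@q),
                    Sigma = config@sigmaE^2 * SigmaY)
    if (config@snpSide == "Y") Y <- discretizeSNP(Y, config@mafRange)
    list(X = X, Y = Y, SigmaX = SigmaX, SigmaY = SigmaY)
  })
  dimnames(out$X) <- list(sprintf("s%d", seq_len(config@n)),
                          sprintf("x%d", seq_len(config@p)))
  dimnames(out$Y) <- list(sprintf("s%d", seq_len(config@n)),
                          sprintf("y%d", seq_len(config@q)))
  truth <- new("SimTruth", supportX = suppX, supportY = suppY,
               groupsX = groupsX, groupsY = groupsY,
               thetaX = config@thetaX, thetaY = config@thetaY,
               sigmaGamma = config@sigmaGamma, sigmaE = config@sigmaE,
               rho = config@rho)
  list(data = PairedMatrices(out$X, out$Y),
       truth = truth,
       maxCorrelation = .latentMaxCorrelation(config, out$SigmaX,
                                              out$SigmaY))
}

## Reference-only estimate of the best attainable correlation: use loading
## directions proportional to theta; cor(Xu, Yv) then follows from the
## generating variances.
.latentMaxCorrelation <- function(config, SigmaX, SigmaY) {
  u <- config@thetaX / sqrt(sum(config@thetaX^2))
  v <- config@thetaY / sqrt(sum(config@thetaY^2))
  sg2 <- config@sigmaGamma^2; se2 <- config@sigmaE^2
  covXY <- sg2 * sum(config@thetaX * u) * sum(config@thetaY * v)
  varX <- sg2 * sum(config@thetaX * u)^2 + se2 * drop(crossprod(u, SigmaX %*% u))
  varY <- sg2 * sum(config@thetaY * v)^2 + se2 * drop(crossprod(v, SigmaY %*% v))
  covXY / sqrt(varX * varY)
}
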