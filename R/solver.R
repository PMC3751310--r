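## Penalized CCA solver: K construction, block soft-threshold updates,
## alternating optimization and rank-one deflation.

#' Cross-product matrix of a standardized paired dataset
#'
#' Computes K = X'Y / (n - 1), the matrix of sample covariances between the
#' standardized columns of X and Y. With identity within-set covariances,
#' penalized CCA reduces to a penalized rank-one decomposition of this
#' matrix; dividing by n - 1 keeps entries on the correlation scale (bounded
#' by ~1 for standardized columns), so that penalty grids such as
#' 0.04, 0.08, ..., 0.4 are meaningful regardless of the sample size.
#'
#' @param data a standardized [PairedMatrices-class] object.
#' @return A [CrossProduct-class] object.
#' @examples
#' pd <- standardizeColumns(
#'   PairedMatrices(matrix(rnorm(50), 10), matrix(rnorm(40), 10)))
#' crossProductMatrix(pd)
#' @export
crossProductMatrix <- function(data) {
  stopifnot(is(data, "PairedMatrices"))
  if (!isStandardized(data))
    stop("crossProductMatrix() requires standardized data; ",
         "call standardizeColumns() first", call. = FALSE)
  n <- nSamples(data)
  if (n < 2L) stop("at least two samples are required", call. = FALSE)
  new("CrossProduct", K = crossprod(xMatrix(data), yMatrix(data)) / (n - 1),
      divisor = n - 1)
}

.asK <- function(K) {
  if (is(K, "CrossProduct")) kMatrix(K) else as.matrix(K)
}

#' Soft-threshold operator
#'
#' Elementwise S(x, lambda) = sign(x) * max(|x| - lambda, 0), the proximal
#' map of the l1 norm.
#'
#' @param x numeric vector.
#' @param lambda nonnegative threshold.
#' @return Numeric vector of the same length as \code{x}.
#' @examples
#' softThreshold(c(3, -2, 0.5), 1)
#' @export
softThreshold <- function(x, lambda) {
  if (length(lambda) != 1L || is.na(lambda) || lambda < 0)
    stop("lambda must be a single nonnegative number", call. = FALSE)
  sign(x) * pmax(abs(x) - lambda, 0)
}

#' Sparse-group block update for one coefficient group
#'
#' Solves the stationarity condition of the sparse group lasso penalized
#' sub-problem for one group, up to the global normalization: given the
#' gradient block g = (Kv)_k, the whole group is zeroed when
#' \eqn{\|S(g, \lambda\tau)\|_2 \le \lambda(1-\tau)\omega_k}; otherwise the
#' block estimate is
#' \eqn{(\|S(g,\lambda\tau)\|_2 - \lambda(1-\tau)\omega_k)\,
#'      S(g,\lambda\tau)/\|S(g,\lambda\tau)\|_2}.
#' Positive multiplicative constants are absorbed by the unit-norm
#' normalization applied once per side update, so only the direction and the
#' relative block magnitudes matter.
#'
#' @param g numeric vector, the gradient block for this group.
#' @param lambda nonnegative sparsity level.
#' @param tau balance in \[0, 1\] between individual (tau = 1) and group
#'   (tau = 0) sparsity.
#' @param omega positive group weight, typically sqrt(group size).
#' @return Numeric vector; exactly zero when the group-zero condition holds.
#' @examples
#' blockUpdate(c(0.3, 0.4), lambda = 1, tau = 0.5, omega = 1)  # zeroed
#' blockUpdate(c(0.8, 0.6), lambda = 0.2, tau = 0.5, omega = 1)
#' @export
blockUpdate <- function(g, lambda, tau, omega) {
  stopifnot(length(lambda) == 1L, lambda >= 0,
            length(tau) == 1L, tau >= 0, tau <= 1,
            length(omega) == 1L, omega > 0)
  s <- softThreshold(g, lambda * tau)
  ns <- sqrt(sum(s^2))
  if (ns <= lambda * (1 - tau) * omega) return(numeric(length(g)))
  ((ns - lambda * (1 - tau) * omega) / ns) * s
}

## Condition signalling a fully-zeroed canonical vector.
.degenerateError <- function(side, lambda) {
  structure(class = c("gsccaDegenerateError", "error", "condition"),
            list(message = sprintf(
              "penalty lambda = %g zeroed every coefficient on the %s side; decrease lambda",
              lambda, side),
              call = sys.call(-1), side = side, lambda = lambda))
}

#' Solve one side sub-problem of penalized CCA
#'
#' Given the other side's unit vector, solves
#' \eqn{\min_u -u'Kv + \Psi(u)} subject to \eqn{\|u\|_2 \le 1} exactly. For
#' the sparse group and group variants this applies [blockUpdate()] to every
#' group of the gradient \code{g = Kv} (the pure group variant uses the
#' reduced zero test \eqn{\|(Kv)_k\|_2 \le \lambda\omega_k}); for the lasso
#' and elastic net variants it soft-thresholds coordinatewise (at lambda and
#' lambda*tau respectively — the elastic net ridge term only rescales a
#' unit-norm vector). The result is renormalized once to unit l2 norm; by the
#' Karush-Kuhn-Tucker conditions this single pass is the exact minimizer.
#'
#' @param K a [CrossProduct-class] or numeric matrix with the side to be
#'   updated along rows (pass \code{t(K)} to update v).
#' @param fixed unit vector of the other side.
#' @param lambda,tau penalty parameters for this side.
#' @param groups [GroupPartition-class] for this side (ignored by the lasso
#'   and elastic net variants).
#' @param variant one of \code{"sparse_group"}, \code{"group"}, \code{"l1"},
#'   \code{"elastic_net"}.
#' @return Unit-norm numeric vector with attribute \code{delta}, half the
#'   Lagrange multiplier of the norm constraint (the norm of the
#'   unnormalized estimate). If the penalty zeroes every coefficient, an
#'   error of class \code{"gsccaDegenerateError"} is raised carrying the
#'   offending lambda (cross-validation catches it and scores the cell as
#'   worst-possible).
#' @export
updateSide <- function(K, fixed, lambda, tau, groups,
                       variant = c("sparse_group", "group", "l1",
                                   "elastic_net")) {
  variant <- match.arg(variant)
  K <- .asK(K)
  g <- drop(K %*% fixed)
  z <- switch(variant,
    l1 = softThreshold(g, lambda),
    elastic_net = softThreshold(g, lambda * tau),
    group = ,
    sparse_group = {
      if (variant == "group") tau <- 0
      stopifnot(is(groups, "GroupPartition"),
                length(groupLabels(groups)) == length(g))
      lab <- groupLabels(groups)
      w <- groupWeights(groups)
      out <- numeric(length(g))
      for (l in names(w)) {
        idx <- which(lab == l)
        out[idx] <- blockUpdate(g[idx], lambda, tau, w[[l]])
      }
      out
    })
  nz <- sqrt(sum(z^2))
  if (nz == 0) stop(.degenerateError("updated", lambda))
  structure(z / nz, delta = nz / 2)
}

.penaltyValue <- function(x, lambda, tau, groups, variant) {
  switch(variant,
    l1 = lambda * sum(abs(x)),
    elastic_net = lambda * (1 - tau) * sum(x^2) + lambda * tau * sum(abs(x)),
    group = ,
    sparse_group = {
      if (variant == "group") tau <- 0
      lab <- groupLabels(groups)
      w <- groupWeights(groups)
      gnorm <- vapply(names(w),
                      function(l) sqrt(sum(x[lab == l]^2)), numeric(1))
      lambda * (1 - tau) * sum(w * gnorm) + lambda * tau * sum(abs(x))
    })
}

## Penalized objective -u'Kv + Psi(u) + Phi(v) traced by the solver.
.objective <- function(K, u, v, penalty, groupsX, groupsY) {
  -drop(crossprod(u, K %*% v)) +
    .penaltyValue(u, penalty@lambda1, penalty@tau1, groupsX, penalty@variant) +
    .penaltyValue(v, penalty@lambda2, penalty@tau2, groupsY, penalty@variant)
}

.leadingPair <- function(K) {
  s <- svd(K, nu = 1L, nv = 1L)
  list(u = s$u[, 1L], v = s$v[, 1L])
}

#' Fit one canonical pair by alternating block coordinate descent
#'
#' Alternates exact side updates ([updateSide()]) for u and v until the
#' larger of the two vector changes falls below \code{tol} or \code{maxIter}
#' is reached. Each sub-problem is convex and solved exactly, so the
#' penalized objective \eqn{-u'Kv + \Psi(u) + \Phi(v)} is non-increasing
#' across half-updates; the trace is recorded. On convergence
#' \eqn{d = tr(Kvu') = u'Kv} and signs are fixed so the largest-magnitude
#' entry of u is positive (v flipped jointly, leaving d unchanged).
#'
#' @param K a [CrossProduct-class] or p x q numeric matrix.
#' @param penalty a [PenaltySpec-class].
#' @param groupsX,groupsY [GroupPartition-class] per side; default singleton
#'   groups.
#' @param initU,initV optional unit-norm starting vectors; default the
#'   leading singular pair of K (the unpenalized CCA solution under identity
#'   covariance).
#' @param tol convergence tolerance on the vector change (default 1e-6).
#' @param maxIter iteration cap (default 500); hitting it sets
#'   \code{converged = FALSE}, it never raises.
#' @param data optional standardized [PairedMatrices-class]; when supplied
#'   the achieved sample correlation cor(Xu, Yv) is recorded.
#' @return A [CanonicalPair-class] object.
#' @examples
#' K <- diag(c(2, 1))
#' fitCanonicalPair(K, PenaltySpec("l1", 0, 0))
#' @export
fitCanonicalPair <- function(K, penalty, groupsX = NULL, groupsY = NULL,
                             initU = NULL, initV = NULL,
                             tol = 1e-6, maxIter = 500L, data = NULL) {
  stopifnot(is(penalty, "PenaltySpec"))
  K <- .asK(K)
  p <- nrow(K); q <- ncol(K)
  if (is.null(groupsX)) groupsX <- singletonGroups(p)
  if (is.null(groupsY)) groupsY <- singletonGroups(q)
  stopifnot(length(groupLabels(groupsX)) == p,
            length(groupLabels(groupsY)) == q)
  if (is.null(initU) || is.null(initV)) {
    sv <- .leadingPair(K)
    if (is.null(initU)) initU <- sv$u
    if (is.null(initV)) initV <- sv$v
  }
  u <- initU / sqrt(sum(initU^2))
  v <- initV / sqrt(sum(initV^2))
  trace <- .objective(K, u, v, penalty, groupsX, groupsY)
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    uNew <- tryCatch(
      updateSide(K, v, penalty@lambda1, penalty@tau1, groupsX,
                 penalty@variant),
      gsccaDegenerateError = function(e) { e$side <- "X"; stop(e) })
    trace <- c(trace, .objective(K, uNew, v, penalty, groupsX, groupsY))
    vNew <- tryCatch(
      updateSide(t(K), uNew, penalty@lambda2, penalty@tau2, groupsY,
                 penalty@variant),
      gsccaDegenerateError = function(e) { e$side <- "Y"; stop(e) })
    trace <- c(trace, .objective(K, uNew, vNew, penalty, groupsX, groupsY))
    delta <- max(sqrt(sum((uNew - u)^2)), sqrt(sum((vNew - v)^2)))
    u <- as.numeric(uNew); v <- as.numeric(vNew)
    attributes(u) <- attributes(v) <- NULL
    if (delta < tol) { converged <- TRUE; break }
  }
  s <- sign(u[which.max(abs(u))])
  if (s < 0) { u <- -u; v <- -v }
  d <- drop(crossprod(u, K %*% v))
  sampleCor <- NA_real_
  if (!is.null(data)) {
    stopifnot(is(data, "PairedMatrices"))
    sampleCor <- cor(drop(xMatrix(data) %*% u), drop(yMatrix(data) %*% v))
  }
  new("CanonicalPair", u = u, v = v, d = d, sampleCorrelation = sampleCor,
      nIterations = iter, converged = converged, objectiveTrace = trace)
}

#' Rank-one deflation of the cross-product matrix
#'
#' Removes the contribution of an extracted pair: K - d u v'. Repeated
#' deflation with unpenalized pairs reproduces the truncated-SVD residual,
#' so successive d values are non-increasing in the unpenalized case.
#'
#' @param K a [CrossProduct-class] or numeric matrix.
#' @param pair a [CanonicalPair-class].
#' @return Object of the same kind as \code{K} with the rank-one component
#'   removed.
#' @export
deflate <- function(K, pair) {
  stopifnot(is(pair, "CanonicalPair"))
  if (is(K, "CrossProduct")) {
    new("CrossProduct", K = K@K - pair@d * tcrossprod(pair@u, pair@v),
        divisor = K@divisor)
  } else {
    K - pair@d * tcrossprod(pair@u, pair@v)
  }
}

#' Penalized canonical correlation analysis
#'
#' The main fitting entry point: standardizes the data (unless already
#' standardized), builds K = X'Y/(n-1), and extracts \code{nPairs} canonical
#' pairs by alternating block coordinate descent with rank-one deflation
#' between pairs. Each pair records its achieved sample correlation
#' cor(Xu, Yv).
#'
#' @param data a [PairedMatrices-class] object.
#' @param penalty a [PenaltySpec-class].
#' @param groupsX,groupsY optional [GroupPartition-class] per side; default
#'   singleton groups (group penalty then behaves like an extra lasso).
#' @param nPairs number of canonical pairs to extract (at most min(p, q)).
#' @param tol,maxIter passed to [fitCanonicalPair()].
#' @return A [SparseCCAFit-class] object.
#' @examples
#' set.seed(1)
#' pd <- PairedMatrices(matrix(rnorm(200), 20), matrix(rnorm(160), 20))
#' fit <- sparseCCA(pd, PenaltySpec("l1", lambda1 = 0.1, lambda2 = 0.1))
#' correlations(fit)
#' @export
sparseCCA <- function(data, penalty, groupsX = NULL, groupsY = NULL,
                      nPairs = 1L, tol = 1e-6, maxIter = 500L) {
  stopifnot(is(data, "PairedMatrices"), is(penalty, "PenaltySpec"))
  if (!isStandardized(data)) data <- standardizeColumns(data)
  p <- ncol(xMatrix(data)); q <- ncol(yMatrix(data))
  if (nPairs < 1L || nPairs > min(p, q))
    stop(sprintf("nPairs must lie in [1, %d]", min(p, q)), call. = FALSE)
  if (is.null(groupsX)) groupsX <- singletonGroups(p)
  if (is.null(groupsY)) groupsY <- singletonGroups(q)
  K <- crossProductMatrix(data)
  pairs <- vector("list", nPairs)
  for (j in seq_len(nPairs)) {
    pairs[[j]] <- tryCatch(
      fitCanonicalPair(K, penalty, groupsX, groupsY,
                       tol = tol, maxIter = maxIter, data = data),
      gsccaDegenerateError = function(e) {
        e$message <- sprintf("canonical pair %d: %s", j, e$message)
        stop(e)
      })
    K <- deflate(K, pairs[[j]])
  }
  fnX <- colnames(xMatrix(data)); fnY <- colnames(yMatrix(data))
  new("SparseCCAFit", pairs = pairs, penalty = penalty,
      groupsX = groupsX, groupsY = groupsY,
      featureNamesX = if (is.null(fnX)) sprintf("x%d", seq_len(p)) else fnX,
      featureNamesY = if (is.null(fnY)) sprintf("y%d", seq_len(q)) else fnY)
}
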