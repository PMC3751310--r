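## Independent oracles and fixture builders used across the test files.
## Everything here is deliberately written without reference to the package
## internals: brute-force loops, dual-distance optimization via
## box-constrained quasi-Newton, and plain-R penalty evaluation.

## Random standardized paired data.
randomPaired <- function(n, p, q, seed) {
  set.seed(seed)
  standardizeColumns(PairedMatrices(matrix(rnorm(n * p), n),
                                    matrix(rnorm(n * q), n)))
}

randomK <- function(p, q, seed) {
  set.seed(seed)
  matrix(rnorm(p * q), p, q)
}

## Element-wise double-loop cross-product oracle.
bruteCrossProduct <- function(X, Y) {
  p <- ncol(X); q <- ncol(Y); n <- nrow(X)
  K <- matrix(0, p, q)
  for (i in seq_len(p)) for (j in seq_len(q))
    K[i, j] <- sum(X[, i] * Y[, j]) / (n - 1)
  K
}

## Sparse-group penalty value, written independently of the package.
oraclePenalty <- function(x, lambda, tau, lab) {
  gn <- vapply(unique(lab), function(l) sqrt(sum(x[lab == l]^2)), numeric(1))
  w <- vapply(unique(lab), function(l) sqrt(sum(lab == l)), numeric(1))
  lambda * (1 - tau) * sum(w * gn) + lambda * tau * sum(abs(x))
}

## Joint penalized objective -u'Kv + Psi(u) + Phi(v), sparse-group variant.
oracleObjective <- function(K, u, v, lambda1, lambda2, tau1, tau2,
                            labX, labY) {
  -drop(crossprod(u, K %*% v)) +
    oraclePenalty(u, lambda1, tau1, labX) +
    oraclePenalty(v, lambda2, tau2, labY)
}

## Groupwise soft threshold = residual of projecting onto the product of
## per-group l2 balls of radii cg[l].
.oracleGST <- function(r, cg, lab) {
  out <- r
  for (l in unique(lab)) {
    idx <- which(lab == l)
    nr <- sqrt(sum(r[idx]^2))
    out[idx] <- if (nr <= cg[[l]]) 0 else (1 - cg[[l]] / nr) * r[idx]
  }
  out
}

## Exact solution of the side sub-problem min_{||u||<=1} -g'u + pen(u) by
## duality: the optimal value is -dist(g, C) with C the Minkowski sum of the
## l-inf box of radius lambda*tau and the per-group l2 balls of radii
## lambda*(1-tau)*w_l; the distance is found by projected quasi-Newton
## (L-BFGS-B) over the box variable, restarted from random box points.
oracleSide <- function(g, lambda, tau, lab, nRestarts = 3L) {
  lt <- lambda * tau
  ug <- unique(lab)
  cg <- setNames(lambda * (1 - tau) *
                   vapply(ug, function(l) sqrt(sum(lab == l)), numeric(1)),
                 ug)
  fn <- function(w1) sum(.oracleGST(g - w1, cg, lab)^2)
  gr <- function(w1) -2 * .oracleGST(g - w1, cg, lab)
  starts <- c(list(rep(0, length(g))),
              lapply(seq_len(nRestarts - 1L),
                     function(i) runif(length(g), -lt, lt)))
  best <- NULL
  for (s in starts) {
    r <- optim(s, fn, gr, method = "L-BFGS-B", lower = -lt, upper = lt,
               control = list(factr = 10, maxit = 2000))
    if (is.null(best) || r$value < best$value) best <- r
  }
  d <- sqrt(best$value)
  if (d < 1e-10) return(list(value = 0, u = numeric(length(g))))
  list(value = -d, u = .oracleGST(g - best$par, cg, lab) / d)
}

## Full alternating oracle fit from random restarts; each side sub-problem
## is solved by oracleSide. Returns the best joint objective found.
oracleFit <- function(K, lambda1, lambda2, tau1, tau2, labX, labY,
                      nRestarts = 100L, maxIter = 200L, seed = 1L) {
  set.seed(seed)
  p <- nrow(K); q <- ncol(K)
  bestObj <- Inf
  for (r in seq_len(nRestarts)) {
    v <- rnorm(q); v <- v / sqrt(sum(v^2))
    u <- rnorm(p); u <- u / sqrt(sum(u^2))
    obj <- Inf
    for (it in seq_len(maxIter)) {
      su <- oracleSide(drop(K %*% v), lambda1, tau1, labX)
      if (all(su$u == 0)) { obj <- Inf; break }
      u <- su$u
      sv <- oracleSide(drop(crossprod(K, u)), lambda2, tau2, labY)
      if (all(sv$u == 0)) { obj <- Inf; break }
      v <- sv$u
      newObj <- oracleObjective(K, u, v, lambda1, lambda2, tau1, tau2,
                                labX, labY)
      if (is.finite(obj) && abs(obj - newObj) < 1e-12) { obj <- newObj; break }
      obj <- newObj
    }
    if (obj < bestObj) bestObj <- obj
  }
  bestObj
}

## Sub-gradient certificate check for a fitted pair at a sparse-group
## penalty: every zero block must satisfy the group-zero condition and every
## nonzero block the stationarity equation with multiplier 2*Delta = ||z||,
## the norm of the unnormalized update. Returns the largest violation.
certificateViolation <- function(K, u, v, lambda, tau, lab) {
  g <- drop(K %*% v)
  w <- vapply(unique(lab), function(l) sqrt(sum(lab == l)), numeric(1))
  names(w) <- unique(lab)
  if (all(u == 0)) return(NA_real_)
  ## contracting the stationarity equation with u (||u|| = 1) gives
  ## 2*Delta = u'g - pen(u)
  twoD <- sum(u * g) - oraclePenalty(u, lambda, tau, lab)
  viol <- 0
  for (l in unique(lab)) {
    idx <- which(lab == l)
    ul <- u[idx]; gl <- g[idx]
    if (all(ul == 0)) {
      s <- sign(gl) * pmax(abs(gl) - lambda * tau, 0)
      viol <- max(viol, sqrt(sum(s^2)) - lambda * (1 - tau) * w[[l]])
    } else {
      nl <- sqrt(sum(ul^2))
      resid <- gl - twoD * ul - lambda * (1 - tau) * w[[l]] * ul / nl
      nz <- ul != 0
      viol <- max(viol,
                  abs(resid[nz] - lambda * tau * sign(ul[nz])),
                  abs(resid[!nz]) - lambda * tau)
    }
  }
  viol
}
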