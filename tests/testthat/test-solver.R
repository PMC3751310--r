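test_that("cross-product matrix matches brute-force covariance and rejects bad input", {
  pd <- randomPaired(10, 3, 4, seed = 11)
  K <- crossProductMatrix(pd)
  expect_s4_class(K, "CrossProduct")
  expect_equal(dim(kMatrix(K)), c(3L, 4L))
  expect_lt(max(abs(kMatrix(K) - bruteCrossProduct(xMatrix(pd),
                                                   yMatrix(pd)))), 1e-12)
  ## a standardized column against itself has covariance exactly 1
  x <- matrix(rnorm(50), 50)
  same <- standardizeColumns(PairedMatrices(x, x))
  expect_equal(drop(kMatrix(crossProductMatrix(same))), 1, tolerance = 1e-12)
  ## orthogonal columns give a zero matrix
  ortho <- standardizeColumns(PairedMatrices(
    cbind(rep(c(1, -1), 4)), cbind(rep(c(1, 1, -1, -1), 2))))
  expect_equal(drop(kMatrix(crossProductMatrix(ortho))), 0)
  ## contract violations
  expect_error(crossProductMatrix(PairedMatrices(x, x)), "standardized")
  expect_error(PairedMatrices(matrix(0, 3, 2), matrix(0, 4, 2)), "sample")
  expect_error(standardizeColumns(PairedMatrices(cbind(rnorm(9), 1),
                                                 matrix(rnorm(9), 9))),
               "constant")
})

test_that("soft threshold has the closed form and validates lambda", {
  expect_equal(softThreshold(c(3, -2, 0.5), 1), c(2, -1, 0))
  x <- rnorm(20)
  expect_equal(softThreshold(x, 0), x)
  expect_equal(softThreshold(numeric(5), 2), numeric(5))
  expect_error(softThreshold(x, -0.1), "nonnegative")
})

test_that("block update zeroes groups exactly when the group-zero condition holds", {
  expect_equal(blockUpdate(numeric(3), 1, 0.5, 1), numeric(3))
  ## S(g, 0.5) = 0 here, so the condition holds with a zero threshold vector
  expect_equal(blockUpdate(c(0.3, 0.4), 1, 0.5, 1), c(0, 0))
  ## lambda = 0: direction preserved
  g <- c(0.8, -0.6, 0.1)
  out <- blockUpdate(g, 0, 0.7, 2)
  expect_equal(out / sqrt(sum(out^2)), g / sqrt(sum(g^2)))
  ## boundary: exact equality ||S(g)|| == lambda*(1-tau)*omega is zero
  expect_equal(blockUpdate(c(0.6, 0.8), 1, 0, 1), c(0, 0))
  expect_error(blockUpdate(c(1, 0), lambda = 2, tau = 0.5, omega = 0))
})

test_that("side update solves the sub-problem exactly (dual oracle, all variants)", {
  set.seed(21)
  for (i in 1:10) {
    p <- sample(5:9, 1)
    lab <- sort(sample(c("a", "b"), p, replace = TRUE))
    gp <- GroupPartition(lab)
    g <- rnorm(p)
    lambda <- runif(1, 0.05, 1.2)
    tau <- runif(1)
    for (variant in c("sparse_group", "group", "l1", "elastic_net")) {
      u <- tryCatch(
        as.numeric(updateSide(diag(p), g, lambda, tau, gp, variant)),
        gsccaDegenerateError = function(e) numeric(p))
      ## effective sparse-group parameters of each variant
      eff <- switch(variant,
        sparse_group = c(lambda, tau),
        group = c(lambda, 0),
        l1 = c(lambda, 1),
        elastic_net = c(lambda * tau, 1))
      fImpl <- if (all(u == 0)) 0 else
        -sum(g * u) + oraclePenalty(u, eff[1], eff[2], lab)
      o <- oracleSide(g, eff[1], eff[2], lab)
      expect_lt(abs(fImpl - o$value), 1e-8)
      if (any(u != 0)) expect_equal(sqrt(sum(u^2)), 1, tolerance = 1e-10)
    }
  }
})

test_that("unpenalized fit reproduces the leading singular triple and deflation the SVD residual", {
  ## diagonal case with a known answer
  pr <- fitCanonicalPair(diag(c(2, 1)), PenaltySpec("l1", 0, 0))
  expect_equal(abs(pr@u), c(1, 0), tolerance = 1e-10)
  expect_equal(abs(pr@v), c(1, 0), tolerance = 1e-10)
  expect_equal(pr@d, 2, tolerance = 1e-10)
  K <- randomK(7, 5, seed = 31)
  s <- svd(K)
  pen0 <- PenaltySpec("sparse_group", 0, 0)
  pr <- fitCanonicalPair(K, pen0, singletonGroups(7), singletonGroups(5))
  expect_lt(max(abs(abs(pr@u) - abs(s$u[, 1]))), 1e-8)
  expect_lt(max(abs(abs(pr@v) - abs(s$v[, 1]))), 1e-8)
  expect_equal(pr@d, s$d[1], tolerance = 1e-8)
  ## sign convention: largest-magnitude entry of u positive, d nonnegative
  expect_gt(pr@u[which.max(abs(pr@u))], 0)
  expect_gte(pr@d, 0)
  ## deflating a rank-one matrix by its own triple leaves zero
  K1 <- 3 * tcrossprod(s$u[, 1], s$v[, 1])
  p1 <- fitCanonicalPair(K1, pen0)
  expect_lt(norm(deflate(K1, p1), "F"), 1e-10)
  ## three unpenalized deflations of a rank-3 matrix leave ~nothing, and the
  ## extracted d values match the sorted singular values
  K3 <- s$u[, 1:3] %*% diag(c(5, 3, 2)) %*% t(s$v[, 1:3])
  ds <- numeric(3)
  Kr <- K3
  for (j in 1:3) {
    pj <- fitCanonicalPair(Kr, pen0)
    ds[j] <- pj@d
    Kr <- deflate(Kr, pj)
  }
  expect_lt(norm(Kr, "F"), 1e-8)
  expect_equal(ds, c(5, 3, 2), tolerance = 1e-8)
  expect_true(all(diff(ds) <= 1e-8))
})

test_that("objective trace is non-increasing for every variant on random instances", {
  set.seed(41)
  for (i in 1:5) {
    K <- matrix(rnorm(8 * 6), 8, 6)
    gx <- GroupPartition(rep(c("a", "b"), c(5, 3)))
    gy <- GroupPartition(rep(c("c", "d"), c(2, 4)))
    for (variant in c("l1", "elastic_net", "group", "sparse_group")) {
      pen <- PenaltySpec(variant, lambda1 = 0.3, lambda2 = 0.25,
                         tau1 = 0.5, tau2 = 0.4)
      pr <- fitCanonicalPair(K, pen, gx, gy)
      expect_lte(max(diff(pr@objectiveTrace)), 1e-10)
      expect_true(pr@converged)
    }
  }
})

test_that("sparse_group reduces bitwise to group (tau=0) and l1 (tau=1); elastic net matches l1", {
  set.seed(51)
  for (i in 1:10) {
    K <- matrix(rnorm(9 * 7), 9, 7)
    gx <- GroupPartition(sample(c("a", "b", "c"), 9, replace = TRUE))
    gy <- GroupPartition(sample(c("d", "e"), 7, replace = TRUE))
    lam <- runif(1, 0.1, 0.6)
    fit1 <- fitCanonicalPair(K, PenaltySpec("sparse_group", lam, lam,
                                            tau1 = 0, tau2 = 0), gx, gy)
    fit2 <- fitCanonicalPair(K, PenaltySpec("group", lam, lam), gx, gy)
    expect_identical(fit1@u, fit2@u)
    expect_identical(fit1@v, fit2@v)
    fit3 <- fitCanonicalPair(K, PenaltySpec("sparse_group", lam, lam,
                                            tau1 = 1, tau2 = 1), gx, gy)
    fit4 <- fitCanonicalPair(K, PenaltySpec("l1", lam, lam), gx, gy)
    expect_identical(fit3@u, fit4@u)
    expect_identical(fit3@v, fit4@v)
    ## elastic net at lambda/tau equals l1 at lambda under the shared
    ## iteration schedule
    tau <- runif(1, 0.3, 0.9)
    fit5 <- fitCanonicalPair(K, PenaltySpec("elastic_net", lam / tau,
                                            lam / tau, tau1 = tau,
                                            tau2 = tau), gx, gy)
    expect_lt(max(abs(fit5@u - fit4@u)), 1e-10)
    expect_lt(max(abs(fit5@v - fit4@v)), 1e-10)
  }
})

test_that("a penalty zeroing a whole side raises a degenerate error in direct fits", {
  K <- matrix(0.01 * rnorm(12), 4, 3)
  expect_error(fitCanonicalPair(K, PenaltySpec("l1", 10, 10)),
               class = "gsccaDegenerateError")
  pd <- randomPaired(20, 4, 3, seed = 61)
  err <- tryCatch(sparseCCA(pd, PenaltySpec("l1", 50, 50)),
                  gsccaDegenerateError = function(e) e)
  expect_s3_class(err, "gsccaDegenerateError")
  expect_equal(err$lambda, 50)
})

test_that("sparseCCA recovers a planted latent correlation and validates nPairs", {
  set.seed(71)
  n <- 200
  gamma <- rnorm(n)
  X <- outer(gamma, c(1, -1, 0.5)) + matrix(rnorm(n * 3, sd = 0.3), n)
  Y <- outer(gamma, c(0.8, 1.2)) + matrix(rnorm(n * 2, sd = 0.3), n)
  pd <- PairedMatrices(X, Y)
  fit <- sparseCCA(pd, PenaltySpec("l1", 0, 0))
  ## population canonical correlation of the latent model, computed from the
  ## generating variances
  rhoX <- sum(c(1, -1, 0.5)^2) / (sum(c(1, -1, 0.5)^2) + 0.3^2)
  rhoY <- sum(c(0.8, 1.2)^2) / (sum(c(0.8, 1.2)^2) + 0.3^2)
  expect_equal(correlations(fit), sqrt(rhoX * rhoY), tolerance = 0.05)
  expect_error(sparseCCA(pd, PenaltySpec("l1", 0, 0), nPairs = 3),
               "nPairs")
})

test_that("multiple pairs come out in extraction order with unit norms", {
  pd <- randomPaired(30, 6, 5, seed = 81)
  fit <- sparseCCA(pd, PenaltySpec("sparse_group", 0.05, 0.05, 0.5, 0.5),
                   nPairs = 3)
  expect_equal(nCanonicalPairs(fit), 3L)
  L <- loadings(fit, "x")
  expect_equal(dim(L), c(6L, 3L))
  for (j in 1:3) {
    pj <- canonicalPair(fit, j)
    expect_equal(sqrt(sum(pj@u^2)), 1, tolerance = 1e-8)
    expect_equal(sqrt(sum(pj@v^2)), 1, tolerance = 1e-8)
  }
})
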