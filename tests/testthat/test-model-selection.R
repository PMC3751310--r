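## Shared strong-signal fixture: a single latent factor drives both sides.
latentPaired <- function(n, p, q, sd = 0.4, seed = 1) {
  set.seed(seed)
  gamma <- rnorm(n)
  PairedMatrices(
    outer(gamma, rep(c(1, 0), c(3, p - 3))) + matrix(rnorm(n * p, sd = sd), n),
    outer(gamma, rep(c(1, 0), c(3, q - 3))) + matrix(rnorm(n * q, sd = sd), n))
}

test_that("deltaCorr is the mean absolute fold difference with strict contracts", {
  expect_equal(deltaCorr(c(0.9, 0.8), c(0.7, 0.8)), 0.1)
  expect_equal(deltaCorr(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7)), 0)
  ## symmetric in the two arguments and invariant to fold order
  a <- runif(6); b <- runif(6)
  expect_equal(deltaCorr(a, b), deltaCorr(b, a))
  expect_equal(deltaCorr(a, b), deltaCorr(rev(a), rev(b)))
  expect_error(deltaCorr(c(1, 2), 1), "same length")
  expect_error(deltaCorr(numeric(), numeric()), "at least one")
})

test_that("penaltyGrid expands the requested cells and validates ranges", {
  g <- penaltyGrid()
  expect_equal(nrow(g), 100L)
  expect_named(g, c("lambda1", "lambda2", "tau1", "tau2"))
  g2 <- penaltyGrid(lambda1 = c(0.1, 0.2), lambda2 = 0.3,
                    tau1 = c(0, 1), tau2 = 0.5)
  expect_equal(nrow(g2), 4L)
  expect_setequal(g2$lambda1, c(0.1, 0.2))
  expect_true(all(g2$lambda2 == 0.3))
  expect_error(penaltyGrid(lambda1 = -1), "lambda1")
  expect_error(penaltyGrid(tau1 = 1.5), "tau1")
})

test_that("cross-validation picks a generalizing cell on strong-signal data and is deterministic", {
  pd <- latentPaired(60, 8, 6, seed = 101)
  grid <- penaltyGrid(lambda1 = c(0.2, 0.8, 1.4), tau1 = 0.5)
  cv1 <- cvSparseCCA(pd, grid, "sparse_group", k = 4, seed = 7)
  cv2 <- cvSparseCCA(pd, grid, "sparse_group", k = 4, seed = 7)
  expect_identical(cv1@meanDeltaCorr, cv2@meanDeltaCorr)
  expect_identical(cv1@best, cv2@best)
  expect_true(all(is.finite(cv1@meanDeltaCorr) | cv1@meanDeltaCorr == Inf))
  ## chosen cell achieves the minimal finite score
  fin <- is.finite(cv1@meanDeltaCorr)
  expect_true(any(fin))
  expect_equal(cv1@meanDeltaCorr[cv1@best], min(cv1@meanDeltaCorr[fin]))
  ## the reported matrices have one row per cell and one column per fold
  expect_equal(dim(cv1@trainCorr), c(nrow(grid), 4L))
  ## refitting at the chosen penalty recovers the latent correlation
  pen <- bestPenalty(cv1)
  fit <- sparseCCA(pd, pen)
  expect_gt(correlations(fit), 0.8)
  expect_error(cvSparseCCA(pd, grid, k = 1), "at least 2")
  expect_error(cvSparseCCA(latentPaired(6, 4, 4), grid, k = 4),
               "2 samples per fold")
})

test_that("degenerate grid cells score Inf and are never chosen; all-degenerate errors", {
  pd <- latentPaired(50, 6, 5, seed = 111)
  grid <- penaltyGrid(lambda1 = c(0.5, 50), tau1 = 1)
  cv <- cvSparseCCA(pd, grid, "l1", k = 5, seed = 3)
  huge <- grid$lambda1 == 50 & grid$lambda2 == 50
  expect_true(all(cv@meanDeltaCorr[huge] == Inf))
  expect_false(cv@best %in% which(huge))
  expect_error(
    cvSparseCCA(pd, penaltyGrid(lambda1 = 50, tau1 = 1), "l1", k = 5),
    "degenerate")
})

test_that("exact score ties break toward the sparsest cell", {
  pd <- latentPaired(40, 5, 5, seed = 121)
  ## the group variant ignores tau, so cells differing only in tau produce
  ## identical fits and exactly tied scores
  grid <- penaltyGrid(lambda1 = 0.4, tau1 = c(0.2, 0.8))
  cv <- cvSparseCCA(pd, grid, "group", k = 4, seed = 5)
  tied <- which(cv@meanDeltaCorr == min(cv@meanDeltaCorr))
  expect_gt(length(tied), 1L)
  expect_equal(cv@grid$tau1[cv@best] + cv@grid$tau2[cv@best],
               max(cv@grid$tau1[tied] + cv@grid$tau2[tied]))
})

test_that("cross-validation leaves the caller's RNG stream untouched", {
  pd <- latentPaired(40, 5, 5, seed = 131)
  grid <- penaltyGrid(lambda1 = 0.3, tau1 = 0.5)
  set.seed(99)
  expected <- rnorm(3)
  set.seed(99)
  invisible(cvSparseCCA(pd, grid, "sparse_group", k = 4, seed = 17))
  expect_identical(rnorm(3), expected)
})

test_that("permutation p-value matches the add-one formula and detects real signal", {
  pd <- standardizeColumns(latentPaired(100, 6, 5, seed = 141))
  fit <- sparseCCA(pd, PenaltySpec("l1", 0.3, 0.3))
  pr <- canonicalPair(fit)
  res <- permutationPValue(pd, pr@u, pr@v, nPerm = 99, seed = 11)
  expect_length(res$permCorrelations, 99L)
  expect_equal(res$pValue,
               (sum(res$permCorrelations >= res$observed) + 1) / 100)
  expect_equal(res$rawProportion,
               sum(res$permCorrelations >= res$observed) / 99)
  ## a strong latent factor beats every permutation
  expect_equal(res$pValue, 1 / 100)
  expect_gt(res$observed, 0.8)
  ## deterministic given the seed; permuting X instead is supported
  res2 <- permutationPValue(pd, pr@u, pr@v, nPerm = 99, seed = 11)
  expect_identical(res$permCorrelations, res2$permCorrelations)
  resX <- permutationPValue(pd, pr@u, pr@v, nPerm = 20, seed = 11,
                            permute = "X")
  expect_length(resX$permCorrelations, 20L)
  expect_error(permutationPValue(pd, pr@u, pr@v, nPerm = 0), "nPerm")
  expect_error(permutationPValue(pd, numeric(6), pr@v, nPerm = 5),
               "zero-variance")
})

test_that("permutation p-values are roughly uniform under independence", {
  ## one modest calibration probe: independent X and Y with fixed loadings
  set.seed(151)
  pvals <- vapply(1:20, function(i) {
    pd <- standardizeColumns(PairedMatrices(matrix(rnorm(40 * 4), 40),
                                            matrix(rnorm(40 * 4), 40)))
    u <- rep(0.5, 4); v <- rep(0.5, 4)
    permutationPValue(pd, u, v, nPerm = 99, seed = i)$pValue
  }, numeric(1))
  ## under the null roughly a twentieth should fall below 0.05; allow wide
  ## binomial slack for 20 draws
  expect_lte(sum(pvals <= 0.05), 5L)
  expect_gt(mean(pvals), 0.2)
})

test_that("split evaluation returns per-repeat records and stable true features", {
  pd <- latentPaired(70, 8, 6, seed = 161)
  grid <- penaltyGrid(lambda1 = c(0.6, 1.2), tau1 = 0.5)
  res <- splitEvaluate(pd, nTrain = 50, nRepeats = 4, grid,
                       variant = "sparse_group", k = 4, seed = 21)
  expect_length(res$correlations, 4L)
  expect_length(res$selectedX, 4L)
  expect_length(res$selectedY, 4L)
  expect_equal(nrow(res$chosen), sum(!is.na(res$correlations)))
  ## the three true features on each side drive a strong latent factor and
  ## should be stable across repeats
  expect_true(all(1:3 %in% res$stableX))
  expect_true(all(1:3 %in% res$stableY))
  expect_gt(mean(res$correlations, na.rm = TRUE), 0.7)
  expect_error(splitEvaluate(pd, nTrain = 70, nRepeats = 2, grid),
               "smaller")
})

test_that("ROC sweep reports rates in [0, 1] sorted by total false positive rate", {
  cfg <- simConfig(n = 60, p = 30, q = 24, gX = 6, gY = 6,
                   thetaX = c(rep(1.2, 5), rep(0, 25)),
                   thetaY = c(rep(1.2, 4), rep(0, 20)),
                   sigmaGamma = 1, sigmaE = 0.4)
  grid <- penaltyGrid(lambda1 = c(0.4, 0.9), tau1 = 0.5)
  roc <- rocCurve(cfg, "sparse_group", grid, vary = "lambda1",
                  varyValues = c(0.2, 0.9, 2.5), nReplicates = 2, k = 4,
                  seed = 31)
  expect_named(roc, c("value", "tfpr", "ttpr"))
  expect_equal(nrow(roc), 3L)
  expect_true(all(roc$tfpr >= 0 & roc$tfpr <= 1))
  expect_true(all(roc$ttpr >= 0 & roc$ttpr <= 1))
  expect_true(!is.unsorted(roc$tfpr))
})
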