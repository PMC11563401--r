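# Univariate and multivariate GBLUP: oracles, invariants, reductions.

test_that("noise-free phenotypes are interpolated by UV-GBLUP", {
  # a reduced-rank G (fewer markers than individuals) makes the zero-noise
  # limit identifiable: the phenotype lies exactly in the genetic subspace
  panel <- makePanel(60, 30, seed = 31)
  bv <- simulateBreedingValues(panel$gm, matrix(1, 1, 1), seed = 32)
  y <- setNames(bv[, 1], rownames(bv))
  fit <- fitUvGblup(y, panel$K)
  expect_gt(cor(gebv(fit)[names(y)], y), 0.999)
})

test_that("UV-GBLUP equals marker-effect ridge with matched penalty", {
  panel <- makePanel(50, 200, seed = 33)
  ph <- makePheno(panel, h2 = 0.5, seed = 34)
  y <- setNames(ph$Y[, 1], rownames(ph$Y))
  G <- grm(panel$K)
  d <- dosages(panel$gm)
  p <- colMeans((d + 1) / 2)
  cNorm <- sum(2 * p * (1 - p))
  W <- sweep(d, 2, colMeans(d))
  lambda <- 1.7 # fixed variance ratio sigmaE2 / sigmaG2
  fit <- fitUvGblup(y, G, fixedRatio = lambda)
  oracle <- snpBlupOracle(y, W, lambda * cNorm)
  expect_lt(max(abs(gebv(fit)[names(y)] - oracle)), 1e-6)
})

test_that("GEBVs shrink monotonically as the fixed variance ratio grows", {
  panel <- makePanel(40, 100, seed = 35)
  ph <- makePheno(panel, h2 = 0.5, seed = 36)
  y <- setNames(ph$Y[, 1], rownames(ph$Y))
  norms <- vapply(c(0.1, 1, 10, 100), function(lam)
    sqrt(mean(gebv(fitUvGblup(y, panel$K, fixedRatio = lam))^2)), numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("GEBVs are invariant to a phenotype shift (intercept absorption)", {
  panel <- makePanel(40, 100, seed = 37)
  ph <- makePheno(panel, h2 = 0.5, seed = 38)
  y <- setNames(ph$Y[, 1], rownames(ph$Y))
  f1 <- fitUvGblup(y, panel$K, fixedRatio = 1)
  f2 <- fitUvGblup(y + 100, panel$K, fixedRatio = 1)
  expect_lt(max(abs(gebv(f1) - gebv(f2))), 1e-8)
})

test_that("masked individuals receive kinship-regression GEBVs", {
  panel <- makePanel(60, 150, seed = 39)
  ph <- makePheno(panel, h2 = 0.6, seed = 40)
  y <- setNames(ph$Y[, 1], rownames(ph$Y))
  yMask <- y; yMask[1:12] <- NA
  fit <- fitUvGblup(yMask, panel$K)
  expect_true(all(is.finite(gebv(fit))))
  expect_gt(cor(gebv(fit)[1:12], ph$bv[1:12, 1]), 0.2)
})

test_that("multivariate EM-REML has a non-decreasing likelihood trace and matches a dense solver", {
  panel <- makePanel(25, 80, seed = 41)
  ph <- makePheno(panel, h2 = c(0.4, 0.7), seed = 42,
                  HTrue = matrix(c(1, 0.6, 0.6, 1), 2))
  mp <- maskedPhenotypes(ph$Y)
  fit <- suppressWarnings(fitMvGblup(mp, panel$K, maxIter = 5000))
  expect_true(all(diff(fit@logLik) > -1e-6))
  ## dense oracle at the fitted (H, R): g = Gamma Z' V^{-1} (y - X beta_gls)
  G <- grm(panel$K)
  H <- fit@HHat; R <- fit@RHat
  n <- nrow(ph$Y); t <- 2
  V <- (H %x% G) + (R %x% diag(1, n))
  X <- diag(1, t) %x% rep(1, n)
  yv <- as.vector(ph$Y)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% yv)
  gOracle <- (H %x% G) %*% Vi %*% (yv - X %*% beta)
  expect_lt(max(abs(as.vector(gebv(fit)) - gOracle)), 1e-6)
})

test_that("a single-trait multivariate fit reduces to the univariate fit", {
  panel <- makePanel(60, 80, seed = 21)
  bv <- simulateBreedingValues(panel$gm, matrix(1, 1, 1), seed = 22)
  set.seed(23)
  y <- setNames(bv[, 1] + rnorm(60, 0, sd(bv[, 1])), rownames(bv))
  uv <- fitUvGblup(y, panel$K)
  mv <- fitMvGblup(maskedPhenotypes(cbind(T = y)), panel$K,
                   tol = 1e-12, maxIter = 20000)
  expect_lt(max(abs(gebv(uv) - gebv(mv)[, 1])), 1e-6)
})

test_that("independent traits yield near-zero genetic correlation estimates", {
  devs <- vapply(1:8, function(s) {
    panel <- makePanel(150, 250, seed = 150 + s)
    ph <- makePheno(panel, h2 = c(0.5, 0.5), seed = 170 + s, HTrue = diag(2))
    fit <- fitMvGblup(maskedPhenotypes(ph$Y), panel$K)
    fit@HHat[1, 2] / sqrt(fit@HHat[1, 1] * fit@HHat[2, 2])
  }, numeric(1))
  expect_lt(abs(mean(devs)), 0.15)
})

test_that("a correlated secondary trait helps predict a masked target", {
  H <- matrix(c(1, 0.9, 0.9, 1), 2)
  wins <- vapply(1:5, function(s) {
    panel <- makePanel(150, 300, seed = 80 + s)
    ph <- makePheno(panel, h2 = c(0.3, 0.7), seed = 90 + s, HTrue = H)
    mask <- matrix(TRUE, 150, 2, dimnames = dimnames(ph$Y))
    mask[1:30, 1] <- FALSE
    mp <- maskedPhenotypes(ph$Y, mask)
    mv <- fitMvGblup(mp, panel$K)
    accMV <- cor(gebv(mv)[1:30, 1], ph$bv[1:30, 1])
    yU <- ifelse(mask[, 1], ph$Y[, 1], NA)
    names(yU) <- rownames(ph$Y)
    uv <- fitUvGblup(yU, panel$K)
    accUV <- cor(gebv(uv)[1:30], ph$bv[1:30, 1])
    accMV > accUV
  }, logical(1))
  expect_gte(sum(wins), 4)
})

test_that("prediction accuracy is the Pearson correlation with guarded degeneracy", {
  expect_equal(predictAccuracy(c(a = 1, b = 2, c = 3), c(a = 1, b = 2, c = 3)), 1)
  expect_equal(predictAccuracy(c(a = 1, b = 2, c = 3), c(a = -1, b = -2, c = -3)), -1)
  expect_equal(predictAccuracy(setNames(c(1, 2, 3, 4), letters[1:4]),
                               setNames(c(1, 3, 2, 4), letters[1:4])), 0.8)
  expect_warning(
    acc <- predictAccuracy(setNames(rep(1, 4), letters[1:4]),
                           setNames(1:4, letters[1:4])), "zero variance")
  expect_true(is.na(acc))
  expect_error(predictAccuracy(c(a = 1, b = 2), c(a = 1, b = 2)), "3")
})
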