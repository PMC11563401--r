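# Multitrait Bayesian regressions: seeded determinism, shrinkage, model
# equivalences, missing-phenotype augmentation.

shortGibbs <- function(seed = 1, nIter = 600, burnIn = 150)
  gibbsConfig(nIter = nIter, burnIn = burnIn, thin = 2, seed = seed)

test_that("chains are deterministic given the seed and ignore no-op masks", {
  panel <- makePanel(50, 120, seed = 71)
  ph <- makePheno(panel, h2 = c(0.5, 0.5), seed = 72,
                  HTrue = matrix(c(1, 0.4, 0.4, 1), 2))
  cfg <- shortGibbs(7)
  f1 <- fitMtBRR(maskedPhenotypes(ph$Y), panel$gm, cfg)
  f2 <- fitMtBRR(maskedPhenotypes(ph$Y), panel$gm, cfg)
  expect_identical(gebv(f1), gebv(f2))
  # an all-TRUE mask is the same model as no mask at all
  mask <- matrix(TRUE, nrow(ph$Y), ncol(ph$Y), dimnames = dimnames(ph$Y))
  f3 <- fitMtBRR(maskedPhenotypes(ph$Y, mask), panel$gm, cfg)
  expect_identical(gebv(f1), gebv(f3))
  s1 <- fitMtSpikeSlab(maskedPhenotypes(ph$Y), panel$gm, cfg)
  s2 <- fitMtSpikeSlab(maskedPhenotypes(ph$Y), panel$gm, cfg)
  expect_identical(gebv(s1), gebv(s2))
  r1 <- fitMtRKHS(maskedPhenotypes(ph$Y), panel$K, cfg)
  r2 <- fitMtRKHS(maskedPhenotypes(ph$Y), panel$K, cfg)
  expect_identical(gebv(r1), gebv(r2))
})

test_that("BRR with fixed effect variance approaches the SNP-BLUP solution", {
  panel <- makePanel(70, 200, seed = 73)
  ph <- makePheno(panel, h2 = 0.5, seed = 74)
  y <- ph$Y[, 1, drop = FALSE]
  d <- dosages(panel$gm)
  W <- sweep(d, 2, colMeans(d))
  msx <- sum(colSums(W^2)) / nrow(W)
  sigmaE2 <- var(y[, 1]) / 2
  sigmaB2 <- var(y[, 1]) / 2 / msx
  fit <- fitMtBRR(maskedPhenotypes(y), panel$gm,
                  shortGibbs(11, nIter = 1200, burnIn = 300),
                  fixSigmaB = matrix(sigmaB2, 1, 1),
                  fixR0 = matrix(sigmaE2, 1, 1))
  oracle <- snpBlupOracle(y[, 1], W, sigmaE2 / sigmaB2)
  expect_gt(cor(gebv(fit)[, 1], oracle), 0.98)
})

test_that("posterior-mean GEBVs shrink to zero as the effect prior scale vanishes", {
  panel <- makePanel(50, 120, seed = 75)
  ph <- makePheno(panel, h2 = 0.5, seed = 76)
  mp <- maskedPhenotypes(ph$Y)
  f1 <- fitMtBRR(mp, panel$gm, shortGibbs(3), priorScaleMult = 1)
  f2 <- fitMtBRR(mp, panel$gm, shortGibbs(3),
                 fixSigmaB = matrix(1e-8, 1, 1))
  expect_lt(sqrt(mean(gebv(f2)^2)), 0.05 * sqrt(mean(gebv(f1)^2)))
})

test_that("extreme masking still yields finite predictions for everyone", {
  panel <- makePanel(40, 100, seed = 77)
  ph <- makePheno(panel, h2 = 0.5, seed = 78)
  mask <- matrix(FALSE, 40, 1, dimnames = dimnames(ph$Y))
  mask[1:3, 1] <- TRUE
  fit <- fitMtBRR(maskedPhenotypes(ph$Y, mask), panel$gm, shortGibbs(5))
  expect_true(all(is.finite(gebv(fit))))
})

test_that("spike-and-slab recovers the inclusion prior under pure noise", {
  panel <- makePanel(80, 150, seed = 79)
  set.seed(80)
  Y <- matrix(rnorm(160), 80, 2,
              dimnames = list(rownames(dosages(panel$gm)), c("A", "B")))
  fit <- fitMtSpikeSlab(maskedPhenotypes(Y), panel$gm,
                        shortGibbs(13, nIter = 1000, burnIn = 300))
  priorMean <- 1 / (1 + 4)
  expect_lt(abs(mean(fit@inclusionProbs) - priorMean), 0.1)
})

test_that("a single large-effect marker attains high inclusion probability", {
  panel <- makePanel(120, 150, seed = 81)
  d <- dosages(panel$gm)
  W <- sweep(d, 2, colMeans(d))
  set.seed(82)
  beta <- sqrt(0.3 / var(W[, 10]))
  y <- W[, 10] * beta + rnorm(120, 0, sqrt(0.7))
  Y <- matrix(y, dimnames = list(rownames(d), "T"))
  fit <- fitMtSpikeSlab(maskedPhenotypes(Y), panel$gm,
                        shortGibbs(15, nIter = 1000, burnIn = 300))
  expect_gt(fit@inclusionProbs[10, 1], 0.8)
})

test_that("RKHS with the G kernel behaves like multivariate GBLUP", {
  panel <- makePanel(80, 200, seed = 83)
  ph <- makePheno(panel, h2 = c(0.6, 0.6), seed = 84,
                  HTrue = matrix(c(1, 0.5, 0.5, 1), 2))
  G <- grm(panel$K)
  ks <- new("KinshipSet", G = G, kernels = list(G / max(G)),
            bandwidths = NA_real_, markerCountUsed = 0L)
  mp <- maskedPhenotypes(ph$Y)
  rk <- fitMtRKHS(mp, ks, shortGibbs(17, nIter = 1200, burnIn = 400))
  mv <- fitMvGblup(mp, panel$K)
  expect_gt(cor(gebv(rk)[, 1], gebv(mv)[, 1]), 0.95)
})

test_that("single-trait RKHS on noise-free data interpolates", {
  panel <- makePanel(40, 30, seed = 85) # reduced-rank kernel, exact signal
  bv <- simulateBreedingValues(panel$gm, matrix(1, 1, 1), seed = 86)
  Y <- matrix(bv[, 1], dimnames = list(rownames(bv), "T"))
  G <- grm(panel$K)
  ks <- new("KinshipSet", G = G, kernels = list(G / max(G)),
            bandwidths = NA_real_, markerCountUsed = 0L)
  fit <- fitMtRKHS(maskedPhenotypes(Y), ks,
                   shortGibbs(19, nIter = 1000, burnIn = 300))
  expect_gt(cor(gebv(fit)[, 1], Y[, 1]), 0.99)
})

test_that("split-half posterior means of the residual variance are stable", {
  panel <- makePanel(60, 120, seed = 87)
  ph <- makePheno(panel, h2 = 0.5, seed = 88)
  cfg1 <- gibbsConfig(nIter = 900, burnIn = 300, thin = 2, seed = 21)
  cfg2 <- gibbsConfig(nIter = 900, burnIn = 300, thin = 2, seed = 22)
  f1 <- fitMtBRR(maskedPhenotypes(ph$Y), panel$gm, cfg1)
  f2 <- fitMtBRR(maskedPhenotypes(ph$Y), panel$gm, cfg2)
  expect_lt(abs(f1@R0Hat[1, 1] - f2@R0Hat[1, 1]),
            0.15 * (f1@R0Hat[1, 1] + f2@R0Hat[1, 1]))
})
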