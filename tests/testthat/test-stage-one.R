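# Stage-one mixed-model analysis: adjusted means, variance components,
# heritability, summaries, deviation indices and the raw-data ANOVA.

makeToyPlots <- function(nGeno, nYears, nReps, conditions = "C1", seed = 1,
                         sg = 1, sge = 0, se = 0, sy = 0, sr = 0) {
  cfg <- simConfig(nGenotypes = nGeno, nMarkers = 40, traitNames = "T",
                   HTrue = matrix(sg, 1, 1), gxeVariances = sge,
                   residVariances = se, yearVariance = sy, repVariance = sr,
                   nYears = nYears, nReps = nReps, conditions = conditions,
                   missingGenoRate = 0, seed = seed)
  simulateTrial(cfg)
}

test_that("noise-free balanced data reproduce plot means with zero variances", {
  st <- makeToyPlots(8, 2, 2, seed = 21)
  p <- plotRecords(st)
  fit <- fitStageOne(p, "T", "C1", genotypeAs = "fixed")
  pm <- tapply(p$T, p$genotype, mean)
  expect_equal(eblues(fit)[names(pm)], pm, tolerance = 1e-8,
               ignore_attr = TRUE)
  vc <- varComponents(fit)
  expect_lt(max(vc[c("sigma_ge2", "sigma_year2", "sigma_rep2", "sigma_e2")]),
            1e-6)
})

test_that("fixed-genotype E-BLUEs match an OLS normal-equations oracle", {
  st <- makeToyPlots(6, 1, 2, seed = 22, se = 0.5)
  p <- plotRecords(st)
  fit <- fitStageOne(p, "T", "C1", genotypeAs = "fixed")
  # balanced single-year design: GLS = OLS, and the OLS genotype "means"
  # come from solving X'X b = X'y directly
  X <- model.matrix(~ 0 + factor(p$genotype))
  b <- solve(crossprod(X), crossprod(X, p$T))
  ols <- setNames(drop(b), levels(factor(p$genotype)))
  expect_equal(eblues(fit)[names(ols)], ols, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("single-year/single-rep designs are rejected as non-identifiable", {
  st <- makeToyPlots(6, 1, 1, seed = 23, se = 0.5)
  expect_error(fitStageOne(plotRecords(st), "T", "C1"), "identifiable")
})

test_that("heritability follows the entry-mean formula with clamping", {
  mk <- function(sg, sge, se) {
    new("StageOneFit", trait = "T", condition = "C1", eblues = numeric(0),
        varComponents = c(sigma_g2 = sg, sigma_ge2 = sge, sigma_year2 = 0,
                          sigma_rep2 = 0, sigma_e2 = se),
        H2 = NA_real_, logLik = 0, converged = TRUE)
  }
  expect_equal(heritability(mk(1, 0, 0), 2, 2), 1)
  expect_equal(heritability(mk(1, 2, 4), 2, 2), 1 / 3)
  expect_equal(heritability(mk(0, 1, 1), 2, 2), 0)
  expect_warning(h0 <- heritability(mk(0, 0, 0), 2, 2), "zero")
  expect_equal(h0, 0)
  # unit invariance: scaling the trait scales every component by c^2
  expect_equal(heritability(mk(3, 0.9, 1.5), 2, 2),
               heritability(mk(3 * 4, 0.9 * 4, 1.5 * 4), 2, 2))
})

test_that("variance components are recovered on simulated trials", {
  st <- makeToyPlots(150, 2, 2, seed = 24, sg = 1, sge = 0.3, se = 0.5,
                     sy = 0.25, sr = 0.05)
  fit <- fitStageOne(plotRecords(st), "T", "C1", genotypeAs = "random")
  vc <- varComponents(fit)
  dg <- mean(diag(grm(computeGRM(mtgp:::completeRecoded(genotypeData(st))))))
  expect_equal(vc[["sigma_g2"]], dg, tolerance = 0.35) # genetic var on the G scale
  expect_equal(vc[["sigma_e2"]], 0.5, tolerance = 0.25)
})

test_that("E-BLUE summaries compute the declared statistics", {
  s <- summarizeEblues(c(a = 1, b = 2, c = 3))
  expect_equal(s$mean, 2)
  expect_equal(s$min, 1)
  expect_equal(s$max, 3)
  expect_equal(s$SE, 1 / sqrt(3), tolerance = 1e-6) # 0.577
  expect_equal(s$CV, 0.5)
  sc <- summarizeEblues(c(a = 4, b = 4, c = 4))
  expect_equal(sc$SE, 0)
  expect_equal(sc$CV, 0)
  # negative-mean index traits use the absolute mean
  sn <- summarizeEblues(c(a = -1, b = -2, c = -3))
  expect_equal(sn$CV, 0.5)
  expect_warning(sz <- summarizeEblues(c(a = -1, b = 1)), "CV undefined")
  expect_true(is.na(sz$CV))
})

test_that("deviation indices are OLS residuals with the declared geometry", {
  set.seed(25)
  gy <- setNames(rnorm(30, 10, 2), sprintf("g%02d", 1:30))
  # perfect linear relation -> all deviations zero
  expect_lt(max(abs(deriveGPD(2 * gy, gy))), 1e-10)
  expect_lt(max(abs(deriveGYD(-3 * gy, gy))), 1e-10)
  # orthogonal regressor (slope estimate 0 by construction)
  gpc <- setNames(rnorm(30, 12, 1), names(gy))
  gpcOrth <- gpc - drop(cov(gpc, gy) / var(gy)) * gy # residualized
  gpd <- deriveGPD(gpcOrth, gy)
  expect_equal(gpd, gpcOrth - mean(gpcOrth), tolerance = 1e-10,
               ignore_attr = TRUE)
  # generic fixture: residuals orthogonal to the regressor, sum zero
  gpd2 <- deriveGPD(gpc, gy)
  expect_lt(abs(sum(gpd2)), 1e-10)
  expect_lt(abs(sum(gpd2 * gy[names(gpd2)])), 1e-8)
  expect_error(deriveGPD(gpc, setNames(rep(1, 30), names(gy))), "zero variance")
})

test_that("raw-data ANOVA matches hand-computed sums of squares on a balanced toy", {
  # 2 genotypes x 2 years x 2 conditions x 2 reps with known cell means
  grid <- expand.grid(genotype = c("g1", "g2"), year = c("Y1", "Y2"),
                      condition = c("A", "B"), replicate = c("R1", "R2"),
                      stringsAsFactors = FALSE)
  base <- c(g1 = 0, g2 = 4)
  yEff <- c(Y1 = 0, Y2 = 2)
  cEff <- c(A = 0, B = 1)
  grid$T <- base[grid$genotype] + yEff[grid$year] + cEff[grid$condition]
  grid$T <- grid$T + 0.1 * as.integer(factor(grid$replicate)) # tiny block effect
  tab <- suppressWarnings(anovaRaw(grid, "T"))
  # hand values: SS_genotype = N/2 * (mean_g1 - mean)^2 * 2 = n*(d/2)^2 ...
  n <- nrow(grid)
  ssG <- n / 4 * (4)^2 # 2 groups of 8: 8*(2^2)*2 = 64
  ssY <- n / 4 * (2)^2 # 16
  ssC <- n / 4 * (1)^2 # 4
  expect_equal(tab$sumsq[tab$term == "genotype"], 64)
  expect_equal(tab$sumsq[tab$term == "year"], 16)
  expect_equal(tab$sumsq[tab$term == "condition"], 4)
  # purely additive means: interaction SS are zero
  expect_lt(tab$sumsq[tab$term == "genotype:year"], 1e-20)
})

test_that("ANOVA p-values are calibrated under the null and powered under signal", {
  # null: pure-noise trials; the genotype term should reject ~5% of the time
  pvals <- vapply(1:120, function(s) {
    set.seed(400 + s)
    grid <- expand.grid(genotype = sprintf("g%d", 1:10), year = c("Y1", "Y2"),
                        condition = c("A", "B"), replicate = c("R1", "R2"),
                        stringsAsFactors = FALSE)
    grid$T <- rnorm(nrow(grid))
    tab <- anovaRaw(grid, "T")
    tab$p[tab$term == "genotype"]
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.12)

  # power: a large injected condition effect is detected at < 0.001
  hits <- vapply(1:25, function(s) {
    set.seed(600 + s)
    grid <- expand.grid(genotype = sprintf("g%d", 1:10), year = c("Y1", "Y2"),
                        condition = c("A", "B"), replicate = c("R1", "R2"),
                        stringsAsFactors = FALSE)
    grid$T <- rnorm(nrow(grid)) + 2 * (grid$condition == "B")
    tab <- anovaRaw(grid, "T")
    tab$p[tab$term == "condition"] < 0.001
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})
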