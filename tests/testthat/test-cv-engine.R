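# Cross-validation engine: fold plans, masking schemes, experiment
# plumbing, Duncan letters and Fisher comparisons.

test_that("fold plans partition the panel with balanced sizes", {
  ids <- sprintf("g%03d", 1:250)
  plan <- makeFolds(ids, seed = 1, nFolds = 5, nRepeats = 3)
  a <- plan@assignments
  for (r in 1:3) {
    sizes <- table(a$fold[a$repeatIdx == r])
    expect_true(all(sizes == 50))
    expect_setequal(a$genotype[a$repeatIdx == r], ids)
  }
  small <- makeFolds(sprintf("g%d", 1:7), seed = 2, nFolds = 5, nRepeats = 1)
  expect_equal(sort(as.integer(table(small@assignments$fold)),
                    decreasing = TRUE), c(2, 2, 1, 1, 1))
  expect_identical(makeFolds(ids, seed = 1, nFolds = 5, nRepeats = 3)@assignments,
                   plan@assignments)
})

test_that("scheme masks hide exactly the declared cells", {
  ids <- sprintf("g%02d", 1:20)
  pheno <- matrix(rnorm(40), 20, 2, dimnames = list(ids, c("T_A", "T_B")))
  plan <- makeFolds(ids, seed = 3, nFolds = 5, nRepeats = 1)
  vp <- plan@assignments$genotype[plan@assignments$fold == 2]

  mv1 <- buildMask(plan, 1, 2, schemeSpec("MV_CV1", "same_trait_two_conditions",
                                          "T_A", "T_B"), pheno)
  expect_true(all(!mv1@mask[vp, ]))
  expect_true(all(mv1@mask[setdiff(ids, vp), ]))
  expect_equal(sum(!mv1@mask), length(vp) * 2)

  mv2 <- buildMask(plan, 1, 2, schemeSpec("MV_CV2", "same_trait_two_conditions",
                                          "T_A", "T_B"), pheno)
  expect_true(all(!mv2@mask[vp, "T_A"]))
  expect_true(all(mv2@mask[, "T_B"])) # secondary stays visible everywhere
  expect_equal(sum(!mv2@mask), length(vp))

  uv <- buildMask(plan, 1, 2, schemeSpec("UV_CV1", "same_trait_two_conditions",
                                         "T_A"), pheno)
  expect_equal(sum(!uv@mask), length(vp))
  expect_error(schemeSpec("MV_CV2", "same_trait_two_conditions", "T_A"),
               "secondary")
})

test_that("experiment plumbing scores UV-GBLUP cells and skips incompatible models", {
  panel <- makePanel(60, 120, seed = 105)
  ph <- makePheno(panel, h2 = c(0.6, 0.6), seed = 106,
                  HTrue = matrix(c(1, 0.6, 0.6, 1), 2))
  colnames(ph$Y) <- c("T_A", "T_B")
  plan <- makeFolds(rownames(ph$Y), seed = 4, nFolds = 5, nRepeats = 1)
  sp <- schemeSpec("UV_CV1", "same_trait_two_conditions", "T_A")
  res <- runExperiment(c("UV_GBLUP"), sp, ph$Y, panel$K, panel$gm, plan)
  expect_equal(nrow(res), 5L)
  expect_true(all(is.finite(res$accuracy)))
  expect_true(all(res$nVp == 12))
  # RF is incompatible with CV2 and must be skipped with a message
  sp2 <- schemeSpec("MV_CV2", "same_trait_two_conditions", "T_A", "T_B")
  expect_message(
    res2 <- runExperiment(c("RF"), sp2, ph$Y, panel$K, panel$gm, plan),
    "not run")
  expect_equal(nrow(res2), 0L)
  # reproducibility from the master seed
  res3 <- runExperiment(c("UV_GBLUP"), sp, ph$Y, panel$K, panel$gm, plan)
  expect_identical(res, res3)
})

test_that("held-out target values can never influence the fits", {
  panel <- makePanel(50, 100, seed = 107)
  ph <- makePheno(panel, h2 = c(0.5, 0.7), seed = 108,
                  HTrue = matrix(c(1, 0.8, 0.8, 1), 2))
  colnames(ph$Y) <- c("T_A", "T_B")
  plan <- makeFolds(rownames(ph$Y), seed = 5, nFolds = 5, nRepeats = 1)
  for (scheme in c("UV_CV1", "MV_CV1", "MV_CV2")) {
    sec <- if (scheme == "UV_CV1") character() else "T_B"
    sp <- schemeSpec(scheme, "same_trait_two_conditions", "T_A", sec)
    mp <- buildMask(plan, 1, 1, sp, ph$Y)
    poisoned <- mp@values
    poisoned[!mp@mask] <- 9999
    mpP <- new("MaskedPhenotypes", values = poisoned, mask = mp@mask)
    f1 <- fitMvGblup(mp, panel$K)
    f2 <- fitMvGblup(mpP, panel$K)
    expect_identical(gebv(f1), gebv(f2))
  }
})

test_that("Duncan letters match the brute-force range procedure", {
  set.seed(6)
  cells <- list(m1 = rnorm(20, 0.50, 0.03), m2 = rnorm(20, 0.52, 0.03),
                m3 = rnorm(20, 0.70, 0.03), m4 = rnorm(20, 0.71, 0.03))
  got <- duncanTest(cells)
  want <- bruteDuncan(cells)
  expect_identical(got$group, want$group)
  expect_identical(got$letters, want$letters)

  same <- list(a = rep(c(0.1, 0.2), 10), b = rep(c(0.1, 0.2), 10))
  dt <- duncanTest(same)
  expect_true(all(dt$letters == "a"))

  forced <- list(lo = rnorm(20, 0.2, 0.001), hi = rnorm(20, 0.9, 0.001))
  dtF <- duncanTest(forced)
  expect_identical(dtF$letters, c("a", "b")) # ordered by decreasing mean

  # randomized cross-checks against the oracle
  for (s in 1:5) {
    set.seed(100 + s)
    k <- sample(3:6, 1)
    cells <- setNames(lapply(seq_len(k), function(i)
      rnorm(15, runif(1, 0.3, 0.8), 0.05)), paste0("g", seq_len(k)))
    expect_identical(duncanTest(cells)$letters, bruteDuncan(cells)$letters)
  }
})

test_that("Fisher z comparison matches the closed form", {
  fc <- fisherCompare(0.58, 250, 0.53, 250)
  expect_equal(fc$z, 0.8036689110473305, tolerance = 1e-10)
  expect_equal(fc$p, 0.42158821340801705, tolerance = 1e-10)
  eq <- fisherCompare(0.4, 100, 0.4, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  sw <- fisherCompare(0.53, 250, 0.58, 250)
  expect_equal(sw$z, -fc$z)
  expect_error(fisherCompare(1, 100, 0.5, 100), "infinite")
  expect_error(fisherCompare(0.5, 3, 0.5, 100), "n > 3")
})

test_that("percent improvement is the declared ratio with a guarded baseline", {
  expect_equal(percentImprovement(0.6, 0.5), 20)
  expect_equal(percentImprovement(0.5, 0.5), 0)
  # printed rounded accuracies for thousand kernel weight under rainfed
  expect_equal(percentImprovement(0.81, 0.52), 55.769, tolerance = 1e-3)
  expect_warning(pi0 <- percentImprovement(0.4, 0), "zero baseline")
  expect_true(is.na(pi0))
})

test_that("accuracy aggregation reports mean and standard error", {
  res <- data.frame(model = rep(c("A", "B"), each = 4), scheme = "UV_CV1",
                    target = "T", repeatIdx = 1, fold = 1:4,
                    accuracy = c(0.5, 0.6, 0.7, 0.8, 0.2, NA, 0.4, 0.3))
  s <- summarizeCV(res)
  a <- s[s$model == "A", ]
  expect_equal(a$mean, 0.65)
  expect_equal(a$SE, sd(c(0.5, 0.6, 0.7, 0.8)) / 2)
  b <- s[s$model == "B", ]
  expect_equal(b$n, 3L)
  expect_equal(b$nExcluded, 1L)
})
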