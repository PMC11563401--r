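# Genotype QC: HapMap parsing, filters, recoding, imputation, GRM and
# kernels, with loop-oracle cross-checks.

test_that("HapMap calls map to the major/minor numeric coding", {
  path <- writeTinyHapmap(list(c("AA", "AA", "AT", "TT")),
                          c("s1", "s2", "s3", "s4"), tempfile())
  gm <- parseHapmap(path)
  expect_identical(codingState(gm), "raw01half")
  expect_equal(unname(dosages(gm)[, 1]), c(1, 1, 0.5, 0))
})

test_that("HapMap parsing enforces structure and keeps degenerate columns", {
  path <- writeTinyHapmap(list(c("AA", "AT", "TT"), c("NN", "NN", "NN")),
                          c("s1", "s2", "s3"), tempfile())
  gm <- parseHapmap(path)
  expect_equal(ncol(dosages(gm)), 2L)
  expect_true(all(is.na(dosages(gm)[, 2])))
  filtered <- suppressMessages(filterMarkers(gm, mafMin = 0.05))
  expect_equal(ncol(dosages(filtered)), 1L)

  dup <- writeTinyHapmap(list(c("AA", "AT", "TT")), c("s1", "s1", "s3"),
                         tempfile())
  expect_error(parseHapmap(dup), "s1")

  bad <- tempfile()
  lines <- readLines(path)
  lines[2] <- paste(strsplit(lines[2], "\t")[[1]][1:10], collapse = "\t")
  writeLines(lines, bad)
  expect_error(parseHapmap(bad), "line 2")
})

test_that("major-allele ties break alphabetically", {
  path <- writeTinyHapmap(list(c("AA", "TT")), c("s1", "s2"), tempfile())
  gm <- parseHapmap(path)
  # A and T tie at 0.5; A is major by the alphabetical rule
  expect_equal(unname(dosages(gm)[, 1]), c(1, 0))
})

test_that("marker filter applies the MAF and missingness cut-offs with kept boundaries", {
  # MAF 0.04 / 0.05 / 0.30 over 50 inbred individuals, no missing
  n <- 100
  mk <- function(maf) c(rep(0, round(maf * n)), rep(1, n - round(maf * n)))
  d <- cbind(m1 = mk(0.04), m2 = mk(0.05), m3 = mk(0.30))
  rownames(d) <- sprintf("g%02d", 1:n)
  gm <- genotypeMatrix(d, "raw01half")
  out <- suppressMessages(filterMarkers(gm))
  expect_identical(markerIds(out), c("m2", "m3"))

  dMiss <- cbind(m1 = c(rep(NA, 50), mk(0.3)[51:n]), m2 = mk(0.3))
  rownames(dMiss) <- rownames(d)
  out2 <- suppressMessages(filterMarkers(genotypeMatrix(dMiss, "raw01half")))
  expect_identical(markerIds(out2), "m2") # 50% missing removed

  dMono <- cbind(m1 = mk(0.01))
  rownames(dMono) <- rownames(d)
  expect_error(suppressMessages(
    filterMarkers(genotypeMatrix(dMono, "raw01half"))),
    "empty panel")
})

test_that("filter results match a brute-force per-marker recount", {
  cfg <- simConfig(nGenotypes = 120, nMarkers = 400,
                   alleleFreqRange = c(0.01, 0.5), missingGenoRate = 0.1,
                   traitNames = "T", HTrue = matrix(1, 1, 1), seed = 12)
  gm <- simulateGenotypes(cfg)
  kept <- markerIds(suppressMessages(filterMarkers(gm)))
  d <- dosages(gm)
  recount <- vapply(colnames(d), function(j) {
    v <- d[, j]
    obs <- v[!is.na(v)]
    if (!length(obs)) return(FALSE)
    fMajor <- mean(obs) # per-individual frequency of the major allele
    maf <- min(fMajor, 1 - fMajor)
    missFrac <- mean(is.na(v))
    maf >= 0.05 && missFrac <= 0.20
  }, logical(1))
  expect_identical(kept, names(recount)[recount])
})

test_that("recoding is the declared substitution and refuses to run twice", {
  d <- cbind(m1 = c(1, 0.5, 0, NA))
  rownames(d) <- sprintf("g%d", 1:4)
  gm <- genotypeMatrix(d, "raw01half")
  rec <- recodePM1(gm)
  expect_equal(unname(dosages(rec)[, 1]), c(-1, 0, 1, NA))
  expect_error(recodePM1(rec), "twice")
  # bijection on non-missing values
  back <- 1 - (dosages(rec) + 1) / 2
  expect_equal(back[1:3], d[1:3])
})

test_that("mean imputation preserves column means and completes the matrix", {
  d <- cbind(m1 = c(-1, 1, NA), m2 = c(-1, 0, 1))
  rownames(d) <- c("a", "b", "c")
  gm <- genotypeMatrix(d, "recoded_pm1")
  imp <- imputeMean(gm)
  expect_equal(dosages(imp)[3, "m1"], 0)
  expect_identical(dosages(imputeMean(imp)), dosages(imp)) # no-op when complete
  set.seed(13)
  d2 <- matrix(sample(c(-1, 0, 1, NA), 200, replace = TRUE), 20, 10,
               dimnames = list(sprintf("g%02d", 1:20), sprintf("m%02d", 1:10)))
  gm2 <- genotypeMatrix(d2, "recoded_pm1")
  imp2 <- imputeMean(gm2)
  pre <- colMeans(d2, na.rm = TRUE)
  expect_equal(colMeans(dosages(imp2)), pre, tolerance = 1e-12)
})

test_that("the GRM matches its marker-by-marker definition and expectations", {
  # identical fully inbred individuals share diagonal and off-diagonal entries
  d <- rbind(g1 = c(-1, 1, -1, 1), g2 = c(-1, 1, -1, 1), g3 = c(1, -1, 1, -1),
             g4 = c(-1, -1, 1, 1))
  colnames(d) <- sprintf("m%d", 1:4)
  G <- grm(computeGRM(genotypeMatrix(d, "recoded_pm1")))
  expect_equal(G["g1", "g2"], G["g1", "g1"], tolerance = 1e-12)

  # loop oracle on a random 10 x 50 instance
  panel <- makePanel(10, 50, seed = 14)
  d2 <- dosages(panel$gm)
  p <- colMeans((d2 + 1) / 2)
  cNorm <- sum(2 * p * (1 - p))
  W <- sweep(d2, 2, colMeans(d2))
  Gloop <- matrix(0, 10, 10)
  for (j in seq_len(ncol(W))) Gloop <- Gloop + outer(W[, j], W[, j])
  Gloop <- Gloop / cNorm
  expect_lt(max(abs(grm(computeGRM(panel$gm)) - Gloop)), 1e-10)

  # mean diagonal close to 1 + f for a near-fully-inbred panel
  big <- makePanel(150, 1000, seed = 15)
  dg <- mean(diag(grm(big$K)))
  expect_gt(dg, 0.9 * 1.95)
  expect_lt(dg, 1.2 * 1.95)

  expect_error(computeGRM(genotypeMatrix(
    matrix(1, 3, 2, dimnames = list(letters[1:3], c("m1", "m2"))),
    "recoded_pm1")), "monomorphic")
})

test_that("GRM is invariant to marker order and duplication", {
  panel <- makePanel(15, 60, seed = 16)
  d <- dosages(panel$gm)
  G1 <- grm(computeGRM(panel$gm))
  perm <- sample(ncol(d))
  G2 <- grm(computeGRM(genotypeMatrix(d[, perm], "recoded_pm1")))
  expect_lt(max(abs(G1 - G2)), 1e-10)
  dd <- cbind(d, d)
  colnames(dd) <- sprintf("m%03d", seq_len(ncol(dd)))
  G3 <- grm(computeGRM(genotypeMatrix(dd, "recoded_pm1")))
  expect_lt(max(abs(G1 - G3)), 1e-10)
})

test_that("Gaussian kernels have the declared geometry", {
  d <- rbind(g1 = c(-1, 1, 0), g2 = c(-1, 1, 0), g3 = c(1, -1, 1))
  colnames(d) <- c("m1", "m2", "m3")
  gm <- genotypeMatrix(d, "recoded_pm1")
  ks <- computeKernels(gm, bandwidths = c(0.5, 2))
  K1 <- kernelMatrices(ks)[[1]]
  expect_equal(K1["g1", "g2"], 1) # identical individuals
  ks0 <- computeKernels(gm, bandwidths = 0)
  expect_true(all(kernelMatrices(ks0)[[1]] == 1)) # h -> 0 limit

  panel <- makePanel(20, 80, seed = 17)
  ksP <- computeKernels(panel$gm, bandwidths = 1)
  K <- kernelMatrices(ksP)[[1]]
  # the median off-diagonal scaled distance maps to exp(-h)
  expect_equal(median(-log(K[upper.tri(K)])), 1, tolerance = 1e-9)
  expect_lt(max(abs(K - t(K))), 1e-10)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  expect_error(computeKernels(genotypeMatrix(
    matrix(0, 1, 3, dimnames = list("g1", c("m1", "m2", "m3"))),
    "recoded_pm1")), "2 individuals")
})

test_that("filtering and recoding commute", {
  cfg <- simConfig(nGenotypes = 60, nMarkers = 200,
                   alleleFreqRange = c(0.02, 0.5), missingGenoRate = 0.05,
                   traitNames = "T", HTrue = matrix(1, 1, 1), seed = 18)
  gm <- simulateGenotypes(cfg)
  a <- suppressMessages(recodePM1(filterMarkers(gm)))
  b <- suppressMessages(filterMarkers(recodePM1(gm)))
  expect_identical(markerIds(a), markerIds(b))
  expect_identical(dosages(a), dosages(b))
})
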