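## Synthetic multi-condition trial generator: genotypes, correlated true
## breeding values, and randomized-complete-block plot records with the
## variance structure of the stage-one model (genotype + year +
## replicate-within-year + genotype-by-year + residual).

## default genetic architecture of the simulated panel: seven traits named
## after the durum-wheat trait set, broad-sense heritabilities spread from
## low (NDVI) to very high (TKW) on a 2-year x 2-rep entry-mean basis, and
## genetic correlations with grain yield spanning about -0.45 to +0.35.
defaultTraitArchitecture <- function() {
  traits <- c("GY", "GPC", "TKW", "TW", "YI", "NDVI", "FLA")
  h2 <- c(GY = 0.55, GPC = 0.80, TKW = 0.90, TW = 0.85, YI = 0.40,
          NDVI = 0.15, FLA = 0.65)
  ## the realized genetic variance of a trait with unit H entry is
  ## mean(diag(G)) ~ 2 - het/(2 p q) ~ 1.95 for a near-fully-inbred panel;
  ## with sigma_ge2 = sigma_e2 = s the entry-mean heritability at
  ## y = r = 2 is dg / (dg + s/2 + s/4)  =>  s = dg (1/H2 - 1) / 0.75
  dg <- 1.95
  s <- dg * (1 / h2 - 1) / 0.75
  R <- diag(1, 7); dimnames(R) <- list(traits, traits)
  gyCor <- c(GPC = -0.43, TKW = 0.34, TW = 0.32, YI = 0.30, NDVI = 0.28,
             FLA = -0.11)
  R["GY", names(gyCor)] <- gyCor
  R[names(gyCor), "GY"] <- gyCor
  ## mild background correlations among the yield-component traits
  bg <- list(c("TKW", "TW", 0.25), c("TKW", "YI", 0.10), c("TW", "YI", 0.10),
             c("GPC", "YI", 0.15), c("NDVI", "FLA", -0.10))
  for (b in bg) {
    R[b[[1]], b[[2]]] <- as.numeric(b[[3]])
    R[b[[2]], b[[1]]] <- as.numeric(b[[3]])
  }
  R <- bendPSD(R, floor = 1e-8, jitter = 1e-6)
  d <- sqrt(diag(R)); R <- R / outer(d, d) # renormalize after bending
  list(traits = traits, HTrue = R, gxe = setNames(s, traits),
       resid = setNames(s, traits))
}

#' Configure the synthetic trial generator
#'
#' Defaults emulate the structure of a durum-wheat association panel
#' evaluated under two field conditions: 250 inbred genotypes, 5000
#' biallelic markers with minor allele frequencies in (0.05, 0.5), 2 years
#' x 2 replicates x 2 conditions, and seven traits whose heritabilities
#' and genetic correlations span the ranges typical of yield, quality and
#' phenology traits.
#'
#' @param nGenotypes,nMarkers panel dimensions.
#' @param alleleFreqRange length-2 range of simulated minor allele
#'   frequencies, strictly inside (0, 1).
#' @param traitNames trait labels.
#' @param HTrue t x t genetic covariance matrix (defaults to the built-in
#'   seven-trait architecture when \code{traitNames} is left at default).
#' @param gxeVariances,residVariances per-trait genotype-by-year and
#'   residual plot variances.
#' @param yearVariance,repVariance year and replicate-within-year effect
#'   variances (trait units^2); defaults 0.25 and 0.05.
#' @param nYears,nReps design counts (defaults 2 and 2).
#' @param conditions condition labels (default \code{c("HNW", "LNR")}).
#' @param conditionCor genetic correlation of the same trait across
#'   conditions (default 0.6).
#' @param missingGenoRate missing-call rate of the simulated genotype
#'   matrix (default 0.02).
#' @param selfingHet target residual heterozygosity of the inbred panel
#'   (default 0.02).
#' @param seed integer seed; every stochastic component of the generator is
#'   derived from it via \code{\link{childSeed}}.
#' @return A validated \code{SimConfig}.
#' @examples
#' cfg <- simConfig(nGenotypes = 20, nMarkers = 50, seed = 1)
#' @export
simConfig <- function(nGenotypes = 250L, nMarkers = 5000L,
                      alleleFreqRange = c(0.05, 0.5),
                      traitNames = NULL, HTrue = NULL,
                      gxeVariances = NULL, residVariances = NULL,
                      yearVariance = 0.25, repVariance = 0.05,
                      nYears = 2L, nReps = 2L,
                      conditions = c("HNW", "LNR"), conditionCor = 0.6,
                      missingGenoRate = 0.02, selfingHet = 0.02,
                      seed = 1L) {
  if (is.null(traitNames)) {
    arch <- defaultTraitArchitecture()
    traitNames <- arch$traits
    HTrue <- HTrue %||% arch$HTrue
    gxeVariances <- gxeVariances %||% arch$gxe
    residVariances <- residVariances %||% arch$resid
  }
  t <- length(traitNames)
  if (is.null(HTrue)) HTrue <- diag(1, t)
  if (is.null(dimnames(HTrue))) dimnames(HTrue) <- list(traitNames, traitNames)
  if (is.null(gxeVariances)) gxeVariances <- rep(0.3, t)
  if (is.null(residVariances)) residVariances <- rep(0.5, t)
  if (length(gxeVariances) == 1L) gxeVariances <- rep(gxeVariances, t)
  if (length(residVariances) == 1L) residVariances <- rep(residVariances, t)
  new("SimConfig", nGenotypes = as.integer(nGenotypes),
      nMarkers = as.integer(nMarkers),
      alleleFreqRange = as.numeric(alleleFreqRange),
      traitNames = as.character(traitNames), HTrue = HTrue,
      gxeVariances = setNames(as.numeric(gxeVariances), traitNames),
      residVariances = setNames(as.numeric(residVariances), traitNames),
      yearVariance = yearVariance, repVariance = repVariance,
      nYears = as.integer(nYears), nReps = as.integer(nReps),
      conditions = as.character(conditions), conditionCor = conditionCor,
      missingGenoRate = missingGenoRate, selfingHet = selfingHet,
      seed = as.integer(seed))
}

## grand mean (trait units) added to every simulated plot value
simGrandMean <- function() 10

#' Simulate a genotype panel of inbred lines
#'
#' Markers are simulated independently (no linkage disequilibrium): each
#' marker draws a minor allele frequency from \code{alleleFreqRange}, and
#' genotypes follow Hardy-Weinberg proportions deflated for inbreeding so
#' that the expected heterozygosity equals \code{selfingHet}. Calls are
#' coded 1 = homozygous major, 0.5 = heterozygous, 0 = homozygous minor;
#' missing calls are placed completely at random at \code{missingGenoRate}.
#'
#' @param config a \code{SimConfig}.
#' @return A \code{GenotypeMatrix} in coding state \code{"raw01half"}.
#' @export
simulateGenotypes <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  n <- config@nGenotypes; m <- config@nMarkers
  set.seed(childSeed(config@seed, "genotypes"))
  p <- runif(m, config@alleleFreqRange[1], config@alleleFreqRange[2]) # minor freq
  hetP <- pmin(1, config@selfingHet / (2 * p * (1 - p)))              # 2pq(1-f)
  probHet <- 2 * p * (1 - p) * hetP
  ## conditional on not heterozygous, split remaining mass p^2+fpq vs q^2+fpq
  f <- 1 - hetP
  probMinor <- p^2 + f * p * (1 - p)
  probMajor <- 1 - probHet - probMinor
  u <- matrix(runif(n * m), n, m)
  d <- matrix(1, n, m) # homozygous major
  hetCut <- rep(probMajor, each = n)
  minCut <- rep(probMajor + probHet, each = n)
  d[u >= hetCut & u < minCut] <- 0.5
  d[u >= minCut] <- 0
  if (config@missingGenoRate > 0) {
    d[matrix(runif(n * m), n, m) < config@missingGenoRate] <- NA_real_
  }
  dimnames(d) <- list(sprintf("G%03d", seq_len(n)), sprintf("M%05d", seq_len(m)))
  genotypeMatrix(d, "raw01half")
}

## complete recoded matrix from any GenotypeMatrix (no filtering)
completeRecoded <- function(gm) {
  if (identical(codingState(gm), "raw01half")) gm <- recodePM1(gm)
  imputeMean(gm)
}

#' Simulate true breeding values from the GBLUP prior
#'
#' Draws the stacked breeding-value vector from N(0, \code{HTrue} \%x\% G),
#' where G is the realized genomic relationship matrix of the panel, and
#' returns it as a genotype x trait matrix. This makes GBLUP exactly
#' correctly specified for the simulated data. With
#' \code{method = "markers"}, breeding values are instead built from
#' explicit i.i.d. normal marker effects (\code{W E t(chol(HTrue)) /
#' sqrt(c)}), which has the same covariance and provides the marker-effect
#' route used by the SNP-BLUP equivalence checks.
#'
#' @param genotypes a \code{GenotypeMatrix} (imputed internally if needed).
#' @param HTrue t x t positive semidefinite genetic covariance matrix.
#' @param seed integer seed.
#' @param method \code{"gblup"} (default) or \code{"markers"}.
#' @return genotype x trait matrix of breeding values.
#' @export
simulateBreedingValues <- function(genotypes, HTrue, seed, method = c("gblup", "markers")) {
  method <- match.arg(method)
  stopifnot(is(genotypes, "GenotypeMatrix"))
  HTrue <- as.matrix(HTrue)
  evH <- eigen((HTrue + t(HTrue)) / 2, symmetric = TRUE)
  if (min(evH$values) < -1e-8 * max(abs(evH$values), 1))
    stopf("HTrue is not positive semidefinite: eigenvalue %.6g < 0", min(evH$values))
  t <- nrow(HTrue)
  LH <- evH$vectors %*% diag(sqrt(pmax(evH$values, 0)), t)
  gm <- completeRecoded(genotypes)
  n <- nrow(dosages(gm))
  set.seed(seed)
  if (method == "gblup") {
    G <- grm(computeGRM(gm))
    evG <- eigen(G, symmetric = TRUE)
    LG <- evG$vectors %*% diag(sqrt(pmax(evG$values, 0)), n)
    Z <- matrix(rnorm(n * t), n, t)
    bv <- LG %*% Z %*% t(LH)
  } else {
    d <- dosages(gm)
    p <- colMeans((d + 1) / 2)
    cNorm <- sum(2 * p * (1 - p))
    W <- sweep(d, 2, colMeans(d))
    E <- matrix(rnorm(ncol(W) * t), ncol(W), t)
    bv <- W %*% E %*% t(LH) / sqrt(cNorm)
  }
  dimnames(bv) <- list(rownames(dosages(gm)),
                       colnames(HTrue) %||% paste0("T", seq_len(t)))
  bv
}

#' Simulate a complete multi-condition field trial
#'
#' Generates genotypes, true breeding values and plot records. A trait's
#' genetic value in the two (or more) conditions is drawn jointly with
#' cross-condition correlation \code{conditionCor}, so the same trait
#' measured under different managements behaves as two genetically
#' correlated traits. Each plot value is
#' grand mean + breeding value + year effect + replicate-within-year
#' effect + genotype-by-year effect + residual, every random term drawn
#' with its configured variance; the result is fully reproducible from
#' \code{config@seed}.
#'
#' @param config a \code{SimConfig}.
#' @return A \code{SimulatedStudy}. The true-breeding-value matrix has one
#'   column per trait:condition combination (named
#'   \code{"<trait>_<condition>"}) when more than one condition is
#'   configured.
#' @export
simulateTrial <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  gm <- simulateGenotypes(config)
  nc <- length(config@conditions)
  t <- length(config@traitNames)
  if (nc > 1L) {
    Ccond <- matrix(config@conditionCor, nc, nc); diag(Ccond) <- 1
    Hexp <- config@HTrue %x% Ccond
    combos <- as.vector(t(outer(config@traitNames, config@conditions, paste, sep = "_")))
    dimnames(Hexp) <- list(combos, combos)
  } else {
    Hexp <- config@HTrue
  }
  bv <- simulateBreedingValues(gm, Hexp, seed = childSeed(config@seed, "bv"))
  ids <- rownames(dosages(gm))
  years <- sprintf("Y%d", seq_len(config@nYears))
  reps <- sprintf("R%d", seq_len(config@nReps))
  grid <- expand.grid(genotype = ids, replicate = reps, year = years,
                      condition = config@conditions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("genotype", "year", "condition", "replicate")]
  set.seed(childSeed(config@seed, "plots"))
  out <- grid
  gi <- match(grid$genotype, ids)
  for (trait in config@traitNames) {
    vals <- numeric(nrow(grid))
    for (cond in config@conditions) {
      bvCol <- if (nc > 1L) paste(trait, cond, sep = "_") else trait
      yearEff <- setNames(rnorm(length(years), 0, sqrt(config@yearVariance)), years)
      repEff <- matrix(rnorm(length(years) * length(reps), 0,
                             sqrt(config@repVariance)),
                       length(years), length(reps), dimnames = list(years, reps))
      gxe <- matrix(rnorm(length(ids) * length(years), 0,
                          sqrt(config@gxeVariances[[trait]])),
                    length(ids), length(years), dimnames = list(ids, years))
      sel <- grid$condition == cond
      yi <- match(grid$year[sel], years)
      ri <- match(grid$replicate[sel], reps)
      vals[sel] <- simGrandMean() + bv[cbind(gi[sel], match(bvCol, colnames(bv)))] +
        yearEff[yi] + repEff[cbind(yi, ri)] + gxe[cbind(gi[sel], yi)] +
        rnorm(sum(sel), 0, sqrt(config@residVariances[[trait]]))
    }
    out[[trait]] <- vals
  }
  new("SimulatedStudy", genotypes = gm, trueBreedingValues = bv,
      plots = out, config = config)
}
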