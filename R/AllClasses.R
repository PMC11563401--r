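## Central S4 containers. Heavier analysis results (CV accuracy tables,
## ANOVA tables, trait summaries) are plain data.frames.

#' GenotypeMatrix: biallelic dosages for a panel of individuals
#'
#' Individuals are rows, markers are columns. Two coding states are
#' supported: \code{"raw01half"} (1 = homozygous major allele, 0 =
#' homozygous minor, 0.5 = heterozygous, the TASSEL-style numeric export)
#' and \code{"recoded_pm1"} (-1 = homozygous major, +1 = homozygous minor,
#' 0 = heterozygous), the coding used by all downstream models. Missing
#' calls are \code{NA}.
#'
#' @slot dosages numeric matrix, individuals x markers, with dimnames.
#' @slot codingState \code{"raw01half"} or \code{"recoded_pm1"}.
#' @export
setClass("GenotypeMatrix",
  representation(dosages = "matrix", codingState = "character"),
  validity = function(object) {
    d <- object@dosages
    msg <- character()
    if (is.null(rownames(d)) || is.null(colnames(d)))
      msg <- c(msg, "dosages must carry individual (row) and marker (column) names")
    else {
      if (anyDuplicated(rownames(d))) msg <- c(msg, "duplicated individual IDs")
      if (anyDuplicated(colnames(d))) msg <- c(msg, "duplicated marker IDs")
    }
    if (!object@codingState %in% c("raw01half", "recoded_pm1"))
      msg <- c(msg, "codingState must be 'raw01half' or 'recoded_pm1'")
    v <- d[!is.na(d)]
    allowed <- if (identical(object@codingState, "raw01half")) c(0, 0.5, 1) else c(-1, 0, 1)
    ## imputed matrices hold per-marker means, which are off-grid; only the
    ## strict codings are enforced here, fractional values are allowed for
    ## recoded_pm1 within [-1, 1]
    if (identical(object@codingState, "raw01half") && length(v) && !all(v %in% allowed))
      msg <- c(msg, "raw01half entries must be in {0, 0.5, 1, NA}")
    if (identical(object@codingState, "recoded_pm1") && length(v) &&
        (min(v) < -1 - 1e-9 || max(v) > 1 + 1e-9))
      msg <- c(msg, "recoded_pm1 entries must lie in [-1, 1] or NA")
    if (length(msg)) msg else TRUE
  }
)

#' KinshipSet: genomic relationship matrix and Gaussian kernels
#'
#' @slot G n x n genomic relationship matrix (VanRaden-type), bent to
#'   positive semidefiniteness if required.
#' @slot kernels list of n x n Gaussian kernel matrices, one per bandwidth.
#' @slot bandwidths numeric vector of bandwidths, parallel to kernels.
#' @slot markerCountUsed integer, markers entering the construction.
#' @export
setClass("KinshipSet",
  representation(G = "matrix", kernels = "list", bandwidths = "numeric",
                 markerCountUsed = "integer"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@G) != ncol(object@G)) msg <- c(msg, "G must be square")
    if (max(abs(object@G - t(object@G))) > 1e-8) msg <- c(msg, "G must be symmetric")
    if (length(object@kernels) != length(object@bandwidths))
      msg <- c(msg, "one bandwidth per kernel required")
    for (K in object@kernels) {
      if (!all(dim(K) == dim(object@G))) msg <- c(msg, "kernel dimensions must match G")
      ## Gaussian kernels lie in (0, 1] by construction; relationship-type
      ## kernels (e.g. G itself) may carry small negative off-diagonals
      if (length(K) && max(K) > 1 + 1e-6)
        msg <- c(msg, "kernel entries must not exceed 1")
      if (length(K) && max(abs(K - t(K))) > 1e-8)
        msg <- c(msg, "kernels must be symmetric")
    }
    if (length(msg)) msg else TRUE
  }
)

#' MaskedPhenotypes: genotype x trait values with an observation mask
#'
#' Realizes the training/validation phenotype availability of the CV1/CV2
#' cross-validation schemes. \code{values} may itself contain \code{NA}
#' (never measured); \code{mask} marks which entries a model is allowed to
#' see. Models must access the data through \code{\link{observedValues}},
#' which hides masked cells, so held-out values can never leak.
#'
#' @slot values numeric matrix, genotypes x traits, with dimnames.
#' @slot mask logical matrix of the same shape; TRUE = visible to models.
#' @export
setClass("MaskedPhenotypes",
  representation(values = "matrix", mask = "matrix"),
  validity = function(object) {
    msg <- character()
    if (!all(dim(object@values) == dim(object@mask)))
      msg <- c(msg, "mask shape must match values")
    if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
    obs <- object@mask & !is.na(object@values)
    if (ncol(obs) && any(colSums(obs) == 0))
      msg <- c(msg, "every trait needs at least one observed entry")
    if (length(msg)) msg else TRUE
  }
)

#' SimConfig: parameters of the synthetic multi-condition trial generator
#'
#' Defines the genetic architecture (per-trait genetic variances and
#' covariances), the trial design (years, replicates, conditions) and the
#' nuisance variances used to simulate plot records from a randomized
#' complete block, multi-year trial.
#'
#' @slot nGenotypes,nMarkers panel dimensions.
#' @slot alleleFreqRange minor-allele frequency range for simulated markers.
#' @slot traitNames trait labels.
#' @slot HTrue t x t genetic covariance matrix among traits (trait units^2).
#' @slot gxeVariances,residVariances per-trait genotype-by-year and residual
#'   variances.
#' @slot yearVariance,repVariance variances of the year and
#'   replicate-within-year effects (shared across traits).
#' @slot nYears,nReps design counts.
#' @slot conditions condition labels (e.g. \code{c("HNW","LNR")}).
#' @slot conditionCor genetic correlation of a trait's expression across
#'   conditions.
#' @slot missingGenoRate missing-call rate in simulated genotypes.
#' @slot selfingHet residual heterozygosity of the inbred panel.
#' @slot seed integer seed.
#' @export
setClass("SimConfig",
  representation(nGenotypes = "integer", nMarkers = "integer",
                 alleleFreqRange = "numeric", traitNames = "character",
                 HTrue = "matrix", gxeVariances = "numeric",
                 residVariances = "numeric", yearVariance = "numeric",
                 repVariance = "numeric", nYears = "integer", nReps = "integer",
                 conditions = "character", conditionCor = "numeric",
                 missingGenoRate = "numeric", selfingHet = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    t <- length(object@traitNames)
    if (object@nGenotypes < 1L || object@nMarkers < 1L)
      msg <- c(msg, "non-positive dimensions")
    if (length(object@alleleFreqRange) != 2L ||
        any(object@alleleFreqRange <= 0) || any(object@alleleFreqRange >= 1))
      msg <- c(msg, "allele frequencies must lie strictly in (0, 1)")
    if (!all(dim(object@HTrue) == c(t, t)))
      msg <- c(msg, "HTrue must be t x t for t traits")
    else if (max(abs(object@HTrue - t(object@HTrue))) > 1e-8 || !isPSD(object@HTrue))
      msg <- c(msg, "HTrue must be symmetric positive semidefinite")
    if (length(object@gxeVariances) != t || any(object@gxeVariances < 0))
      msg <- c(msg, "gxeVariances must be t nonnegative values")
    if (length(object@residVariances) != t || any(object@residVariances < 0))
      msg <- c(msg, "residVariances must be t nonnegative values")
    if (object@yearVariance < 0 || object@repVariance < 0)
      msg <- c(msg, "design variances must be nonnegative")
    if (object@nReps < 1L) msg <- c(msg, "nReps must be >= 1")
    if (object@nYears < 1L) msg <- c(msg, "nYears must be >= 1")
    if (object@missingGenoRate < 0 || object@missingGenoRate >= 1)
      msg <- c(msg, "missingGenoRate must be in [0, 1)")
    if (object@conditionCor < -1 || object@conditionCor > 1)
      msg <- c(msg, "conditionCor must be in [-1, 1]")
    if (length(msg)) msg else TRUE
  }
)

#' SimulatedStudy: a complete synthetic trial with known ground truth
#'
#' @slot genotypes a \code{GenotypeMatrix}.
#' @slot trueBreedingValues genotype x (trait or trait:condition) matrix of
#'   the simulated additive genetic values.
#' @slot plots plot-record data.frame: genotype, year, condition, replicate,
#'   then one column per trait.
#' @slot config the \code{SimConfig} used.
#' @export
setClass("SimulatedStudy",
  representation(genotypes = "GenotypeMatrix", trueBreedingValues = "matrix",
                 plots = "data.frame", config = "SimConfig"),
  validity = function(object) {
    msg <- character()
    if (!all(unique(object@plots$genotype) %in% rownames(object@genotypes@dosages)))
      msg <- c(msg, "every genotype in plots must exist in genotypes")
    cfg <- object@config
    perCond <- cfg@nGenotypes * cfg@nYears * cfg@nReps
    cnt <- table(object@plots$condition)
    if (length(cnt) && !all(cnt == perCond))
      msg <- c(msg, "plots must contain nGenotypes x nYears x nReps rows per condition")
    if (length(msg)) msg else TRUE
  }
)

#' StageOneFit: one trait/condition stage-one mixed-model analysis
#'
#' @slot trait,condition labels.
#' @slot eblues named numeric vector of adjusted genotype means (genotype
#'   fitted as fixed), or the empty vector for a variance-component fit.
#' @slot varComponents named numeric vector: sigma_g2 (genotype), sigma_ge2
#'   (genotype-by-year), sigma_year2, sigma_rep2 (replicate within year),
#'   sigma_e2 (residual). sigma_g2 is NA when the genotype was fixed.
#' @slot H2 broad-sense heritability on an entry-mean basis (NA for fixed
#'   genotype fits).
#' @slot logLik REML log-likelihood.
#' @slot converged logical.
#' @export
setClass("StageOneFit",
  representation(trait = "character", condition = "character",
                 eblues = "numeric", varComponents = "numeric",
                 H2 = "numeric", logLik = "numeric", converged = "logical"))

#' GeneticParams: bivariate genomic variance/covariance estimates
#'
#' @slot traits the two trait labels.
#' @slot SigmaG 2 x 2 genetic covariance matrix.
#' @slot SigmaE 2 x 2 residual covariance matrix.
#' @slot rhoG genetic correlation.
#' @slot estimator label of the estimator used.
#' @export
setClass("GeneticParams",
  representation(traits = "character", SigmaG = "matrix", SigmaE = "matrix",
                 rhoG = "numeric", estimator = "character"))

#' UvGblupFit: univariate GBLUP fit
#'
#' @slot sigmaG2,sigmaE2 REML variance estimates.
#' @slot gebv named vector of genomic breeding values for every individual
#'   in G (phenotyped or not).
#' @slot mu GLS intercept.
#' @slot logLik REML log-likelihood at the optimum.
#' @slot converged logical.
#' @export
setClass("UvGblupFit",
  representation(sigmaG2 = "numeric", sigmaE2 = "numeric", gebv = "numeric",
                 mu = "numeric", logLik = "numeric", converged = "logical"))

#' MvGblupFit: multivariate GBLUP fit (EM-REML)
#'
#' @slot HHat t x t genetic covariance among traits.
#' @slot RHat t x t residual covariance (diagonal unless fitted unstructured).
#' @slot gebvMatrix genotype x trait matrix of breeding values.
#' @slot mu trait intercepts.
#' @slot logLik REML log-likelihood trace (last value = final).
#' @slot converged logical.
#' @export
setClass("MvGblupFit",
  representation(HHat = "matrix", RHat = "matrix", gebvMatrix = "matrix",
                 mu = "numeric", logLik = "numeric", converged = "logical"))

#' GibbsConfig: sampler settings for the multitrait Bayesian models
#'
#' @slot nIter,burnIn,thin chain controls.
#' @slot seed integer seed of the chain.
#' @slot dfPrior inverse-Wishart degrees of freedom added to t (effect and
#'   residual covariance priors use df = t + dfPrior).
#' @slot scaleSplit fraction of the empirical phenotypic (co)variance
#'   assigned to the genetic side of the prior scales.
#' @slot inclusionBeta Beta prior (a, b) on the spike-and-slab inclusion
#'   probability per trait.
#' @export
setClass("GibbsConfig",
  representation(nIter = "integer", burnIn = "integer", thin = "integer",
                 seed = "integer", dfPrior = "numeric", scaleSplit = "numeric",
                 inclusionBeta = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@burnIn >= object@nIter) msg <- c(msg, "burnIn must be < nIter")
    if (object@thin < 1L) msg <- c(msg, "thin must be >= 1")
    if (object@dfPrior <= 0) msg <- c(msg, "dfPrior must be positive")
    if (length(object@inclusionBeta) != 2L || any(object@inclusionBeta <= 0))
      msg <- c(msg, "inclusionBeta must be two positive shape parameters")
    if (length(msg)) msg else TRUE
  }
)

#' MtBayesFit: multitrait Bayesian whole-genome regression fit
#'
#' @slot model "BRR", "SpikeSlab" or "RKHS".
#' @slot posteriorMeanGebv genotype x trait posterior-mean genetic values.
#' @slot effects posterior mean marker x trait effects (BRR/SpikeSlab) or a
#'   list of individual x trait kernel effects (RKHS).
#' @slot R0Hat posterior mean residual covariance.
#' @slot inclusionProbs marker x trait posterior inclusion probabilities
#'   (SpikeSlab only; otherwise a 0 x 0 matrix).
#' @slot mu posterior-mean trait intercepts.
#' @slot chainSeed seed used for the chain.
#' @export
setClass("MtBayesFit",
  representation(model = "character", posteriorMeanGebv = "matrix",
                 effects = "ANY", R0Hat = "matrix", inclusionProbs = "matrix",
                 mu = "numeric", chainSeed = "integer"))

#' RfConfig: multivariate random-forest tuning grid
#'
#' Defaults follow the standard genomic-prediction grid: trees
#' \{100, 200, 300\}, mtry \{80, 100, 120\}, minimum terminal node size
#' \{3, 6, 9\}, tuned by inner 5-fold cross-validation on the training set.
#'
#' @slot nTreesGrid,mtryGrid,minNodeGrid hyperparameter grids.
#' @slot innerFolds inner CV folds used for tuning.
#' @slot seed integer seed.
#' @export
setClass("RfConfig",
  representation(nTreesGrid = "integer", mtryGrid = "integer",
                 minNodeGrid = "integer", innerFolds = "integer",
                 seed = "integer"),
  validity = function(object) {
    if (!length(object@nTreesGrid) || !length(object@mtryGrid) ||
        !length(object@minNodeGrid)) return("grids must be non-empty")
    if (object@innerFolds < 2L) return("innerFolds must be >= 2")
    TRUE
  }
)

#' RfFit: fitted multivariate random forest
#'
#' @slot chosen named vector of the selected hyperparameters.
#' @slot forest external-pointer-free list representation of the ensemble.
#' @slot predictions training-panel genotype x trait predictions.
#' @slot markerIds markers the forest was grown on (prediction inputs must
#'   match).
#' @slot tuningTable per-grid-point inner-CV scores.
#' @export
setClass("RfFit",
  representation(chosen = "numeric", forest = "list", predictions = "matrix",
                 markerIds = "character", tuningTable = "data.frame"))

#' FoldPlan: repeated k-fold partitions of the panel
#'
#' @slot assignments data.frame with columns repeatIdx, genotype, fold.
#' @slot nFolds,nRepeats,seed plan parameters.
#' @export
setClass("FoldPlan",
  representation(assignments = "data.frame", nFolds = "integer",
                 nRepeats = "integer", seed = "integer"))

#' SchemeSpec: one cross-validation scheme applied to one analysis
#'
#' @slot scheme "UV_CV1", "MV_CV1" or "MV_CV2".
#' @slot analysis "same_trait_two_conditions" or "target_with_secondaries".
#' @slot targetTrait column of the phenotype matrix being predicted.
#' @slot secondaryTraits columns observed alongside the target.
#' @export
setClass("SchemeSpec",
  representation(scheme = "character", analysis = "character",
                 targetTrait = "character", secondaryTraits = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@scheme %in% c("UV_CV1", "MV_CV1", "MV_CV2"))
      msg <- c(msg, "unknown scheme")
    if (!object@analysis %in% c("same_trait_two_conditions", "target_with_secondaries"))
      msg <- c(msg, "unknown analysis")
    if (identical(object@scheme, "UV_CV1") && length(object@secondaryTraits))
      msg <- c(msg, "UV_CV1 takes no secondary traits")
    if (identical(object@scheme, "MV_CV2") && !length(object@secondaryTraits))
      msg <- c(msg, "MV_CV2 needs at least one secondary trait observed on the VP")
    if (length(msg)) msg else TRUE
  }
)
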