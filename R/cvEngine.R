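## Cross-validation engine: repeated k-fold plans, the CV1/CV2 masking
## schemes, accuracy computation and aggregation, Duncan multiple-range
## letters and Fisher z comparisons.

#' Build a repeated k-fold plan over the panel
#'
#' Each repeat partitions the genotypes into folds whose sizes differ by
#' at most one, without stratification; deterministic given the seed.
#'
#' @param genotypeIds character vector of panel IDs.
#' @param seed integer seed.
#' @param nFolds folds per repeat (default 5).
#' @param nRepeats repeats (default 10).
#' @return A \code{FoldPlan}.
#' @export
makeFolds <- function(genotypeIds, seed, nFolds = 5L, nRepeats = 10L) {
  n <- length(genotypeIds)
  if (n < nFolds) stopf("need at least %d genotypes for %d folds", nFolds, nFolds)
  if (anyDuplicated(genotypeIds)) stopf("duplicated genotype IDs in fold plan")
  out <- vector("list", nRepeats)
  for (rep in seq_len(nRepeats)) {
    set.seed(childSeed(seed, "folds", rep))
    perm <- sample(genotypeIds)
    fold <- integer(n) # fold sizes differ by at most one

    fold[match(perm, genotypeIds)] <- rep_len(seq_len(nFolds), n)
    out[[rep]] <- data.frame(repeatIdx = rep, genotype = genotypeIds,
                             fold = fold, stringsAsFactors = FALSE)
  }
  new("FoldPlan", assignments = do.call(rbind, out),
      nFolds = as.integer(nFolds), nRepeats = as.integer(nRepeats),
      seed = as.integer(seed))
}

#' Describe one cross-validation scheme
#'
#' @param scheme \code{"UV_CV1"}, \code{"MV_CV1"} or \code{"MV_CV2"}.
#' @param analysis \code{"same_trait_two_conditions"} (the secondary is
#'   the same trait under the other condition) or
#'   \code{"target_with_secondaries"} (the secondaries are the most
#'   genetically correlated traits).
#' @param targetTrait column of the phenotype matrix to predict.
#' @param secondaryTraits columns observed alongside the target (empty for
#'   UV_CV1).
#' @return A \code{SchemeSpec}.
#' @export
schemeSpec <- function(scheme, analysis, targetTrait,
                       secondaryTraits = character()) {
  new("SchemeSpec", scheme = scheme, analysis = analysis,
      targetTrait = targetTrait,
      secondaryTraits = as.character(secondaryTraits))
}

#' Materialize the phenotype mask for one repeat and fold
#'
#' Scheme semantics: under UV_CV1 the target trait is hidden on the
#' validation fold; under MV_CV1 every modeled trait is hidden on the
#' validation fold; under MV_CV2 only the target is hidden on the
#' validation fold while the secondary traits stay visible everywhere
#' (cells that were never measured simply remain missing).
#'
#' @param plan a \code{FoldPlan}.
#' @param repeatIdx,fold which cell of the plan.
#' @param spec a \code{SchemeSpec}.
#' @param pheno genotype x trait matrix holding the modeled traits
#'   (target plus secondaries).
#' @return A \code{MaskedPhenotypes}.
#' @export
buildMask <- function(plan, repeatIdx, fold, spec, pheno) {
  stopifnot(is(plan, "FoldPlan"), is(spec, "SchemeSpec"))
  pheno <- as.matrix(pheno)
  if (!spec@targetTrait %in% colnames(pheno))
    stopf("target trait '%s' not in phenotype matrix", spec@targetTrait)
  if (!all(spec@secondaryTraits %in% colnames(pheno)))
    stopf("secondary traits missing from phenotype matrix")
  a <- plan@assignments
  vp <- a$genotype[a$repeatIdx == repeatIdx & a$fold == fold]
  if (!length(vp)) stopf("empty validation fold (repeat %d, fold %d)", repeatIdx, fold)
  mask <- matrix(TRUE, nrow(pheno), ncol(pheno), dimnames = dimnames(pheno))
  vpRows <- rownames(pheno) %in% vp
  if (spec@scheme == "UV_CV1") {
    mask[vpRows, spec@targetTrait] <- FALSE
  } else if (spec@scheme == "MV_CV1") {
    mask[vpRows, ] <- FALSE
  } else { # MV_CV2
    mask[vpRows, spec@targetTrait] <- FALSE
  }
  maskedPhenotypes(pheno, mask)
}

modelSchemeCompatible <- function(model, scheme) {
  switch(model,
         UV_GBLUP = scheme == "UV_CV1",
         RF = scheme == "MV_CV1",
         MV_GBLUP = , BRR = , SpikeSlab = , RKHS = scheme %in% c("MV_CV1", "MV_CV2"),
         FALSE)
}

fitAndPredictCell <- function(model, mp, spec, K, gm, gibbsCfg, rfCfg, vp) {
  target <- spec@targetTrait
  if (model == "UV_GBLUP") {
    v <- observedValues(mp)[, target]
    fit <- fitUvGblup(setNames(v, rownames(mp@values)), K)
    return(gebv(fit)[vp])
  }
  cols <- unique(c(target, spec@secondaryTraits))
  mpSub <- maskedPhenotypes(mp@values[, cols, drop = FALSE],
                            mp@mask[, cols, drop = FALSE])
  if (model == "MV_GBLUP") {
    ## fold-level fits use a looser convergence tolerance: the variance
    ## parameters only enter the accuracy through the GEBV ranking, which
    ## is insensitive to their last digits
    fit <- suppressWarnings(fitMvGblup(mpSub, K, tol = 1e-6, maxIter = 500L,
                                       polish = "never"))
    return(gebv(fit)[vp, target])
  }
  if (model == "BRR") {
    fit <- fitMtBRR(mpSub, gm, gibbsCfg)
    return(gebv(fit)[vp, target])
  }
  if (model == "SpikeSlab") {
    fit <- fitMtSpikeSlab(mpSub, gm, gibbsCfg)
    return(gebv(fit)[vp, target])
  }
  if (model == "RKHS") {
    fit <- fitMtRKHS(mpSub, K, gibbsCfg)
    return(gebv(fit)[vp, target])
  }
  if (model == "RF") {
    v <- observedValues(mpSub)
    tp <- rownames(v)[complete.cases(v)]
    fit <- tuneAndFitRF(v[tp, , drop = FALSE], gm, rfCfg)
    pred <- predictRF(fit, genotypeMatrix(dosages(gm)[vp, , drop = FALSE],
                                          "recoded_pm1"))
    return(pred[, target])
  }
  stopf("unknown model '%s'", model)
}

#' Run a cross-validation experiment for a set of prediction models
#'
#' For every repeat x fold of the plan: build the scheme's mask, fit each
#' requested model on the visible phenotypes, predict the validation
#' genotypes and score the Pearson correlation against their held-out
#' adjusted means. Models incompatible with the scheme (e.g. the random
#' forest under CV2, which cannot handle missing responses) are skipped
#' with a log message, and every cell derives its own seed from the master
#' seed, so reruns are exactly reproducible.
#'
#' @param models character vector among \code{"UV_GBLUP"},
#'   \code{"MV_GBLUP"}, \code{"BRR"}, \code{"SpikeSlab"}, \code{"RKHS"},
#'   \code{"RF"}.
#' @param spec a \code{SchemeSpec}.
#' @param pheno genotype x trait matrix of adjusted means (rownames must
#'   match the kinship matrix).
#' @param K a \code{KinshipSet} (kernels required if RKHS is requested).
#' @param gm complete recoded \code{GenotypeMatrix} (required for BRR,
#'   SpikeSlab, RF).
#' @param plan a \code{FoldPlan} (shared across models so comparisons are
#'   paired).
#' @param masterSeed seed from which per-cell chain seeds are derived.
#' @param gibbsCfg a \code{GibbsConfig} template for the Bayesian models.
#' @param rfCfg an \code{RfConfig} template for the forest.
#' @return Long-format data.frame: model, scheme, analysis, target,
#'   repeatIdx, fold, accuracy, nVp.
#' @export
runExperiment <- function(models, spec, pheno, K, gm = NULL, plan,
                          masterSeed = 1L, gibbsCfg = gibbsConfig(),
                          rfCfg = rfConfig()) {
  stopifnot(is(spec, "SchemeSpec"), is(plan, "FoldPlan"))
  pheno <- as.matrix(pheno)
  run <- expand.grid(repeatIdx = seq_len(plan@nRepeats),
                     fold = seq_len(plan@nFolds), KEEP.OUT.ATTRS = FALSE)
  res <- list()
  for (model in models) {
    if (!modelSchemeCompatible(model, spec@scheme)) {
      message(sprintf("runExperiment: model %s not run under %s (incompatible scheme)",
                      model, spec@scheme))
      next
    }
    for (i in seq_len(nrow(run))) {
      rep <- run$repeatIdx[i]; fold <- run$fold[i]
      mp <- buildMask(plan, rep, fold, spec, pheno)
      a <- plan@assignments
      vp <- a$genotype[a$repeatIdx == rep & a$fold == fold]
      cellSeed <- childSeed(masterSeed, model, spec@scheme, rep, fold)
      gc2 <- gibbsCfg; gc2@seed <- cellSeed
      rc2 <- rfCfg; rc2@seed <- cellSeed
      pred <- fitAndPredictCell(model, mp, spec, K, gm, gc2, rc2, vp)
      acc <- predictAccuracy(pred, pheno[vp, spec@targetTrait])
      res[[length(res) + 1L]] <- data.frame(
        model = model, scheme = spec@scheme, analysis = spec@analysis,
        target = spec@targetTrait, repeatIdx = rep, fold = fold,
        accuracy = acc, nVp = length(vp), stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(data.frame())
  do.call(rbind, res)
}

#' Aggregate per-cell accuracies
#'
#' Mean and standard error (sd over the fold x repeat cells divided by
#' the square root of their count) per model; undefined accuracies are
#' excluded with a note in the \code{nExcluded} column.
#'
#' @param results long-format output of \code{\link{runExperiment}} (rows
#'   from several calls may be concatenated).
#' @return data.frame: model, scheme, target, mean, SE, n, nExcluded.
#' @export
summarizeCV <- function(results) {
  sp <- split(results, list(results$model, results$scheme, results$target),
              drop = TRUE)
  out <- lapply(sp, function(d) {
    v <- d$accuracy
    ok <- is.finite(v)
    data.frame(model = d$model[1], scheme = d$scheme[1], target = d$target[1],
               mean = mean(v[ok]), SE = sd(v[ok]) / sqrt(sum(ok)),
               n = sum(ok), nExcluded = sum(!ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Duncan's multiple range test with letter groupings
#'
#' One-way ANOVA across the groups followed by the stepwise
#' studentized-range procedure at the protection levels
#' 1 - (1 - alpha)^(p - 1): two means p ranks apart differ when their
#' difference exceeds the least significant range
#' \code{qtukey((1-alpha)^(p-1), p, df) * sqrt(MSE / r)}. Groups sharing a
#' letter are not significantly different. With zero residual variance,
#' means are compared exactly and identical means share a letter.
#'
#' @param cellValues named list: group label -> numeric vector of equal
#'   length (e.g. model -> 50 fold x repeat accuracies).
#' @param alpha significance level (default 0.05).
#' @return data.frame: group, mean, letters, ordered by decreasing mean.
#' @export
duncanTest <- function(cellValues, alpha = 0.05) {
  stopifnot(is.list(cellValues), length(cellValues) >= 2L,
            !is.null(names(cellValues)))
  cellValues <- lapply(cellValues, function(v) v[is.finite(v)])
  r <- unique(lengths(cellValues))
  if (length(r) != 1L)
    stopf("Duncan's test requires equal replication per group (got %s)",
          paste(lengths(cellValues), collapse = ", "))
  k <- length(cellValues)
  means <- vapply(cellValues, mean, numeric(1))
  N <- k * r
  mse <- sum(vapply(cellValues, function(v) sum((v - mean(v))^2), numeric(1))) /
    (N - k)
  ord <- order(-means)
  m <- means[ord]
  different <- function(i, j) { # i < j on the ordered scale
    p <- j - i + 1L
    if (mse <= 0) return(m[i] != m[j])
    Rp <- qtukey((1 - alpha)^(p - 1), p, N - k) * sqrt(mse / r)
    (m[i] - m[j]) > Rp
  }
  ## maximal non-significant ranges -> letters
  ranges <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !different(i, j + 1L)) j <- j + 1L
    ranges[[i]] <- c(i, j)
  }
  keep <- rep(TRUE, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j && keep[i] &&
        ranges[[j]][1] <= ranges[[i]][1] && ranges[[i]][2] <= ranges[[j]][2] &&
        !(ranges[[j]][1] == ranges[[i]][1] && ranges[[j]][2] == ranges[[i]][2]))
      keep[i] <- FALSE
  }
  uniq <- unique(ranges[keep])
  letters <- character(k)
  for (g in seq_along(uniq)) {
    span <- uniq[[g]]
    for (i in span[1]:span[2])
      letters[i] <- paste0(letters[i], base::letters[g])
  }
  data.frame(group = names(m), mean = unname(m), letters = letters,
             stringsAsFactors = FALSE)
}

#' Fisher z comparison of two correlations
#'
#' Tests whether two independent Pearson correlations differ:
#' z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3)), two-sided
#' normal p-value.
#'
#' @param r1,r2 the two correlations (|r| < 1).
#' @param n1,n2 the sample sizes behind them (> 3).
#' @return list with elements z and p.
#' @export
fisherCompare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stopf("Fisher z transform is infinite at |r| = 1")
  if (n1 <= 3 || n2 <= 3) stopf("Fisher comparison needs n > 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Percent improvement of one accuracy over a baseline
#'
#' @param paMv accuracy of the multivariate scheme.
#' @param paUv baseline accuracy.
#' @return 100 * (paMv - paUv) / paUv; NA with a warning for a zero
#'   baseline.
#' @export
percentImprovement <- function(paMv, paUv) {
  if (any(paUv == 0)) {
    warnf("zero baseline accuracy; percent improvement undefined")
    return(ifelse(paUv == 0, NA_real_, 100 * (paMv - paUv) / paUv))
  }
  100 * (paMv - paUv) / paUv
}
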