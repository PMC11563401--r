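## Multivariate random forest with inner grid-search tuning. Used only
## under CV1-style schemes: the training phenotypes must be complete.

#' Configure the multivariate random forest
#'
#' @param nTreesGrid,mtryGrid,minNodeGrid hyperparameter grids; defaults
#'   \{100, 200, 300\}, \{80, 100, 120\} and \{3, 6, 9\}.
#' @param innerFolds inner cross-validation folds for tuning (default 5).
#' @param seed integer seed.
#' @return An \code{RfConfig}.
#' @export
rfConfig <- function(nTreesGrid = c(100L, 200L, 300L),
                     mtryGrid = c(80L, 100L, 120L),
                     minNodeGrid = c(3L, 6L, 9L),
                     innerFolds = 5L, seed = 1L) {
  new("RfConfig", nTreesGrid = as.integer(nTreesGrid),
      mtryGrid = as.integer(mtryGrid), minNodeGrid = as.integer(minNodeGrid),
      innerFolds = as.integer(innerFolds), seed = as.integer(seed))
}

rfDesign <- function(gm, ids = NULL) {
  stopifnot(is(gm, "GenotypeMatrix"))
  if (!identical(codingState(gm), "recoded_pm1"))
    stopf("random forest needs a recoded (-1/0/+1) genotype matrix")
  d <- dosages(gm)
  if (anyNA(d)) stopf("genotype matrix must be complete; call imputeMean() first")
  if (!is.null(ids)) d <- d[ids, , drop = FALSE]
  d
}

#' Tune and fit the multivariate random forest
#'
#' For every grid point, inner k-fold cross-validation on the training
#' set scores the mean across traits of the variance-normalized squared
#' prediction error; the best grid point (ties resolved in canonical grid
#' order) is refit on the full training set. Each tree grows on a
#' bootstrap sample; at every node \code{mtry} candidate markers are
#' scored by the multivariate criterion (summed per-trait
#' sum-of-squares reduction, each normalized by the node's sum of squares
#' for that trait) and splitting stops when a child would fall below the
#' minimum node size. Masked training phenotypes are an error: the forest
#' cannot digest missing responses, which is why it runs under CV1 only.
#'
#' @param Y complete genotype x trait matrix of training phenotypes, or a
#'   \code{MaskedPhenotypes} whose visible part is complete on the
#'   training rows.
#' @param gm complete \code{GenotypeMatrix} (\code{"recoded_pm1"}).
#' @param cfg an \code{RfConfig}.
#' @return An \code{RfFit}.
#' @export
tuneAndFitRF <- function(Y, gm, cfg = rfConfig()) {
  if (is(Y, "MaskedPhenotypes")) Y <- observedValues(Y)
  Y <- as.matrix(Y)
  if (anyNA(Y))
    stopf("random forest training phenotypes contain masked/missing values; use it under MV-CV1 (complete training set) only")
  X <- rfDesign(gm, rownames(Y))
  if (max(cfg@mtryGrid) > ncol(X))
    stopf("mtry grid exceeds marker count (%d markers)", ncol(X))
  n <- nrow(X)
  grid <- expand.grid(nTrees = cfg@nTreesGrid, mtry = cfg@mtryGrid,
                      minNode = cfg@minNodeGrid, KEEP.OUT.ATTRS = FALSE)
  vT <- apply(Y, 2, var)
  vT[vT <= 0] <- 1
  scores <- rep(NA_real_, nrow(grid))
  if (nrow(grid) > 1L) {
    set.seed(childSeed(cfg@seed, "rf", "innercv"))
    foldId <- sample(rep_len(seq_len(cfg@innerFolds), n))
    for (g in seq_len(nrow(grid))) {
      err <- 0; cnt <- 0
      for (f in seq_len(cfg@innerFolds)) {
        tr <- which(foldId != f); te <- which(foldId == f)
        if (length(tr) < 2L || !length(te)) next
        set.seed(childSeed(cfg@seed, "rf", "grid", g, "fold", f))
        trees <- .mvrfGrow(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                           grid$nTrees[g], grid$mtry[g], grid$minNode[g],
                           0L, TRUE)
        pred <- .mvrfPredict(trees, X[te, , drop = FALSE], ncol(Y))
        err <- err + sum(sweep((Y[te, , drop = FALSE] - pred)^2, 2, vT, "/"))
        cnt <- cnt + length(te) * ncol(Y)
      }
      scores[g] <- err / cnt
    }
    best <- which.min(scores) # ties: first in canonical grid order
  } else best <- 1L
  set.seed(childSeed(cfg@seed, "rf", "final"))
  trees <- .mvrfGrow(X, Y, grid$nTrees[best], grid$mtry[best],
                     grid$minNode[best], 0L, TRUE)
  pred <- .mvrfPredict(trees, X, ncol(Y))
  dimnames(pred) <- dimnames(Y)
  new("RfFit",
      chosen = c(nTrees = grid$nTrees[best], mtry = grid$mtry[best],
                 minNode = grid$minNode[best]),
      forest = trees, predictions = pred, markerIds = colnames(X),
      tuningTable = cbind(grid, score = scores))
}

#' Predict with a fitted multivariate random forest
#'
#' Averages the per-tree terminal-node means for each new genotype. The
#' marker set must match the one the forest was grown on.
#'
#' @param fit an \code{RfFit}.
#' @param gmNew a complete \code{GenotypeMatrix} (\code{"recoded_pm1"}) or
#'   bare dosage matrix with the training markers as columns.
#' @return genotype x trait prediction matrix.
#' @export
predictRF <- function(fit, gmNew) {
  stopifnot(is(fit, "RfFit"))
  Xn <- if (is(gmNew, "GenotypeMatrix")) rfDesign(gmNew) else as.matrix(gmNew)
  missing <- setdiff(fit@markerIds, colnames(Xn))
  if (length(missing))
    stopf("markers missing from prediction input: %s%s",
          paste(head(missing, 5), collapse = ", "),
          if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5) else "")
  Xn <- Xn[, fit@markerIds, drop = FALSE]
  out <- .mvrfPredict(fit@forest, Xn, ncol(fit@predictions))
  dimnames(out) <- list(rownames(Xn), colnames(fit@predictions))
  out
}

## single deterministic tree without bootstrap/depth limits; exposed for
## exact small-case checks
growSingleTree <- function(X, Y, mtry = ncol(X), minNode = 1L) {
  .mvrfGrow(as.matrix(X), as.matrix(Y), 1L, as.integer(mtry),
            as.integer(minNode), 0L, FALSE)
}
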