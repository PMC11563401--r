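## Genomic genetic (co)variance and correlation between trait pairs, and
## selection of the traits most genetically correlated with a target.

#' Estimate the genetic covariance and correlation of a trait pair
#'
#' Fits a bivariate genomic mixed model with genetic covariance
#' Sigma_g \%x\% G and residual Sigma_e \%x\% I. The default estimator is
#' the multivariate REML core (with an unstructured residual covariance,
#' since adjusted means of two traits measured on the same plots share
#' non-genetic variation); alternatively a Bayesian kernel regression on G
#' can be used, reporting posterior means.
#'
#' @param eblues genotype x 2 matrix (or data.frame) of adjusted means,
#'   rownames = genotype IDs matching the kinship matrix.
#' @param K a \code{KinshipSet} or bare GRM.
#' @param estimator \code{"reml"} (default) or \code{"gibbs"}.
#' @param cfg a \code{GibbsConfig}, used when \code{estimator = "gibbs"}.
#' @return A \code{GeneticParams}.
#' @export
estimateGeneticCovariance <- function(eblues, K,
                                      estimator = c("reml", "gibbs"),
                                      cfg = gibbsConfig()) {
  estimator <- match.arg(estimator)
  Y <- as.matrix(eblues)
  if (ncol(Y) != 2L) stopf("expected exactly 2 traits, got %d", ncol(Y))
  if (is.null(colnames(Y))) colnames(Y) <- c("trait1", "trait2")
  Y <- Y[complete.cases(Y), , drop = FALSE]
  G <- if (is(K, "KinshipSet")) grm(K) else K
  if (estimator == "reml") {
    fit <- fitMvGblup(maskedPhenotypes(Y), G[rownames(Y), rownames(Y)],
                      residual = "unstructured", polish = "never")
    Sg <- fit@HHat; Se <- fit@RHat
  } else {
    Gs <- G[rownames(Y), rownames(Y)]
    ks1 <- new("KinshipSet", G = Gs, kernels = list(Gs / max(Gs)),
               bandwidths = NA_real_, markerCountUsed = 0L)
    fit <- fitMtRKHS(maskedPhenotypes(Y), ks1, cfg)
    Sg <- fit@effects$SigmaK[[1]]; Se <- fit@R0Hat
    dimnames(Sg) <- dimnames(Se) <- list(colnames(Y), colnames(Y))
  }
  if (!isPSD(Sg)) {
    warnf("genetic covariance estimate not PSD; bent")
    Sg <- bendPSD(Sg, floor = 0, jitter = 1e-10)
  }
  rho <- Sg[1, 2] / sqrt(Sg[1, 1] * Sg[2, 2])
  rho <- min(max(rho, -1), 1)
  new("GeneticParams", traits = colnames(Y), SigmaG = Sg, SigmaE = Se,
      rhoG = rho, estimator = estimator)
}

#' Select the traits most genetically correlated with a target
#'
#' Orders candidates by absolute genetic correlation with the target
#' (strong negative correlations are as informative for multivariate
#' prediction as positive ones) after removing the target itself and any
#' excluded traits (typically derivative indices of the target). Ties are
#' broken alphabetically, so selection is deterministic.
#'
#' @param rhoG named numeric vector of genetic correlations with the
#'   target trait.
#' @param target name of the target trait (removed from candidates).
#' @param k number of traits to return (default 5).
#' @param exclude character vector of trait names to exclude.
#' @return Character vector of up to k trait names, strongest correlation
#'   first.
#' @export
selectTopCorrelated <- function(rhoG, target, k = 5L, exclude = character()) {
  stopifnot(!is.null(names(rhoG)))
  cand <- rhoG[!(names(rhoG) %in% c(target, exclude))]
  cand <- cand[!is.na(cand)]
  if (length(cand) < k) {
    warnf("only %d candidate traits available (k = %d); returning all",
          length(cand), k)
    k <- length(cand)
  }
  ord <- order(-abs(cand), names(cand))
  names(cand)[ord][seq_len(k)]
}
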