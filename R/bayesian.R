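## Multitrait Bayesian whole-genome regressions by Gibbs sampling: ridge
## (BRR), spike-and-slab, and RKHS kernel regression, all with
## missing-phenotype augmentation. Missing cells are imputed from their
## conditional normal each iteration, which is what lets these models run
## under the CV2 masking schemes.

#' Configure the Gibbs sampler
#'
#' @param nIter total iterations (default 12000).
#' @param burnIn discarded iterations (default 2000).
#' @param thin keep every thin-th sample (default 5).
#' @param seed chain seed.
#' @param dfPrior degrees of freedom added to t for the inverse-Wishart
#'   priors on the effect and residual covariances (default 3, weakly
#'   informative).
#' @param scaleSplit fraction of the empirical phenotypic variance
#'   assigned to the genetic side of the prior scales (default 0.5).
#' @param inclusionBeta Beta prior shape parameters on the spike-and-slab
#'   inclusion probability per trait (default c(1, 4): prior mean 0.2).
#' @return A \code{GibbsConfig}.
#' @export
gibbsConfig <- function(nIter = 12000L, burnIn = 2000L, thin = 5L, seed = 1L,
                        dfPrior = 3, scaleSplit = 0.5,
                        inclusionBeta = c(1, 4)) {
  new("GibbsConfig", nIter = as.integer(nIter), burnIn = as.integer(burnIn),
      thin = as.integer(thin), seed = as.integer(seed), dfPrior = dfPrior,
      scaleSplit = scaleSplit, inclusionBeta = as.numeric(inclusionBeta))
}

## inverse-Wishart draw via rWishart on the inverse scale
riwish <- function(df, S) {
  Sinv <- chol2inv(chol((S + t(S)) / 2))
  W <- stats::rWishart(1, df, (Sinv + t(Sinv)) / 2)[, , 1]
  chol2inv(chol((W + t(W)) / 2))
}

## shared setup: visible phenotype matrix, missing-pattern cache, start values
prepPhenotypes <- function(Y) {
  stopifnot(is(Y, "MaskedPhenotypes"))
  V <- observedValues(Y)
  obsM <- !is.na(V)
  mu0 <- vapply(seq_len(ncol(V)), function(s) mean(V[obsM[, s], s]), numeric(1))
  Ycur <- V
  for (s in seq_len(ncol(V))) Ycur[!obsM[, s], s] <- mu0[s]
  pat <- apply(obsM, 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(nrow(V)), pat)
  groups <- groups[vapply(groups, function(ix) any(!obsM[ix[1], ]), logical(1))]
  v <- vapply(seq_len(ncol(V)), function(s) var(V[obsM[, s], s]), numeric(1))
  list(V = V, obsM = obsM, Ycur = Ycur, mu0 = mu0, groups = groups, varP = v)
}

## one conditional-normal imputation pass over the cached missing patterns
imputeMissing <- function(Ycur, Eta, R0, prep) {
  for (ix in prep$groups) {
    o <- which(prep$obsM[ix[1], ])
    m <- which(!prep$obsM[ix[1], ])
    if (!length(m)) next
    if (length(o)) {
      Roo <- R0[o, o, drop = FALSE]
      Rmo <- R0[m, o, drop = FALSE]
      W <- Rmo %*% chol2inv(chol(Roo))
      condVar <- R0[m, m, drop = FALSE] - W %*% t(Rmo)
      resid <- prep$V[ix, o, drop = FALSE] - Eta[ix, o, drop = FALSE]
      mean <- Eta[ix, m, drop = FALSE] + resid %*% t(W)
    } else {
      condVar <- R0[m, m, drop = FALSE]
      mean <- Eta[ix, m, drop = FALSE]
    }
    cl <- chol((condVar + t(condVar)) / 2 + diag(1e-12, length(m)))
    Z <- matrix(rnorm(length(ix) * length(m)), length(ix), length(m))
    Ycur[ix, m] <- mean + Z %*% cl
  }
  Ycur
}

markerDesign <- function(gm) {
  stopifnot(is(gm, "GenotypeMatrix"))
  if (!identical(codingState(gm), "recoded_pm1"))
    stopf("Bayesian regressions need a recoded (-1/0/+1) genotype matrix")
  d <- dosages(gm)
  if (anyNA(d)) stopf("genotype matrix must be complete; call imputeMean() first")
  sweep(d, 2, colMeans(d))
}

## common Gibbs driver for the marker-based models (BRR / SpikeSlab)
runMarkerGibbs <- function(Y, gm, cfg, model, fixSigmaB = NULL, fixR0 = NULL,
                           priorScaleMult = 1) {
  X <- markerDesign(gm)
  prep <- prepPhenotypes(Y)
  if (!identical(rownames(prep$V), rownames(X)))
    stopf("phenotype rows must match genotype rows")
  n <- nrow(X); m <- ncol(X); t <- ncol(prep$V)
  xtx <- colSums(X^2)
  msx <- sum(xtx) / n # total marker variance, for prior scaling
  dfB <- t + cfg@dfPrior; dfR <- t + cfg@dfPrior
  Sp <- diag(prep$varP, t)
  SBscale <- max(dfB - t - 1, 0.5) * cfg@scaleSplit * Sp / max(msx, 1e-12) *
    priorScaleMult
  SRscale <- max(dfR - t - 1, 0.5) * (1 - cfg@scaleSplit) * Sp
  set.seed(cfg@seed)
  mu <- prep$mu0
  B <- matrix(0, m, t)
  delta <- matrix(1L, m, t)
  SigmaB <- if (!is.null(fixSigmaB)) as.matrix(fixSigmaB) else
    SBscale / max(dfB - t - 1, 0.5)
  R0 <- if (!is.null(fixR0)) as.matrix(fixR0) else diag(prep$varP / 2, t)
  slabVar <- pmax(diag(SigmaB), 1e-10)
  piIncl <- rep(cfg@inclusionBeta[1] / sum(cfg@inclusionBeta), t)
  nu0 <- 5 # slab-variance prior df (spike-and-slab only)
  s0 <- diag(SBscale) / max(dfB - t - 1, 0.5) * 2 # prior mean of slab variance
  Ycur <- prep$Ycur
  keep <- 0L
  accG <- matrix(0, n, t); accB <- matrix(0, m, t); accR <- matrix(0, t, t)
  accMu <- numeric(t); accD <- matrix(0, m, t); accPi <- numeric(t)
  for (it in seq_len(cfg@nIter)) {
    XB <- X %*% B
    ## trait intercepts
    Ebar <- colMeans(Ycur - XB)
    clR <- chol((R0 + t(R0)) / 2)
    mu <- Ebar + drop(rnorm(t) %*% clR) / sqrt(n)
    E <- Ycur - matrix(mu, n, t, byrow = TRUE) - XB
    R0inv <- chol2inv(chol(R0))
    if (model == "BRR") {
      SigmaBinv <- chol2inv(chol(SigmaB + diag(1e-12, t)))
      sw <- .brrSweep(E, X, B, R0inv, SigmaBinv, xtx)
      E <- sw$E; B <- sw$B
      if (is.null(fixSigmaB))
        SigmaB <- riwish(dfB + m, SBscale + crossprod(B))
    } else {
      logitPi <- log(piIncl / (1 - piIncl))
      sw <- .ssSweep(E, X, B, delta, R0inv, slabVar, logitPi, xtx)
      E <- sw$E; B <- sw$B; delta <- sw$delta
      kIncl <- colSums(delta)
      for (s in seq_len(t)) {
        ssb <- sum(B[delta[, s] == 1L, s]^2)
        slabVar[s] <- (nu0 * s0[s] + ssb) / rchisq(1, nu0 + kIncl[s])
        piIncl[s] <- rbeta(1, cfg@inclusionBeta[1] + kIncl[s],
                           cfg@inclusionBeta[2] + m - kIncl[s])
        piIncl[s] <- min(max(piIncl[s], 1e-6), 1 - 1e-6)
      }
    }
    if (is.null(fixR0)) {
      R0 <- riwish(dfR + n, SRscale + crossprod(E))
    }
    Eta <- matrix(mu, n, t, byrow = TRUE) + X %*% B
    if (length(prep$groups)) Ycur <- imputeMissing(Ycur, Eta, R0, prep)
    if (it > cfg@burnIn && ((it - cfg@burnIn) %% cfg@thin == 0L)) {
      keep <- keep + 1L
      accG <- accG + X %*% B
      accB <- accB + B
      accR <- accR + R0
      accMu <- accMu + mu
      if (model == "SpikeSlab") { accD <- accD + delta; accPi <- accPi + piIncl }
    }
  }
  if (!keep) stopf("no posterior samples kept; check nIter/burnIn/thin")
  gebv <- accG / keep
  dimnames(gebv) <- dimnames(prep$V)
  Bm <- accB / keep
  dimnames(Bm) <- list(colnames(X), colnames(prep$V))
  R0m <- accR / keep
  dimnames(R0m) <- list(colnames(prep$V), colnames(prep$V))
  incl <- if (model == "SpikeSlab") {
    dm <- accD / keep
    dimnames(dm) <- dimnames(Bm)
    dm
  } else matrix(numeric(0), 0, 0)
  new("MtBayesFit", model = model, posteriorMeanGebv = gebv, effects = Bm,
      R0Hat = R0m, inclusionProbs = incl,
      mu = setNames(accMu / keep, colnames(prep$V)), chainSeed = cfg@seed)
}

#' Multitrait Bayesian ridge regression (BRR)
#'
#' Data model: Y = 1 mu' + X B + E with rows of E multivariate normal
#' N(0, R0) (R0 unstructured) and rows of B sharing a common effect
#' covariance with an inverse-Wishart prior. The Gibbs cycle samples trait
#' intercepts, marker-effect rows from their multivariate-normal full
#' conditionals, the effect covariance, R0, and imputes masked phenotype
#' cells from their conditional normal. GEBVs are the posterior mean of
#' X B. Chains are deterministic given \code{cfg@seed}.
#'
#' @param Y a \code{MaskedPhenotypes}.
#' @param gm complete \code{GenotypeMatrix} in \code{"recoded_pm1"} coding.
#' @param cfg a \code{GibbsConfig}.
#' @param fixSigmaB optional fixed effect-covariance matrix (skips its
#'   update; used for ridge-equivalence checks).
#' @param fixR0 optional fixed residual covariance.
#' @param priorScaleMult multiplier on the effect-covariance prior scale
#'   (1 = default calibration).
#' @return An \code{MtBayesFit}.
#' @export
fitMtBRR <- function(Y, gm, cfg = gibbsConfig(), fixSigmaB = NULL,
                     fixR0 = NULL, priorScaleMult = 1) {
  runMarkerGibbs(Y, gm, cfg, "BRR", fixSigmaB, fixR0, priorScaleMult)
}

#' Multitrait spike-and-slab regression
#'
#' As \code{\link{fitMtBRR}} but every marker x trait effect carries a
#' Bernoulli inclusion indicator with a trait-specific inclusion
#' probability (Beta prior); excluded effects are exactly zero. Posterior
#' inclusion probabilities per marker and trait are reported.
#'
#' @inheritParams fitMtBRR
#' @return An \code{MtBayesFit} with \code{inclusionProbs} filled.
#' @export
fitMtSpikeSlab <- function(Y, gm, cfg = gibbsConfig()) {
  runMarkerGibbs(Y, gm, cfg, "SpikeSlab")
}

#' Multitrait RKHS kernel regression
#'
#' Data model: Y = 1 mu' + U_1 + ... + U_K + E, one random-effect matrix
#' per kernel with covariance Sigma_k \%x\% K_k (a separate trait
#' covariance per kernel, each inverse-Wishart) and unstructured R0.
#' Sampling works in each kernel's eigenbasis, where the full conditional
#' factorizes over eigencomponents. GEBV = posterior mean of the summed
#' kernel effects.
#'
#' @param Y a \code{MaskedPhenotypes}.
#' @param K a \code{KinshipSet} whose kernels slot holds the kernel
#'   matrices (typically three bandwidths).
#' @param cfg a \code{GibbsConfig}.
#' @return An \code{MtBayesFit}; \code{effects} is a list with posterior
#'   mean kernel effects \code{U} and trait covariances \code{SigmaK}.
#' @export
fitMtRKHS <- function(Y, K, cfg = gibbsConfig()) {
  stopifnot(is(K, "KinshipSet"))
  kernels <- kernelMatrices(K)
  if (!length(kernels)) stopf("KinshipSet carries no kernels; run computeKernels()")
  prep <- prepPhenotypes(Y)
  n <- nrow(prep$V); t <- ncol(prep$V); nk <- length(kernels)
  eig <- lapply(kernels, function(Km) {
    e <- eigen((Km + t(Km)) / 2, symmetric = TRUE)
    keepEv <- e$values > 1e-8 * max(e$values)
    list(V = e$vectors[, keepEv, drop = FALSE], d = e$values[keepEv])
  })
  dfK <- t + cfg@dfPrior; dfR <- t + cfg@dfPrior
  Sp <- diag(prep$varP, t)
  SKscale <- max(dfK - t - 1, 0.5) * cfg@scaleSplit * Sp / nk
  SRscale <- max(dfR - t - 1, 0.5) * (1 - cfg@scaleSplit) * Sp
  set.seed(cfg@seed)
  mu <- prep$mu0
  U <- lapply(seq_len(nk), function(k) matrix(0, n, t))
  SigmaK <- lapply(seq_len(nk), function(k) SKscale / max(dfK - t - 1, 0.5))
  R0 <- diag(prep$varP / 2, t)
  Ycur <- prep$Ycur
  keep <- 0L
  accG <- matrix(0, n, t); accR <- matrix(0, t, t); accMu <- numeric(t)
  accU <- lapply(seq_len(nk), function(k) matrix(0, n, t))
  accSK <- lapply(seq_len(nk), function(k) matrix(0, t, t))
  for (it in seq_len(cfg@nIter)) {
    Usum <- Reduce(`+`, U)
    Ebar <- colMeans(Ycur - Usum)
    clR <- chol((R0 + t(R0)) / 2)
    mu <- Ebar + drop(rnorm(t) %*% clR) / sqrt(n)
    R0inv <- chol2inv(chol(R0))
    for (k in seq_len(nk)) {
      Ek <- Ycur - matrix(mu, n, t, byrow = TRUE) - (Usum - U[[k]])
      Etil <- crossprod(eig[[k]]$V, Ek)
      SKinv <- chol2inv(chol(SigmaK[[k]] + diag(1e-12, t)))
      Util <- .rkhsSweep(Etil, eig[[k]]$d, R0inv, SKinv)
      Unew <- eig[[k]]$V %*% Util
      Usum <- Usum - U[[k]] + Unew
      U[[k]] <- Unew
      SigmaK[[k]] <- riwish(dfK + length(eig[[k]]$d),
                            SKscale + crossprod(Util / sqrt(eig[[k]]$d), Util))
    }
    E <- Ycur - matrix(mu, n, t, byrow = TRUE) - Usum
    R0 <- riwish(dfR + n, SRscale + crossprod(E))
    Eta <- matrix(mu, n, t, byrow = TRUE) + Usum
    if (length(prep$groups)) Ycur <- imputeMissing(Ycur, Eta, R0, prep)
    if (it > cfg@burnIn && ((it - cfg@burnIn) %% cfg@thin == 0L)) {
      keep <- keep + 1L
      accG <- accG + Usum
      accR <- accR + R0
      accMu <- accMu + mu
      for (k in seq_len(nk)) {
        accU[[k]] <- accU[[k]] + U[[k]]
        accSK[[k]] <- accSK[[k]] + SigmaK[[k]]
      }
    }
  }
  if (!keep) stopf("no posterior samples kept; check nIter/burnIn/thin")
  gebv <- accG / keep
  dimnames(gebv) <- dimnames(prep$V)
  R0m <- accR / keep
  dimnames(R0m) <- list(colnames(prep$V), colnames(prep$V))
  new("MtBayesFit", model = "RKHS", posteriorMeanGebv = gebv,
      effects = list(U = lapply(accU, function(a) a / keep),
                     SigmaK = lapply(accSK, function(a) a / keep)),
      R0Hat = R0m, inclusionProbs = matrix(numeric(0), 0, 0),
      mu = setNames(accMu / keep, colnames(prep$V)), chainSeed = cfg@seed)
}
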