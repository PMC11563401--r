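# Shared fixtures and independent oracles used across the test files.
# Everything is generated in code; nothing is read from disk.

# a complete, recoded marker panel plus kinships, built from the generator
makePanel <- function(n, m, seed, het = 0.02, freq = c(0.05, 0.5)) {
  cfg <- simConfig(nGenotypes = n, nMarkers = m, traitNames = "T",
                   HTrue = matrix(1, 1, 1, dimnames = list("T", "T")),
                   conditions = "C1", missingGenoRate = 0,
                   selfingHet = het, alleleFreqRange = freq, seed = seed)
  gm <- imputeMean(recodePM1(simulateGenotypes(cfg)))
  list(gm = gm, K = computeKernels(gm), cfg = cfg)
}

# heritable phenotype on the G scale: y = g + e with
# var(e) = meanDiag(G) * (1/h2 - 1) so that sigmaG2/(sigmaG2 + sigmaE2/diagG)
# equals h2 in the GBLUP parameterization
makePheno <- function(panel, h2, seed, HTrue = NULL) {
  G <- grm(panel$K)
  t <- length(h2)
  if (is.null(HTrue)) HTrue <- diag(1, t)
  bv <- simulateBreedingValues(panel$gm, HTrue, seed = seed)
  dg <- mean(diag(G))
  set.seed(seed + 1L)
  noise <- vapply(seq_len(t), function(s)
    rnorm(nrow(G), 0, sqrt(dg * HTrue[s, s] * (1 / h2[s] - 1))), numeric(nrow(G)))
  Y <- bv + noise
  rownames(Y) <- rownames(G)
  colnames(Y) <- colnames(bv)
  list(Y = Y, bv = bv)
}

# independent SNP-BLUP oracle: ridge on marker effects with an intercept,
# solved from the dense mixed-model equations. lambdaM is the ridge on the
# marker effects (sigmaE2/sigmaB2); returns fitted genetic values W %*% a.
snpBlupOracle <- function(y, W, lambdaM) {
  n <- nrow(W); m <- ncol(W)
  X <- cbind(rep(1, n))
  A <- rbind(cbind(crossprod(X), crossprod(X, W)),
             cbind(crossprod(W, X), crossprod(W) + diag(lambdaM, m)))
  b <- c(crossprod(X, y), crossprod(W, y))
  sol <- solve(A, b)
  drop(W %*% sol[-1])
}

# independent brute-force Duncan procedure: all-pairs range comparisons at
# the protection levels, groups formed by the containment rule
bruteDuncan <- function(cellValues, alpha = 0.05) {
  k <- length(cellValues)
  r <- length(cellValues[[1]])
  means <- vapply(cellValues, mean, numeric(1))
  N <- k * r
  mse <- sum(vapply(cellValues, function(v) sum((v - mean(v))^2), numeric(1))) /
    (N - k)
  ord <- order(-means)
  m <- means[ord]
  diffMat <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    p <- j - i + 1
    crit <- if (mse <= 0) 0 else
      qtukey((1 - alpha)^(p - 1), p, N - k) * sqrt(mse / r)
    diffMat[i, j] <- if (mse <= 0) m[i] != m[j] else (m[i] - m[j]) > crit
  }
  ranges <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !diffMat[i, j + 1]) j <- j + 1
    ranges[[i]] <- c(i, j)
  }
  keep <- rep(TRUE, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j && keep[i] &&
        ranges[[j]][1] <= ranges[[i]][1] && ranges[[i]][2] <= ranges[[j]][2] &&
        !identical(ranges[[j]], ranges[[i]]))
      keep[i] <- FALSE
  }
  uniq <- unique(ranges[keep])
  lab <- character(k)
  for (g in seq_along(uniq)) {
    for (i in uniq[[g]][1]:uniq[[g]][2]) lab[i] <- paste0(lab[i], letters[g])
  }
  data.frame(group = names(m), mean = unname(m), letters = lab,
             stringsAsFactors = FALSE)
}

# write a tiny HapMap file from a list of marker call vectors
writeTinyHapmap <- function(calls, sampleIds, path) {
  meta <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
            "center", "protLSID", "assayLSID", "panelLSID", "QCcode")
  lines <- paste(c(meta, sampleIds), collapse = "\t")
  for (i in seq_along(calls)) {
    lines <- c(lines, paste(c(sprintf("m%d", i), "A/T", "1", i, "+",
                              rep("NA", 6), calls[[i]]), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}
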