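## Genotype QC, recoding, imputation, genomic relationship matrix and
## Gaussian kernels.

## minor-allele frequency per marker, from either coding.
## raw01half: dosage = frequency of the major allele in the individual,
## so major-allele frequency = mean(d) and MAF = 1 - mean(d).
## recoded_pm1: minor-allele frequency = mean((d + 1) / 2).
## In both cases the frequency is folded to [0, 0.5] so that filtering is
## meaningful on arbitrary subsets of the panel.
markerMAF <- function(gm) {
  d <- dosages(gm)
  f <- if (identical(codingState(gm), "raw01half")) {
    1 - colMeans(d, na.rm = TRUE)
  } else {
    colMeans((d + 1) / 2, na.rm = TRUE)
  }
  pmin(f, 1 - f)
}

markerMissingness <- function(gm) colMeans(is.na(dosages(gm)))

#' Parse a HapMap-format genotype file
#'
#' Reads the standard tab-delimited HapMap text layout (11 metadata columns
#' followed by one column per sample, diploid two-letter calls, \code{NN}
#' or \code{N} missing) and converts calls to the numeric coding 1 =
#' homozygous major allele, 0.5 = heterozygous, 0 = homozygous minor
#' allele. The major allele of each marker is the one with the higher
#' observed count across the panel; exact ties are broken by alphabetical
#' allele order (the alphabetically first allele is taken as major), so
#' parsing is deterministic.
#'
#' @param path path to the HapMap text file.
#' @return A \code{GenotypeMatrix} in coding state \code{"raw01half"}.
#' @seealso \code{\link{filterMarkers}}, \code{\link{recodePM1}}
#' @export
parseHapmap <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  if (!length(lines)) stopf("empty HapMap file: %s", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 12L)
    stopf("HapMap header needs 11 metadata columns plus >=1 sample, found %d columns",
          length(header))
  sampleIds <- header[-(1:11)]
  dup <- sampleIds[duplicated(sampleIds)]
  if (length(dup)) stopf("duplicated sample ID in HapMap file: %s", dup[[1]])
  nSamp <- length(sampleIds)
  nMark <- length(lines) - 1L
  out <- matrix(NA_real_, nrow = nSamp, ncol = nMark,
                dimnames = list(sampleIds, character(nMark)))
  for (i in seq_len(nMark)) {
    fields <- strsplit(lines[[i + 1L]], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 11L + nSamp)
      stopf("malformed HapMap row at line %d: %d fields, expected %d",
            i + 1L, length(fields), 11L + nSamp)
    colnames(out)[i] <- fields[[1]]
    calls <- toupper(fields[-(1:11)])
    chars <- strsplit(calls, "", fixed = TRUE)
    alleles <- unlist(chars)
    alleles <- alleles[alleles %in% c("A", "C", "G", "T")]
    if (!length(alleles)) next # all-missing marker: retained as NA column
    tab <- sort(table(alleles), decreasing = TRUE)
    cnt <- as.vector(tab); names(cnt) <- names(tab)
    top <- names(cnt)[cnt == max(cnt)]
    major <- sort(top)[[1]] # alphabetical tie-break
    val <- vapply(chars, function(ch) {
      ch <- ch[ch != ""]
      if (length(ch) == 1L) ch <- c(ch, ch) # haploid-style call, treat as hom
      if (any(!ch %in% c("A", "C", "G", "T"))) return(NA_real_)
      mean(ch == major) # 1, 0.5 or 0
    }, numeric(1))
    out[, i] <- val
  }
  if (anyDuplicated(colnames(out)))
    stopf("duplicated marker ID in HapMap file: %s",
          colnames(out)[duplicated(colnames(out))][[1]])
  genotypeMatrix(out, "raw01half")
}

#' Filter markers on minor allele frequency and missingness
#'
#' A marker is kept iff its MAF is at least \code{mafMin} and its missing
#' fraction is at most \code{missingMax}; boundary values are kept. Markers
#' with no observed calls are always removed. The per-rule removal counts
#' are attached as attribute \code{"filterLog"} and reported via
#' \code{message()}.
#'
#' @param gm a \code{GenotypeMatrix} in either coding state.
#' @param mafMin minimum minor allele frequency (default 0.05).
#' @param missingMax maximum missing-call fraction (default 0.20).
#' @return The filtered \code{GenotypeMatrix}.
#' @export
filterMarkers <- function(gm, mafMin = 0.05, missingMax = 0.20) {
  stopifnot(is(gm, "GenotypeMatrix"))
  maf <- markerMAF(gm)
  miss <- markerMissingness(gm)
  allMissing <- miss >= 1
  failMaf <- !allMissing & (is.na(maf) | maf < mafMin)
  failMiss <- !allMissing & miss > missingMax
  keep <- !(allMissing | failMaf | failMiss)
  if (!any(keep)) stopf("all %d markers removed by QC filters; empty panel", length(keep))
  log <- list(input = length(keep), removedMAF = sum(failMaf),
              removedMissing = sum(failMiss), removedAllMissing = sum(allMissing),
              kept = sum(keep))
  message(sprintf("filterMarkers: kept %d/%d (removed %d MAF < %g, %d missing > %g, %d empty)",
                  log$kept, log$input, log$removedMAF, mafMin,
                  log$removedMissing, missingMax, log$removedAllMissing))
  out <- genotypeMatrix(dosages(gm)[, keep, drop = FALSE], codingState(gm))
  attr(out, "filterLog") <- log
  out
}

#' Recode major/minor dosages to the -1/0/+1 model coding
#'
#' Maps 1 (homozygous major) to -1, 0 (homozygous minor) to +1 and 0.5
#' (heterozygous) to 0, preserving missing calls. Applying it to an already
#' recoded matrix is an error, so a matrix can never be double-recoded.
#'
#' @param gm a \code{GenotypeMatrix} in coding state \code{"raw01half"}.
#' @return A \code{GenotypeMatrix} in coding state \code{"recoded_pm1"}.
#' @export
recodePM1 <- function(gm) {
  stopifnot(is(gm, "GenotypeMatrix"))
  if (identical(codingState(gm), "recoded_pm1"))
    stopf("matrix is already in recoded_pm1 coding; refusing to recode twice")
  genotypeMatrix(1 - 2 * dosages(gm), "recoded_pm1")
}

#' Mean-impute missing genotype calls
#'
#' Replaces each missing entry by the per-marker mean of the non-missing
#' dosages (so imputation never changes a marker's mean).
#'
#' @param gm a \code{GenotypeMatrix} in coding state \code{"recoded_pm1"}.
#' @return A complete \code{GenotypeMatrix}.
#' @export
imputeMean <- function(gm) {
  stopifnot(is(gm, "GenotypeMatrix"))
  if (!identical(codingState(gm), "recoded_pm1"))
    stopf("imputeMean expects recoded_pm1 coding; call recodePM1() first")
  d <- dosages(gm)
  if (!anyNA(d)) return(gm)
  nObs <- colSums(!is.na(d))
  if (any(nObs == 0L))
    stopf("marker with zero non-missing calls (e.g. %s); run filterMarkers() first",
          colnames(d)[which(nObs == 0L)[1]])
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mu[idx[, 2]]
  genotypeMatrix(d, "recoded_pm1")
}

#' Compute the genomic relationship matrix
#'
#' VanRaden-type construction: \code{G = W W' / c} where \code{W} is the
#' column-centered dosage matrix and \code{c = sum_j 2 p_j (1 - p_j)} with
#' \code{p_j} the observed allele frequency of marker j (computed from the
#' post-filter panel). If the minimum eigenvalue of \code{G} is negative,
#' the matrix is bent by adding a small multiple of the identity
#' (\code{1e-6} plus the eigenvalue deficit), which leaves breeding-value
#' rankings untouched while making downstream factorizations safe.
#'
#' @param gm a complete \code{GenotypeMatrix} in \code{"recoded_pm1"} coding.
#' @return A \code{KinshipSet} carrying \code{G} (no kernels).
#' @export
computeGRM <- function(gm) {
  stopifnot(is(gm, "GenotypeMatrix"))
  if (!identical(codingState(gm), "recoded_pm1"))
    stopf("computeGRM expects recoded_pm1 coding")
  d <- dosages(gm)
  if (anyNA(d)) stopf("computeGRM requires a complete matrix; call imputeMean() first")
  p <- colMeans((d + 1) / 2)
  cNorm <- sum(2 * p * (1 - p))
  if (cNorm <= 0) stopf("zero GRM normalizer: all markers are monomorphic")
  W <- sweep(d, 2, colMeans(d))
  G <- tcrossprod(W) / cNorm
  G <- (G + t(G)) / 2
  ev <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-10) G <- G + diag(1e-6 - ev, nrow(G))
  dimnames(G) <- list(rownames(d), rownames(d))
  new("KinshipSet", G = G, kernels = list(), bandwidths = numeric(),
      markerCountUsed = ncol(d))
}

#' Compute Gaussian kernel relationship matrices
#'
#' Builds one kernel per bandwidth from the squared-distance matrix
#' \code{D_ik = mean_j (x_ij - x_kj)^2}, scaled by the median of its
#' off-diagonal entries so bandwidths are unitless:
#' \code{K_h = exp(-h D / median(offdiag(D)))}. The default bandwidths
#' \code{0.2, 1, 5} give one flat, one intermediate and one local kernel,
#' the usual three-kernel set for kernel-averaging RKHS regression.
#'
#' @param gm a complete \code{GenotypeMatrix} in \code{"recoded_pm1"} coding.
#' @param bandwidths positive numeric vector.
#' @return A \code{KinshipSet} with \code{G} and the kernels.
#' @export
computeKernels <- function(gm, bandwidths = c(0.2, 1, 5)) {
  stopifnot(is(gm, "GenotypeMatrix"), all(bandwidths >= 0))
  d <- dosages(gm)
  if (nrow(d) < 2L) stopf("need at least 2 individuals to build kernels")
  if (anyNA(d)) stopf("computeKernels requires a complete matrix")
  ## squared Euclidean distance / m via the Gram matrix
  cp <- tcrossprod(d)
  sq <- diag(cp)
  D <- (outer(sq, sq, "+") - 2 * cp) / ncol(d)
  D[D < 0] <- 0
  med <- median(D[upper.tri(D)])
  if (med <= 0) {
    warnf("median off-diagonal distance is 0 (panel of clones?); kernels are all-ones")
    med <- 1
  }
  Ds <- D / med
  ks <- computeGRM(gm)
  ks@kernels <- lapply(bandwidths, function(h) {
    K <- exp(-h * Ds)
    (K + t(K)) / 2
  })
  ks@bandwidths <- as.numeric(bandwidths)
  ks
}
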