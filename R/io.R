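## Readers and writers for the package's delimited-text interchange
## formats: genotype matrices (numeric and HapMap), plot tables, square
## kinship matrices and simulation configs.

#' Write a genotype matrix as a delimited numeric table
#'
#' Individuals as rows, marker IDs as header, missing calls as NA,
#' tab-separated.
#'
#' @param gm a \code{GenotypeMatrix}.
#' @param path output file.
#' @export
writeGenotypeMatrix <- function(gm, path) {
  stopifnot(is(gm, "GenotypeMatrix"))
  d <- dosages(gm)
  df <- data.frame(id = rownames(d), d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix written by \code{\link{writeGenotypeMatrix}}
#'
#' @param path input file.
#' @param codingState coding of the stored dosages.
#' @return A \code{GenotypeMatrix}.
#' @export
readGenotypeMatrix <- function(path, codingState = "raw01half") {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  genotypeMatrix(m, codingState)
}

#' Write a genotype matrix as HapMap-format text
#'
#' Standard 11 metadata columns followed by one column per individual.
#' Alleles are encoded synthetically (major = A, minor = C), so only the
#' numeric content round-trips, not real nucleotides.
#'
#' @param gm a \code{GenotypeMatrix} in \code{"raw01half"} coding.
#' @param path output file.
#' @export
writeHapmap <- function(gm, path) {
  stopifnot(is(gm, "GenotypeMatrix"))
  if (!identical(codingState(gm), "raw01half"))
    stopf("writeHapmap expects raw01half coding")
  d <- dosages(gm)
  meta <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
            "center", "protLSID", "assayLSID", "panelLSID", "QCcode")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(meta, rownames(d)), collapse = "\t"), con)
  callMap <- function(v) {
    out <- rep("NN", length(v))
    out[!is.na(v) & v == 1] <- "AA"
    out[!is.na(v) & v == 0.5] <- "AC"
    out[!is.na(v) & v == 0] <- "CC"
    out
  }
  for (j in seq_len(ncol(d))) {
    row <- c(colnames(d)[j], "A/C", "1", as.character(j), "+", "NA",
             "NA", "NA", "NA", "NA", "NA", callMap(d[, j]))
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a plot-record table
#'
#' Tab-separated with header genotype, year, condition, replicate, then
#' one column per trait.
#'
#' @param plots plot-record data.frame.
#' @param path output file.
#' @export
writePlots <- function(plots, path) {
  write.table(plots, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plot-record table
#'
#' @param path input file.
#' @return data.frame.
#' @export
readPlots <- function(path) read.delim(path, check.names = FALSE)

#' Write a square matrix (kinship, kernel, correlation) with ID headers
#'
#' @param M square matrix with dimnames.
#' @param path output file.
#' @export
writeSquareMatrix <- function(M, path) {
  df <- data.frame(id = rownames(M), M, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square matrix written by \code{\link{writeSquareMatrix}}
#'
#' @param path input file.
#' @return matrix with dimnames.
#' @export
readSquareMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a simulation config as structured text
#'
#' Key/value lines with matrix-valued fields flattened row-wise, readable
#' by \code{\link{readSimConfig}}.
#'
#' @param config a \code{SimConfig}.
#' @param path output file.
#' @export
writeSimConfig <- function(config, path) {
  stopifnot(is(config, "SimConfig"))
  fmt <- function(x) paste(formatC(x, digits = 17, format = "g"), collapse = ",")
  lines <- c(
    paste("nGenotypes:", config@nGenotypes),
    paste("nMarkers:", config@nMarkers),
    paste("alleleFreqRange:", fmt(config@alleleFreqRange)),
    paste("traitNames:", paste(config@traitNames, collapse = ",")),
    paste("HTrue:", fmt(as.vector(config@HTrue))),
    paste("gxeVariances:", fmt(config@gxeVariances)),
    paste("residVariances:", fmt(config@residVariances)),
    paste("yearVariance:", fmt(config@yearVariance)),
    paste("repVariance:", fmt(config@repVariance)),
    paste("nYears:", config@nYears),
    paste("nReps:", config@nReps),
    paste("conditions:", paste(config@conditions, collapse = ",")),
    paste("conditionCor:", fmt(config@conditionCor)),
    paste("missingGenoRate:", fmt(config@missingGenoRate)),
    paste("selfingHet:", fmt(config@selfingHet)),
    paste("seed:", config@seed))
  writeLines(lines, path)
  invisible(path)
}

#' Read a simulation config written by \code{\link{writeSimConfig}}
#'
#' @param path input file.
#' @return A \code{SimConfig}.
#' @export
readSimConfig <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, ": ?")
  vals <- setNames(lapply(kv, function(x) paste(x[-1], collapse = ":")),
                   vapply(kv, `[[`, character(1), 1))
  num <- function(k) as.numeric(strsplit(vals[[k]], ",")[[1]])
  chr <- function(k) strsplit(vals[[k]], ",")[[1]]
  traits <- chr("traitNames")
  t <- length(traits)
  H <- matrix(num("HTrue"), t, t, dimnames = list(traits, traits))
  simConfig(nGenotypes = num("nGenotypes"), nMarkers = num("nMarkers"),
            alleleFreqRange = num("alleleFreqRange"), traitNames = traits,
            HTrue = H, gxeVariances = num("gxeVariances"),
            residVariances = num("residVariances"),
            yearVariance = num("yearVariance"), repVariance = num("repVariance"),
            nYears = num("nYears"), nReps = num("nReps"),
            conditions = chr("conditions"), conditionCor = num("conditionCor"),
            missingGenoRate = num("missingGenoRate"),
            selfingHet = num("selfingHet"), seed = num("seed"))
}
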