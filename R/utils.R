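#' @useDynLib mtgp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats var sd cor coef lm optimize rnorm rbinom runif rWishart
#'   rchisq rbeta qtukey ptukey pf pnorm aov anova median setNames complete.cases
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed and a label path
#'
#' Deterministically maps a master seed plus any number of string/integer
#' labels to an integer seed below 2^31, so that independent stages, folds
#' and chains of an analysis each get their own reproducible stream.
#'
#' @param master integer master seed.
#' @param ... labels (coerced to character) identifying the consumer.
#' @return A single integer seed.
#' @examples
#' childSeed(1, "cv", 3, "fold", 2)
#' @export
childSeed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(abs(as.integer(master)) %% m)
  for (lab in unlist(lapply(list(...), as.character))) {
    for (code in utf8ToInt(lab)) {
      h <- (h * 131 + code) %% m
    }
    h <- (h * 131 + 7) %% m
  }
  as.integer(h %% (m - 2)) + 1L
}

## symmetrize and, if needed, bend a covariance matrix to PSD by flooring
## eigenvalues; returns the matrix unchanged when already PSD.
bendPSD <- function(M, floor = 0, jitter = 1e-6) {
  M <- (M + t(M)) / 2
  ev <- eigen(M, symmetric = TRUE)
  if (min(ev$values) >= floor) return(M)
  vals <- pmax(ev$values, jitter)
  M2 <- ev$vectors %*% (vals * t(ev$vectors))
  (M2 + t(M2)) / 2
}

isPSD <- function(M, tol = -1e-8) {
  min(eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values) >= tol
}

## log(det) of a positive-definite matrix via Cholesky
logDet <- function(M) 2 * sum(log(diag(chol(M))))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
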