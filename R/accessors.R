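## Accessors and show methods.

#' @rdname GenotypeMatrix-class
#' @param object,x a \code{GenotypeMatrix}.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosages)

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("codingState", function(x) standardGeneric("codingState"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("codingState", "GenotypeMatrix", function(x) x@codingState)

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("individualIds", "GenotypeMatrix", function(x) rownames(x@dosages))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("markerIds", "GenotypeMatrix", function(x) colnames(x@dosages))

setMethod("show", "GenotypeMatrix", function(object) {
  d <- object@dosages
  cat(sprintf("GenotypeMatrix: %d individuals x %d markers (%s)\n",
              nrow(d), ncol(d), object@codingState))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(d))))
})

#' Construct a GenotypeMatrix
#'
#' @param dosages numeric matrix (individuals x markers) with dimnames.
#' @param codingState \code{"raw01half"} or \code{"recoded_pm1"}.
#' @return A \code{GenotypeMatrix}.
#' @export
genotypeMatrix <- function(dosages, codingState = "raw01half") {
  new("GenotypeMatrix", dosages = dosages, codingState = codingState)
}

#' @rdname KinshipSet-class
#' @param x a \code{KinshipSet}.
#' @export
setGeneric("grm", function(x) standardGeneric("grm"))

#' @rdname KinshipSet-class
#' @export
setMethod("grm", "KinshipSet", function(x) x@G)

#' @rdname KinshipSet-class
#' @export
setGeneric("kernelMatrices", function(x) standardGeneric("kernelMatrices"))

#' @rdname KinshipSet-class
#' @export
setMethod("kernelMatrices", "KinshipSet", function(x) x@kernels)

setMethod("show", "KinshipSet", function(object) {
  cat(sprintf("KinshipSet: %d individuals, %d markers used, %d kernel(s)\n",
              nrow(object@G), object@markerCountUsed, length(object@kernels)))
  if (length(object@bandwidths))
    cat("  bandwidths:", paste(object@bandwidths, collapse = ", "), "\n")
})

#' Construct MaskedPhenotypes
#'
#' @param values genotype x trait numeric matrix with dimnames.
#' @param mask logical matrix of the same shape (TRUE = visible); defaults
#'   to everything observed.
#' @return A \code{MaskedPhenotypes}.
#' @export
maskedPhenotypes <- function(values, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(values), ncol(values),
                                    dimnames = dimnames(values))
  new("MaskedPhenotypes", values = values, mask = mask)
}

#' Values a model is allowed to see
#'
#' Returns the phenotype matrix with every masked cell set to \code{NA}.
#' All model-fitting code reads phenotypes exclusively through this
#' accessor, which is what makes the held-out-entry integrity guarantee
#' hold.
#'
#' @param x a \code{MaskedPhenotypes}.
#' @return numeric matrix with NA at masked or unmeasured cells.
#' @export
setGeneric("observedValues", function(x) standardGeneric("observedValues"))

#' @rdname observedValues
#' @export
setMethod("observedValues", "MaskedPhenotypes", function(x) {
  v <- x@values
  v[!x@mask] <- NA_real_
  v
})

setMethod("show", "MaskedPhenotypes", function(object) {
  cat(sprintf("MaskedPhenotypes: %d genotypes x %d traits, %d masked cells\n",
              nrow(object@values), ncol(object@values), sum(!object@mask)))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d genotypes, %d markers, %d traits, %d years x %d reps, conditions: %s\n",
              object@nGenotypes, object@nMarkers, length(object@traitNames),
              object@nYears, object@nReps, paste(object@conditions, collapse = "/")))
})

setMethod("show", "SimulatedStudy", function(object) {
  cat("SimulatedStudy\n")
  show(object@config)
  cat(sprintf("  plots: %d rows; true breeding values: %d x %d\n",
              nrow(object@plots), nrow(object@trueBreedingValues),
              ncol(object@trueBreedingValues)))
})

#' @rdname SimulatedStudy-class
#' @param x a \code{SimulatedStudy}.
#' @export
setGeneric("plotRecords", function(x) standardGeneric("plotRecords"))

#' @rdname SimulatedStudy-class
#' @export
setMethod("plotRecords", "SimulatedStudy", function(x) x@plots)

#' @rdname SimulatedStudy-class
#' @export
setGeneric("trueBreedingValues", function(x) standardGeneric("trueBreedingValues"))

#' @rdname SimulatedStudy-class
#' @export
setMethod("trueBreedingValues", "SimulatedStudy", function(x) x@trueBreedingValues)

#' @rdname SimulatedStudy-class
#' @export
setGeneric("genotypeData", function(x) standardGeneric("genotypeData"))

#' @rdname SimulatedStudy-class
#' @export
setMethod("genotypeData", "SimulatedStudy", function(x) x@genotypes)

setMethod("show", "StageOneFit", function(object) {
  cat(sprintf("StageOneFit: trait %s, condition %s (%s)\n", object@trait,
              object@condition,
              if (length(object@eblues)) "genotype fixed" else "genotype random"))
  if (!is.na(object@H2)) cat(sprintf("  H2 = %.3f\n", object@H2))
  if (length(object@varComponents))
    cat("  variance components:",
        paste(sprintf("%s=%.4g", names(object@varComponents),
                      object@varComponents), collapse = ", "), "\n")
})

#' @rdname StageOneFit-class
#' @param x a \code{StageOneFit}.
#' @export
setGeneric("eblues", function(x) standardGeneric("eblues"))

#' @rdname StageOneFit-class
#' @export
setMethod("eblues", "StageOneFit", function(x) x@eblues)

#' @rdname StageOneFit-class
#' @export
setGeneric("varComponents", function(x) standardGeneric("varComponents"))

#' @rdname StageOneFit-class
#' @export
setMethod("varComponents", "StageOneFit", function(x) x@varComponents)

setMethod("show", "GeneticParams", function(object) {
  cat(sprintf("GeneticParams (%s): traits %s; rho_g = %.3f\n",
              object@estimator, paste(object@traits, collapse = " / "),
              object@rhoG))
})

#' @rdname UvGblupFit-class
#' @param x a fit object.
#' @export
setGeneric("gebv", function(x) standardGeneric("gebv"))

#' @rdname UvGblupFit-class
#' @export
setMethod("gebv", "UvGblupFit", function(x) x@gebv)

#' @rdname MvGblupFit-class
#' @export
setMethod("gebv", "MvGblupFit", function(x) x@gebvMatrix)

#' @rdname MtBayesFit-class
#' @export
setMethod("gebv", "MtBayesFit", function(x) x@posteriorMeanGebv)

#' @rdname RfFit-class
#' @export
setMethod("gebv", "RfFit", function(x) x@predictions)

setMethod("show", "UvGblupFit", function(object) {
  cat(sprintf("UvGblupFit: sigmaG2 = %.4g, sigmaE2 = %.4g, %d GEBVs%s\n",
              object@sigmaG2, object@sigmaE2, length(object@gebv),
              if (object@converged) "" else " (NOT converged)"))
})

setMethod("show", "MvGblupFit", function(object) {
  cat(sprintf("MvGblupFit: %d traits, %d genotypes%s\n", ncol(object@gebvMatrix),
              nrow(object@gebvMatrix),
              if (object@converged) "" else " (NOT converged)"))
})

setMethod("show", "MtBayesFit", function(object) {
  cat(sprintf("MtBayesFit (%s): %d genotypes x %d traits, seed %d\n",
              object@model, nrow(object@posteriorMeanGebv),
              ncol(object@posteriorMeanGebv), object@chainSeed))
})

setMethod("show", "RfFit", function(object) {
  cat(sprintf("RfFit: %d trees, mtry %d, min node %d\n",
              object@chosen[["nTrees"]], object@chosen[["mtry"]],
              object@chosen[["minNode"]]))
})

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan: %d repeats x %d folds over %d genotypes (seed %d)\n",
              object@nRepeats, object@nFolds,
              length(unique(object@assignments$genotype)), object@seed))
})

setMethod("show", "SchemeSpec", function(object) {
  cat(sprintf("SchemeSpec: %s / %s, target %s%s\n", object@scheme,
              object@analysis, object@targetTrait,
              if (length(object@secondaryTraits))
                paste0(", secondaries: ",
                       paste(object@secondaryTraits, collapse = ", ")) else ""))
})
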