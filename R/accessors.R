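# Generics, accessors and show() methods for the S4 containers.

#' @rdname DistinguisherResult-class
#' @param object,x an object.
#' @export
setGeneric("anchorGenes", function(x) standardGeneric("anchorGenes"))

#' @describeIn DistinguisherResult-class gene identifiers of the final
#'   distinguishers, in selection order.
#' @export
setMethod("anchorGenes", "DistinguisherResult", function(x) x@anchorIds)

#' @rdname DistinguisherResult-class
#' @export
setGeneric("bestLengths", function(x) standardGeneric("bestLengths"))

#' @describeIn DistinguisherResult-class the bestLengths diagnostic matrix
#'   (rows = rank, columns = process).
#' @export
setMethod("bestLengths", "DistinguisherResult", function(x) x@bestLengths)

#' @rdname DistinguisherResult-class
#' @export
setGeneric("runnerUpTables", function(x) standardGeneric("runnerUpTables"))

#' @describeIn DistinguisherResult-class per-process ranked runners-up
#'   tables (gene_id, distance).
#' @export
setMethod("runnerUpTables", "DistinguisherResult", function(x) x@runnersUp)

#' @rdname DeconvolutionResult-class
#' @param x an object.
#' @export
setGeneric("sampleProportions", function(x) standardGeneric("sampleProportions"))

#' @describeIn DeconvolutionResult-class estimated processes-by-samples
#'   mixing fractions (columns sum to one).
#' @export
setMethod("sampleProportions", "DeconvolutionResult", function(x) x@proportions)

#' @describeIn SyntheticDataset-class true mixing fractions used to build
#'   the mixtures.
#' @export
setMethod("sampleProportions", "SyntheticDataset", function(x) x@proportions)

#' @rdname DeconvolutionResult-class
#' @export
setGeneric("processSignatures", function(x) standardGeneric("processSignatures"))

#' @describeIn DeconvolutionResult-class estimated genes-by-processes pure
#'   signatures.
#' @export
setMethod("processSignatures", "DeconvolutionResult", function(x) x@signatures)

#' @describeIn SyntheticDataset-class true pure signatures.
#' @export
setMethod("processSignatures", "SyntheticDataset", function(x) x@signatures)

#' @rdname SyntheticDataset-class
#' @param x an object.
#' @export
setGeneric("observedMatrix", function(x) standardGeneric("observedMatrix"))

#' @describeIn SyntheticDataset-class the observed (noised, replicated)
#'   mixed expression matrix.
#' @export
setMethod("observedMatrix", "SyntheticDataset", function(x) x@observed)

#' @rdname SyntheticDataset-class
#' @export
setGeneric("anchorTruth", function(x) standardGeneric("anchorTruth"))

#' @describeIn SyntheticDataset-class per-process list of the designed
#'   exclusive (anchor) gene identifiers.
#' @export
setMethod("anchorTruth", "SyntheticDataset", function(x) x@anchorTruth)

#' @rdname MarkerSets-class
#' @param x an object.
#' @export
setGeneric("markerList", function(x) standardGeneric("markerList"))

#' @describeIn MarkerSets-class named list of marker gene vectors.
#' @export
setMethod("markerList", "MarkerSets",
          function(x) stats::setNames(x@members, x@processIds))

#' @rdname MarkerSets-class
#' @export
setGeneric("processIds", function(x) standardGeneric("processIds"))

#' @describeIn MarkerSets-class process identifiers.
#' @export
setMethod("processIds", "MarkerSets", function(x) x@processIds)

#' @describeIn DeconvolutionResult-class process identifiers.
#' @export
setMethod("processIds", "DeconvolutionResult", function(x) x@processIds)

setMethod("show", "ConditionalGeometry", function(object) {
  cat("ConditionalGeometry:", length(object@geneIds), "genes x",
      length(object@sampleIds), "samples (factored; no g x g matrix)\n")
})

setMethod("show", "MarkerSets", function(object) {
  cat("MarkerSets:", length(object@processIds), "processes;",
      paste0("sizes [", paste(lengths(object@members), collapse = ", "), "]\n"))
})

setMethod("show", "DistinguisherResult", function(object) {
  cat("DistinguisherResult: b =", object@b, "processes, spike =",
      format(object@spike, digits = 4), "\n")
  cat("  anchors:", paste(object@anchorIds, collapse = ", "), "\n")
  cat("  best-distinguisher hyperplane distances:",
      paste(format(object@bestLengths[1L, ], digits = 4), collapse = ", "),
      "\n")
})

setMethod("show", "DeconvolutionResult", function(object) {
  cat("DeconvolutionResult:", nrow(object@proportions), "processes x",
      ncol(object@proportions), "samples;",
      nrow(object@signatures), "genes\n")
  cat("  converged:", object@converged, "after", object@nIterations,
      "iterations; final residual",
      format(object@objectiveTrace[length(object@objectiveTrace)],
             digits = 6), "\n")
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset:", nrow(object@signatures), "genes,",
      ncol(object@signatures), "processes,",
      ncol(object@proportions), "samples x", object@replicates,
      "replicate(s)\n")
  cat("  design:", object@designOrigin, " sigma:", object@sigmaRel,
      " seed:", object@seed, "\n")
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport\n")
  cat("  mean proportions RMSE:   ", format(object@meanRMSE, digits = 6), "\n")
  cat("  uniform-baseline RMSE:   ",
      format(object@uniformBaselineRMSE, digits = 6), "\n")
  if (!all(is.na(object@perProcessPearson)))
    cat("  signature Pearson:       ",
        paste(format(object@perProcessPearson, digits = 4), collapse = ", "),
        "\n")
  if (!is.na(object@concatenatedCosine))
    cat("  concatenated cosine:     ",
        format(object@concatenatedCosine, digits = 6), "\n")
  cat("  process matching:        ",
      paste(object@permutation, collapse = " "), "\n")
})
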