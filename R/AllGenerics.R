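#' @rdname PrecisionTruth-class
#' @param object,x a package object.
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))

#' @rdname PrecisionTruth-class
#' @export
setGeneric("thetaTrue", function(object) standardGeneric("thetaTrue"))

#' @rdname PrecisionTruth-class
#' @export
setGeneric("sigmaTrue", function(object) standardGeneric("sigmaTrue"))

#' @rdname GeneNetwork-class
#' @export
setGeneric("edgeMatrix", function(object) standardGeneric("edgeMatrix"))

#' @rdname GeneNetwork-class
#' @export
setGeneric("degrees", function(object) standardGeneric("degrees"))

#' @rdname GeneNetwork-class
#' @export
setGeneric("scaledDegrees", function(object) standardGeneric("scaledDegrees"))

#' @rdname PrecisionEstimate-class
#' @export
setGeneric("thetaHat", function(object) standardGeneric("thetaHat"))

#' @rdname PrecisionEstimate-class
#' @export
setGeneric("sigmaHat", function(object) standardGeneric("sigmaHat"))

#' @rdname CVResult-class
#' @export
setGeneric("lambdaOpt", function(object) standardGeneric("lambdaOpt"))

#' @rdname CVResult-class
#' @export
setGeneric("lambdaMin", function(object) standardGeneric("lambdaMin"))

setMethod("adjacency", "PrecisionTruth", function(object) object@adjacency)
setMethod("thetaTrue", "PrecisionTruth", function(object) object@thetaTrue)
setMethod("sigmaTrue", "PrecisionTruth", function(object) object@sigmaTrue)
setMethod("edgeMatrix", "PrecisionTruth", function(object) object@edges)
setMethod("edgeMatrix", "GeneNetwork", function(object) object@edges)
setMethod("degrees", "GeneNetwork", function(object) object@degree)
setMethod("scaledDegrees", "GeneNetwork", function(object) object@scaledDegree)
setMethod("thetaHat", "PrecisionEstimate", function(object) object@thetaHat)
setMethod("sigmaHat", "PrecisionEstimate", function(object) object@sigmaHat)
setMethod("lambdaOpt", "CVResult", function(object) object@lambdaOpt)
setMethod("lambdaMin", "CVResult", function(object) object@lambdaMin)

#' @rdname GeneNetwork-class
#' @export
setGeneric("nodeNames", function(object) standardGeneric("nodeNames"))
setMethod("nodeNames", "GeneNetwork", function(object) object@nodes)

setMethod("show", "PrecisionTruth", function(object) {
  p <- nrow(object@adjacency)
  cat("PrecisionTruth:", p, "nodes,", nrow(object@edges), "edges",
      sprintf("(density %.4g)\n", nrow(object@edges) / (p * (p - 1) / 2)))
})

setMethod("show", "TwoGroupTruth", function(object) {
  cat("TwoGroupTruth:", nrow(object@truthA@adjacency), "nodes,",
      length(object@differentialNodes), "planted differential hubs\n")
})

setMethod("show", "PrecisionEstimate", function(object) {
  p <- nrow(object@thetaHat)
  supp <- abs(object@thetaHat) > 1e-8
  diag(supp) <- FALSE
  cat(sprintf(
    "PrecisionEstimate: p = %d, lambda = %.4g, %d edges, %s (%d sweeps)\n",
    p, object@lambda, sum(supp) / 2,
    if (object@converged) "converged" else "NOT converged",
    object@iterations))
})

setMethod("show", "GeneNetwork", function(object) {
  cat("GeneNetwork:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges")
  if (nrow(object@edges)) {
    hub <- which.max(object@degree)
    cat(sprintf("; max degree %d (%s)", object@degree[hub],
                object@nodes[hub]))
  }
  cat("\n")
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf(
    "CVResult: %d lambda values; lambdaMin = %.4g, lambdaOpt (1-SE) = %.4g\n",
    length(object@grid), object@lambdaMin, object@lambdaOpt))
})
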