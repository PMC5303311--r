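#' @import methods
NULL

#' Simulated ground truth for a sparse Gaussian graphical model
#'
#' Holds the adjacency matrix of a scale-free graph, the true precision
#' matrix built on that topology, and the implied covariance matrix rescaled
#' to unit diagonal (a correlation matrix). The off-diagonal support of
#' `thetaTrue` equals the adjacency support by construction.
#'
#' @slot adjacency symmetric binary p x p matrix, zero diagonal.
#' @slot thetaTrue symmetric positive-definite p x p precision matrix.
#' @slot sigmaTrue its inverse rescaled to a correlation matrix.
#' @slot edges two-column integer matrix of edge endpoints (i < j).
#'
#' @export
setClass("PrecisionTruth",
  representation(
    adjacency = "matrix",
    thetaTrue = "matrix",
    sigmaTrue = "matrix",
    edges     = "matrix"
  )
)

setValidity("PrecisionTruth", function(object) {
  A <- object@adjacency
  Th <- object@thetaTrue
  Sg <- object@sigmaTrue
  p <- nrow(A)
  msg <- character()
  if (!isSymmetric(A) || any(diag(A) != 0) || !all(A %in% c(0, 1)))
    msg <- c(msg, "adjacency must be symmetric binary with zero diagonal")
  if (any(dim(Th) != p) || any(dim(Sg) != p))
    msg <- c(msg, "dimension mismatch between adjacency and matrices")
  supp <- abs(Th) > 1e-10
  diag(supp) <- FALSE
  if (!identical(unname(supp), unname(A == 1)))
    msg <- c(msg, "off-diagonal support of thetaTrue must equal adjacency")
  if (max(abs(diag(Sg) - 1)) > 1e-8)
    msg <- c(msg, "sigmaTrue must have unit diagonal")
  if (min(eigen(Th, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    msg <- c(msg, "thetaTrue must be positive definite")
  if (length(msg)) msg else TRUE
})

#' Paired ground truths for two-group differential network simulations
#'
#' Two [PrecisionTruth-class] objects sharing a common edge backbone, plus
#' the identity of the nodes whose connectivity was altered in exactly one
#' group ("planted differential hubs") and the true scaled-degree difference
#' of every node.
#'
#' @slot truthA,truthB per-group ground truths.
#' @slot differentialNodes integer indices of the planted hubs.
#' @slot trueDns numeric vector, |scaled degree difference| per node in the
#'   true graphs.
#'
#' @export
setClass("TwoGroupTruth",
  representation(
    truthA = "PrecisionTruth",
    truthB = "PrecisionTruth",
    differentialNodes = "integer",
    trueDns = "numeric"
  )
)

setValidity("TwoGroupTruth", function(object) {
  hubs <- object@differentialNodes
  if (length(hubs) && any(object@trueDns[hubs] <= 0))
    return("planted differential nodes must have a nonzero true scaled-degree difference")
  TRUE
})

#' Estimated sparse precision matrix
#'
#' Result of [wglassoFit()] / [glassoFit()]: the estimate, its inverse as
#' maintained by the block solver, and the penalty that produced it.
#'
#' @slot thetaHat symmetric p x p estimate (symmetrized, exact zeros kept).
#' @slot sigmaHat the covariance estimate tracked by the solver.
#' @slot lambda scalar penalty level.
#' @slot weights prior weight matrix W, or NULL for the unweighted problem.
#' @slot penalizeDiagonal whether the diagonal carried the penalty lambda.
#' @slot objectiveValue value of the penalized negative log-likelihood.
#' @slot converged,iterations solver status.
#'
#' @export
setClass("PrecisionEstimate",
  representation(
    thetaHat = "matrix",
    sigmaHat = "matrix",
    lambda = "numeric",
    weights = "ANY",
    penalizeDiagonal = "logical",
    objectiveValue = "numeric",
    converged = "logical",
    iterations = "integer"
  )
)

setValidity("PrecisionEstimate", function(object) {
  Th <- object@thetaHat
  if (max(abs(Th - t(Th))) > 1e-8)
    return("thetaHat must be symmetric (tolerance 1e-8)")
  TRUE
})

#' Undirected gene network with degrees and scaled degrees
#'
#' @slot nodes character vector of node (gene) identifiers, in order.
#' @slot edges two-column integer matrix of endpoint indices (i < j).
#' @slot degree integer degree per node (named).
#' @slot scaledDegree degree divided by the maximum degree in this network
#'   (all zero when the network has no edges), in `[0, 1]`.
#'
#' @export
setClass("GeneNetwork",
  representation(
    nodes = "character",
    edges = "matrix",
    degree = "integer",
    scaledDegree = "numeric"
  )
)

setValidity("GeneNetwork", function(object) {
  p <- length(object@nodes)
  E <- object@edges
  msg <- character()
  if (ncol(E) != 2) msg <- c(msg, "edges must have two columns")
  if (nrow(E) && (any(E[, 1] >= E[, 2]) || any(E < 1) || any(E > p)))
    msg <- c(msg, "edges must be index pairs with i < j inside the node set")
  if (length(object@degree) != p || length(object@scaledDegree) != p)
    msg <- c(msg, "degree vectors must match the node count")
  if (nrow(E)) {
    if (abs(max(object@scaledDegree) - 1) > 1e-12)
      msg <- c(msg, "maximum scaled degree must be 1 when edges exist")
  } else if (any(object@scaledDegree != 0)) {
    msg <- c(msg, "scaled degrees must all be 0 in an empty network")
  }
  if (length(msg)) msg else TRUE
})

#' Cross-validation result for the penalty level
#'
#' @slot grid descending lambda values.
#' @slot cvError mean held-out negative log-likelihood per lambda.
#' @slot cvSe standard error per lambda.
#' @slot lambdaMin lambda attaining the minimal error.
#' @slot lambdaOpt largest lambda whose error is within one standard error
#'   of the minimum (the one-standard-error rule).
#'
#' @export
setClass("CVResult",
  representation(
    grid = "numeric",
    cvError = "numeric",
    cvSe = "numeric",
    lambdaMin = "numeric",
    lambdaOpt = "numeric"
  )
)

setValidity("CVResult", function(object) {
  msg <- character()
  if (is.unsorted(rev(object@grid)))
    msg <- c(msg, "grid must be in descending order")
  if (object@lambdaOpt < object@lambdaMin)
    msg <- c(msg, "one-SE lambda cannot be smaller than lambdaMin")
  if (!object@lambdaOpt %in% object@grid)
    msg <- c(msg, "lambdaOpt must be a grid value")
  if (length(msg)) msg else TRUE
})
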