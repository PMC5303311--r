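#' Weighted graphical LASSO
#'
#' Estimates a sparse precision matrix by minimizing the penalized Gaussian
#' negative log-likelihood
#' \deqn{-\log\det\Theta + \mathrm{tr}(S\Theta) +
#'   \lambda \| (1 - W) * \Theta \|_1,}
#' where `*` is element-wise multiplication and `W` is a symmetric matrix of
#' prior confidence scores in `[0, 1]` (e.g. rescaled STRING combined
#' scores). A score of 1 removes the penalty from that pair entirely; a
#' score of 0 leaves the full penalty `lambda`, recovering the plain
#' graphical LASSO when `W` is absent. The solver is block coordinate
#' descent over columns, each column solved as an L1-penalized quadratic
#' program with per-coordinate penalties; it stops when the mean absolute
#' change of the off-diagonal covariance estimate per sweep falls below
#' `tol` times the mean absolute off-diagonal entry of `S`.
#'
#' @param S sample covariance/correlation matrix (symmetric, positive
#'   diagonal).
#' @param lambda scalar penalty level (>= 0).
#' @param weights optional prior weight matrix W; `NULL` means W = 0.
#' @param penalizeDiagonal if `TRUE` (default) the diagonal carries penalty
#'   `lambda` (diagonal weights are treated as 0).
#' @param tol relative convergence tolerance (default 1e-4).
#' @param maxIter maximum outer sweeps (default 200).
#' @param warmStart optional [PrecisionEstimate-class] from a nearby lambda
#'   used to initialize the solver.
#' @return a [PrecisionEstimate-class].
#' @seealso [glassoFit()], [networkFromEstimate()], [tuneLambdaCV()]
#' @export
wglassoFit <- function(S, lambda, weights = NULL, penalizeDiagonal = TRUE,
                       tol = 1e-4, maxIter = 200L, warmStart = NULL) {
  if (!is.matrix(S) || !isSymmetric(unname(S), tol = 1e-8))
    stop("'S' must be a symmetric matrix")
  if (any(diag(S) <= 0)) stop("'S' must have a positive diagonal")
  if (lambda < 0) stop("'lambda' must be nonnegative")
  S <- (unname(S) + t(unname(S))) / 2
  p <- nrow(S)
  if (is.null(weights)) {
    W <- matrix(0, p, p)
  } else {
    W <- unname(as.matrix(weights))
    checkWeightMatrix(W, p)
  }
  diag(W) <- 0                       # diagonal weight convention
  Lambda <- lambda * (1 - W)

  # fully unpenalized problem: the MLE is S^-1 and needs an invertible S
  offZero <- p < 2 || all(Lambda[upper.tri(Lambda)] == 0)
  if (offZero && (!penalizeDiagonal || lambda == 0)) {
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch))
      stop("S is singular and the effective penalty is zero: ",
           "the unpenalized MLE does not exist")
  }

  Sigma0 <- NULL
  B0 <- NULL
  if (!is.null(warmStart)) {
    stopifnot(is(warmStart, "PrecisionEstimate"))
    Sigma0 <- warmStart@sigmaHat
    B0 <- attr(warmStart@sigmaHat, "beta")
  }
  fit <- cpp_wglasso(S, Lambda, penalizeDiagonal, tol, as.integer(maxIter),
                     Sigma0, B0)
  if (!fit$converged)
    warning("wglasso did not converge in ", maxIter, " sweeps")
  sig <- fit$sigma
  attr(sig, "beta") <- fit$beta
  new("PrecisionEstimate",
      thetaHat = fit$theta, sigmaHat = sig, lambda = lambda,
      weights = if (is.null(weights)) NULL else W,
      penalizeDiagonal = penalizeDiagonal,
      objectiveValue = fit$objective,
      converged = fit$converged, iterations = as.integer(fit$iterations))
}

#' Plain graphical LASSO
#'
#' The unweighted special case of [wglassoFit()] (all prior weights zero,
#' uniform penalty `lambda` on every entry).
#'
#' @inheritParams wglassoFit
#' @return a [PrecisionEstimate-class].
#' @export
glassoFit <- function(S, lambda, penalizeDiagonal = TRUE, tol = 1e-4,
                      maxIter = 200L, warmStart = NULL) {
  wglassoFit(S, lambda, weights = NULL, penalizeDiagonal = penalizeDiagonal,
             tol = tol, maxIter = maxIter, warmStart = warmStart)
}

#' Neighbor selection (per-node lasso) network estimation
#'
#' Runs an L1-penalized regression of every column of `X` on all the
#' others with a single shared penalty `lambda`, then reconciles the
#' asymmetric neighborhoods: under the `"or"` rule an edge (i, j) exists
#' when either regression selects the partner, under the `"and"` rule only
#' when both do, so the `"and"` network is always a subgraph of the `"or"`
#' network.
#'
#' @param X data matrix (samples x genes); columns are centered and scaled
#'   to unit sum of squares internally.
#' @param lambda shared lasso penalty (>= 0).
#' @param rule `"or"` or `"and"`.
#' @return a [GeneNetwork-class].
#' @export
neighborSelectionFit <- function(X, lambda, rule = c("or", "and")) {
  rule <- match.arg(rule)
  if (lambda < 0) stop("'lambda' must be nonnegative")
  X <- standardizeColumns(as.matrix(X))
  B <- nsCoefficients(X, lambda)
  networkFromNsCoef(B, rule, colnames(X))
}

# Coefficient matrix of the p per-node lasso fits (column j = regression of
# variable j on the rest), via coordinate descent on the Gram matrix.
nsCoefficients <- function(X, lambda, warmB = NULL) {
  G <- crossprod(X)
  cpp_ns_coef(G, lambda, 1e-7, 1000L, warmB)
}

networkFromNsCoef <- function(B, rule, nodes = NULL) {
  sel <- B != 0
  A <- if (rule == "or") (sel | t(sel)) else (sel & t(sel))
  if (is.null(nodes)) nodes <- paste0("g", seq_len(nrow(B)))
  makeGeneNetwork(edgePairs(A), nodes)
}

#' Extract the undirected network of a precision estimate
#'
#' An edge (i, j), i < j, exists whenever `|thetaHat_ij| > zeroTol`. The
#' coordinate-descent solver returns exact zeros, so `zeroTol` only guards
#' against floating-point noise introduced by symmetrization. Node degrees
#' are scaled by the maximum degree in the network ("scaled degree" in
#' `[0, 1]`); an empty network has all scaled degrees 0.
#'
#' @param est a [PrecisionEstimate-class].
#' @param zeroTol support threshold (default 1e-8).
#' @param nodes optional node names (default `g1..gp`).
#' @return a [GeneNetwork-class].
#' @export
networkFromEstimate <- function(est, zeroTol = 1e-8, nodes = NULL) {
  Th <- thetaHat(est)
  p <- nrow(Th)
  if (is.null(nodes)) nodes <- paste0("g", seq_len(p))
  supp <- abs(Th) > zeroTol
  diag(supp) <- FALSE
  makeGeneNetwork(edgePairs(supp), nodes)
}

# Construct a GeneNetwork from an (i < j) index pair matrix.
makeGeneNetwork <- function(pairs, nodes) {
  p <- length(nodes)
  d <- integer(p)
  if (nrow(pairs)) {
    tab <- tabulate(c(pairs[, 1], pairs[, 2]), nbins = p)
    d <- as.integer(tab)
  }
  sd <- if (max(d) > 0) d / max(d) else rep(0, p)
  names(d) <- names(sd) <- nodes
  new("GeneNetwork", nodes = nodes, edges = pairs, degree = d,
      scaledDegree = sd)
}

#' Verify the subgradient (KKT) optimality conditions of an estimate
#'
#' For the weighted problem the stationarity conditions at the optimum are
#' `S - solve(thetaHat) + Lambda * sign(thetaHat) = 0` on the support and
#' `|S_ij - solve(thetaHat)_ij| <= Lambda_ij` off the support. Returns the
#' largest violation; a correctly solved instance should be below roughly
#' ten times the solver tolerance (scaled by the mean |S| off-diagonal).
#'
#' @param est a [PrecisionEstimate-class].
#' @param S the sample covariance it was fitted to.
#' @param zeroTol support threshold.
#' @return largest KKT violation (a nonnegative scalar).
#' @export
kktViolation <- function(est, S, zeroTol = 1e-8) {
  Th <- thetaHat(est)
  p <- nrow(Th)
  W <- if (is.null(est@weights)) matrix(0, p, p) else est@weights
  Lambda <- est@lambda * (1 - W)
  diag(Lambda) <- if (est@penalizeDiagonal) est@lambda else 0
  Sg <- solve(Th)
  G <- S - Sg
  viol <- 0
  on <- abs(Th) > zeroTol
  offIdx <- !on
  viol <- max(viol, max(abs(G + Lambda * sign(Th))[on]))
  if (any(offIdx))
    viol <- max(viol, max((abs(G) - Lambda)[offIdx], 0))
  viol
}
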