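#' Default penalty grid
#'
#' 50 logarithmically spaced values from `max |S_ij|` (i != j), the level
#' that fully shrinks the unweighted problem, down to 1/100 of it.
#'
#' @param S sample covariance matrix.
#' @param length number of grid points.
#' @param ratio smallest / largest grid value.
#' @return descending numeric vector.
#' @export
lambdaGrid <- function(S, length = 50L, ratio = 0.01) {
  lamMax <- max(abs(S[upper.tri(S)]))
  if (lamMax <= 0) lamMax <- 1
  exp(seq(log(lamMax), log(lamMax * ratio), length.out = length))
}

#' Choose the penalty by cross-validation with the one-standard-error rule
#'
#' Splits the samples into `kFolds` folds after a seeded shuffle. For each
#' penalty value the model is fitted on the training folds and scored on
#' the held-out fold by the Gaussian negative log-likelihood
#' `-log det(Theta) + tr(S_test Theta)`; the held-out fold is standardized
#' with the training fold's centers and scales and its second-moment matrix
#' rescaled to the training convention. `lambdaOpt` is the largest (most
#' regularized) grid value whose mean error is within one standard error of
#' the minimum.
#'
#' @param X data matrix (samples x genes).
#' @param weights optional prior weight matrix W.
#' @param kFolds number of folds (default 10; at least 2, at most n).
#' @param grid descending penalty values; default [lambdaGrid()] of the
#'   full-data correlation matrix.
#' @param seed integer seed controlling the fold shuffle.
#' @param penalizeDiagonal,tol,maxIter passed to [wglassoFit()].
#' @return a [CVResult-class].
#' @export
tuneLambdaCV <- function(X, weights = NULL, kFolds = 10L, grid = NULL,
                         seed = 1L, penalizeDiagonal = TRUE, tol = 1e-4,
                         maxIter = 200L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (kFolds < 2 || kFolds > n) stop("'kFolds' must be in [2, n]")
  if (is.null(grid)) grid <- lambdaGrid(crossprod(standardizeColumns(X)))
  if (!length(grid)) stop("empty penalty grid")
  if (is.unsorted(rev(grid))) grid <- sort(grid, decreasing = TRUE)
  foldId <- withSeed(seed,
    sample(rep_len(seq_len(kFolds), n)))
  if (min(tabulate(foldId, kFolds)) < 3)
    stop("every fold needs at least 3 samples")

  errs <- matrix(NA_real_, kFolds, length(grid))
  for (f in seq_len(kFolds)) {
    trainIdx <- which(foldId != f)
    testIdx <- which(foldId == f)
    Xtr <- X[trainIdx, , drop = FALSE]
    ctr <- colMeans(Xtr)
    Xtr <- sweep(Xtr, 2, ctr, "-")
    scl <- sqrt(colSums(Xtr^2))
    if (any(scl == 0)) stop("constant column within a training fold")
    Xtr <- sweep(Xtr, 2, scl, "/")
    Str <- crossprod(Xtr)
    Xte <- sweep(sweep(X[testIdx, , drop = FALSE], 2, ctr, "-"), 2, scl, "/")
    # rescale so that a fold behaving like the training data gives a test
    # second-moment matrix on the training scale (unit-ish diagonal)
    Ste <- crossprod(Xte) * (length(trainIdx) / length(testIdx))
    warm <- NULL
    for (g in seq_along(grid)) {
      fit <- suppressWarnings(
        wglassoFit(Str, grid[g], weights = weights,
                   penalizeDiagonal = penalizeDiagonal, tol = tol,
                   maxIter = maxIter, warmStart = warm))
      warm <- fit
      Th <- thetaHat(fit)
      ld <- determinant(Th, logarithm = TRUE)
      errs[f, g] <- if (ld$sign > 0)
        -as.numeric(ld$modulus) + sum(Ste * Th) else NA_real_
    }
  }
  cvErr <- colMeans(errs)
  cvSe <- apply(errs, 2, stats::sd) / sqrt(kFolds)
  ok <- which(is.finite(cvErr))
  if (!length(ok)) stop("cross-validation produced no finite errors")
  iMin <- ok[which.min(cvErr[ok])]
  thresh <- cvErr[iMin] + cvSe[iMin]
  iOpt <- min(which(is.finite(cvErr) & cvErr <= thresh))  # grid descends
  new("CVResult", grid = grid, cvError = cvErr, cvSe = cvSe,
      lambdaMin = grid[iMin], lambdaOpt = grid[iOpt])
}

#' Tune the penalty to a target edge count (sparsity matching)
#'
#' Bisects on lambda until the estimated network has exactly `targetEdges`
#' edges, the protocol used to compare methods at the sparsity of the true
#' network. If the exact count is unreachable within `maxSteps` bisection
#' steps (edge counts move in jumps), the sparser nearest solution is
#' returned with `attr(, "matched") = FALSE`.
#'
#' @param X data matrix, or a precomputed covariance when `isCovariance`.
#' @param targetEdges desired number of edges (>= 0).
#' @param method `"wglasso"`, `"glasso"`, `"ns-or"` or `"ns-and"`.
#' @param weights prior weight matrix (wglasso only).
#' @param lambdaBounds search bracket; defaults to (lamMax/1e4, lamMax).
#' @param maxSteps maximum bisection steps (default 40).
#' @param isCovariance interpret `X` as a covariance matrix (graphical
#'   methods only).
#' @param penalizeDiagonal,tol,maxIter solver controls.
#' @return list with `lambda`, `network` (a [GeneNetwork-class]), `estimate`
#'   (a [PrecisionEstimate-class] or NULL for neighbor selection), and
#'   logical `matched`.
#' @export
tuneLambdaToSparsity <- function(X, targetEdges, method = c(
                                   "wglasso", "glasso", "ns-or", "ns-and"),
                                 weights = NULL, lambdaBounds = NULL,
                                 maxSteps = 40L, isCovariance = FALSE,
                                 penalizeDiagonal = TRUE, tol = 1e-4,
                                 maxIter = 200L) {
  method <- match.arg(method)
  if (targetEdges < 0) stop("'targetEdges' must be nonnegative")
  ns <- method %in% c("ns-or", "ns-and")
  rule <- sub("ns-", "", method)
  if (ns) {
    if (isCovariance) stop("neighbor selection needs the data matrix")
    X <- standardizeColumns(as.matrix(X))
    S <- crossprod(X)
  } else {
    S <- if (isCovariance) as.matrix(X) else
      crossprod(standardizeColumns(as.matrix(X)))
  }
  nodes <- colnames(S)
  if (is.null(nodes)) nodes <- paste0("g", seq_len(ncol(S)))
  lamMax <- max(abs(S[upper.tri(S)]))
  if (is.null(lambdaBounds)) lambdaBounds <- c(lamMax * 1e-4, lamMax)
  lo <- lambdaBounds[1]; hi <- lambdaBounds[2]

  evalAt <- function(lam, warm) {
    if (ns) {
      B <- cpp_ns_coef(S, lam, 1e-7, 1000L, warm)
      net <- networkFromNsCoef(B, rule, nodes)
      list(net = net, est = NULL, warm = B, edges = nrow(edgeMatrix(net)))
    } else {
      fit <- suppressWarnings(
        wglassoFit(S, lam, weights = if (method == "wglasso") weights,
                   penalizeDiagonal = penalizeDiagonal,
                   tol = tol, maxIter = maxIter, warmStart = warm))
      net <- networkFromEstimate(fit, nodes = nodes)
      list(net = net, est = fit, warm = fit, edges = nrow(edgeMatrix(net)))
    }
  }

  best <- NULL       # exact match, largest lambda (sparsest ties resolution)
  bestUnder <- NULL  # sparser than target, closest
  bestAny <- NULL    # fallback: closest in absolute terms
  consider <- function(state, lam) {
    state$lambda <- lam
    d <- state$edges - targetEdges
    if (d == 0 && (is.null(best) || lam > best$lambda)) best <<- state
    if (d < 0 && (is.null(bestUnder) || state$edges > bestUnder$edges))
      bestUnder <<- state
    if (is.null(bestAny) ||
        abs(d) < abs(bestAny$edges - targetEdges)) bestAny <<- state
    state
  }

  loBound <- lo
  step <- 0L
  sHi <- consider(evalAt(hi, NULL), hi)
  # expand the bracket upward if even the upper bound is too dense
  while (is.null(best) && sHi$edges > targetEdges && step < maxSteps) {
    hi <- hi * 4
    sHi <- consider(evalAt(hi, sHi$warm), hi)
    step <- step + 1L
  }
  # walk downward until the estimate is denser than the target (lazy, so
  # the near-unpenalized regime is never visited unless required)
  lo <- hi
  sLo <- sHi
  while (is.null(best) && sLo$edges <= targetEdges && lo > loBound &&
         step < maxSteps) {
    lo <- max(lo / 4, loBound)
    sLo <- consider(evalAt(lo, sLo$warm), lo)
    step <- step + 1L
  }
  while (is.null(best) && step < maxSteps && sLo$edges > targetEdges &&
         sHi$edges < targetEdges) {
    mid <- sqrt(lo * hi)
    sMid <- consider(evalAt(mid, sLo$warm), mid)
    if (sMid$edges > targetEdges) {
      lo <- mid; sLo <- sMid
    } else {
      hi <- mid; sHi <- sMid
    }
    step <- step + 1L
  }
  out <- if (!is.null(best)) best else
    if (!is.null(bestUnder)) bestUnder else bestAny
  matched <- out$edges == targetEdges
  if (!matched)
    warning("sparsity target ", targetEdges, " not reached exactly; ",
            "returning ", out$edges, " edges")
  list(lambda = out$lambda, network = out$net, estimate = out$est,
       matched = matched)
}
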