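#' Confusion counts between an estimated network and the truth
#'
#' Counts over unordered node pairs (the upper triangle): `fp` is the
#' number of estimated edges absent from the truth, `fn` the number of true
#' edges missed, so `tp + fp + fn + tn = p(p-1)/2`.
#'
#' @param estimated a [GeneNetwork-class].
#' @param truth a [PrecisionTruth-class] (or adjacency matrix) on the same
#'   node set.
#' @return named list with integer `tp`, `fp`, `fn`, `tn`.
#' @export
countFpFn <- function(estimated, truth) {
  A <- if (is(truth, "PrecisionTruth")) adjacency(truth) else truth
  p <- length(nodeNames(estimated))
  if (nrow(A) != p)
    stop("estimate and truth must share the same node set")
  E <- matrix(FALSE, p, p)
  em <- edgeMatrix(estimated)
  if (nrow(em)) E[em] <- TRUE
  Tm <- A[upper.tri(A)] != 0
  Em <- E[upper.tri(E)]
  tp <- sum(Em & Tm)
  fp <- sum(Em & !Tm)
  fn <- sum(!Em & Tm)
  tn <- sum(!Em & !Tm)
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Precision-recall curve of a method along a penalty grid
#'
#' For each penalty value the network is estimated and scored against the
#' truth; points with an empty estimate (undefined precision) are skipped.
#' Points are reported in grid order (descending penalty); recall is not
#' forced to be monotone.
#'
#' @param method `"wglasso"`, `"glasso"`, `"ns-or"` or `"ns-and"`.
#' @param X data matrix.
#' @param truth a [PrecisionTruth-class].
#' @param weights prior weight matrix (wglasso only).
#' @param grid descending penalty values; default [lambdaGrid()].
#' @param penalizeDiagonal,tol,maxIter solver controls.
#' @return data.frame with columns `lambda`, `precision`, `recall`.
#' @export
precisionRecallCurve <- function(method, X, truth, weights = NULL,
                                 grid = NULL, penalizeDiagonal = TRUE,
                                 tol = 1e-4, maxIter = 200L) {
  method <- match.arg(method, c("wglasso", "glasso", "ns-or", "ns-and"))
  X <- standardizeColumns(as.matrix(X))
  S <- crossprod(X)
  if (is.null(grid)) grid <- lambdaGrid(S)
  if (is.unsorted(rev(grid))) grid <- sort(grid, decreasing = TRUE)
  ns <- method %in% c("ns-or", "ns-and")
  rule <- sub("ns-", "", method)
  out <- vector("list", length(grid))
  warm <- NULL
  for (g in seq_along(grid)) {
    lam <- grid[g]
    if (ns) {
      B <- cpp_ns_coef(S, lam, 1e-7, 1000L, warm)
      warm <- B
      net <- networkFromNsCoef(B, rule)
    } else {
      fit <- suppressWarnings(
        wglassoFit(S, lam, weights = if (method == "wglasso") weights,
                   penalizeDiagonal = penalizeDiagonal, tol = tol,
                   maxIter = maxIter, warmStart = warm))
      warm <- fit
      net <- networkFromEstimate(fit)
    }
    cc <- countFpFn(net, truth)
    if (cc$tp + cc$fp > 0)
      out[[g]] <- data.frame(lambda = lam,
                             precision = cc$tp / (cc$tp + cc$fp),
                             recall = cc$tp / (cc$tp + cc$fn))
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(lambda = numeric(), precision = numeric(),
                      recall = numeric()))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Area under a precision-recall curve
#'
#' Trapezoid rule on the recall-sorted upper hull of the points, with the
#' curve extended horizontally to recall 0 from its first point.
#'
#' @param pr data.frame from [precisionRecallCurve()].
#' @return scalar area in `[0, 1]` (NA for an empty curve).
#' @export
prArea <- function(pr) {
  if (is.null(pr) || nrow(pr) == 0) return(NA_real_)
  o <- order(pr$recall, pr$precision)
  r <- pr$recall[o]
  p <- rev(cummax(rev(pr$precision[o])))  # interpolated (non-increasing) hull
  # collapse duplicate recalls to their best precision
  keep <- !duplicated(r)
  r <- r[keep]; p <- p[keep]
  r <- c(0, r); p <- c(p[1], p)
  sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' Simulation benchmark at matched sparsity
#'
#' For each scenario `(p, n, acc)` and replicate: generate a fresh
#' scale-free truth, sample Gaussian data, corrupt the prior weight matrix
#' to accuracy `acc`, tune every method's penalty to the true edge count by
#' [tuneLambdaToSparsity()], and record false positives / negatives over
#' unordered pairs. Means and standard deviations are aggregated per
#' (scenario, method) cell.
#'
#' Under the default `tuning = "calibration"`, the penalty is tuned to the
#' target sparsity on a calibration draw and then applied, fixed, to an
#' independent scoring draw from the same truth; the scored network's edge
#' count therefore fluctuates around the target, so false positives and
#' false negatives can differ (false positives typically slightly exceed
#' false negatives). `tuning = "per-replicate"` tunes on the scored data
#' itself, which pins the edge count to the target and makes the two
#' counts equal whenever the bisection matches exactly.
#'
#' @param scenarios data.frame with columns `p`, `n`, `acc`.
#' @param methods subset of `c("ns-or", "ns-and", "glasso", "wglasso")`.
#' @param replicates number of replicates per scenario (>= 2).
#' @param seed master seed; each replicate draws its own sub-seed.
#' @param tuning `"calibration"` (default) or `"per-replicate"`, see
#'   Details.
#' @param v,u precision construction parameters.
#' @param tol,maxIter solver controls.
#' @return list with `summary` (one row per cell: mean/sd of fp and fn,
#'   replicate count) and `replicates` (per-replicate counts).
#' @export
runBenchmark <- function(scenarios, methods = c("ns-or", "ns-and",
                                                "glasso", "wglasso"),
                         replicates = 100L, seed = 1L,
                         tuning = c("calibration", "per-replicate"),
                         v = 0.3, u = 0.1, tol = 1e-4, maxIter = 200L) {
  if (replicates < 2) stop("'replicates' must be at least 2")
  methods <- match.arg(methods, several.ok = TRUE)
  tuning <- match.arg(tuning)
  rows <- list()
  for (s in seq_len(nrow(scenarios))) {
    p <- scenarios$p[s]; n <- scenarios$n[s]; acc <- scenarios$acc[s]
    seeds <- deriveSeeds(seed + s, replicates)
    for (r in seq_len(replicates)) {
      sub <- deriveSeeds(seeds[r], 4L)
      truth <- buildPrecisionMatrix(generateScaleFreeGraph(p, sub[1]),
                                    v = v, u = u)
      X <- sampleData(sigmaTrue(truth), n, sub[2])
      Xcal <- if (tuning == "calibration")
        sampleData(sigmaTrue(truth), n, sub[4]) else X
      W <- if ("wglasso" %in% methods)
        corruptWeightMatrix(truth, acc, sub[3]) else NULL
      m <- nrow(edgeMatrix(truth))
      for (method in methods) {
        Wm <- if (method == "wglasso") W
        cal <- tuneLambdaToSparsity(Xcal, m, method = method, weights = Wm,
                                    tol = tol, maxIter = maxIter)
        if (tuning == "calibration") {
          fit <- fitAtLambda(X, cal$lambda, method, Wm, tol, maxIter)
          fit$matched <- cal$matched
        } else {
          fit <- cal
        }
        ok <- is.null(fit$estimate) || fit$estimate@converged
        cc <- countFpFn(fit$network, truth)
        rows[[length(rows) + 1L]] <- data.frame(
          p = p, n = n, acc = acc, method = method, replicate = r,
          fp = cc$fp, fn = cc$fn, tp = cc$tp,
          matched = fit$matched, converged = ok)
      }
    }
  }
  reps <- do.call(rbind, rows)
  reps <- finishBenchmark(reps)
  reps
}

# fit one method at a fixed penalty (no tuning)
fitAtLambda <- function(X, lambda, method, weights, tol, maxIter) {
  X <- standardizeColumns(as.matrix(X))
  S <- crossprod(X)
  if (method %in% c("ns-or", "ns-and")) {
    B <- cpp_ns_coef(S, lambda, 1e-7, 1000L, NULL)
    list(network = networkFromNsCoef(B, sub("ns-", "", method)),
         estimate = NULL)
  } else {
    est <- suppressWarnings(
      wglassoFit(S, lambda, weights = weights, tol = tol,
                 maxIter = maxIter))
    list(network = networkFromEstimate(est), estimate = est)
  }
}

finishBenchmark <- function(reps) {
  used <- reps[reps$converged, , drop = FALSE]
  dropped <- sum(!reps$converged)
  if (dropped)
    message(dropped, " non-converged replicate fits excluded")
  key <- interaction(used$p, used$n, used$acc, used$method, drop = TRUE)
  summ <- do.call(rbind, lapply(split(used, key), function(d) {
    data.frame(p = d$p[1], n = d$n[1], acc = d$acc[1], method = d$method[1],
               replicates = nrow(d),
               fpMean = mean(d$fp), fpSd = stats::sd(d$fp),
               fnMean = mean(d$fn), fnSd = stats::sd(d$fn))
  }))
  rownames(summ) <- NULL
  list(summary = summ, replicates = reps)
}
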