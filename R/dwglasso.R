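#' Per-gene Welch t-test significance with BH-FDR control
#'
#' Two-sample t statistics with unequal variances (Welch-Satterthwaite
#' degrees of freedom) for every gene, Benjamini-Hochberg adjustment across
#' genes, and a significance flag at `alpha`. A gene with zero variance in
#' both groups gets p = 1 by convention.
#'
#' @param X expression matrix (samples x genes, named columns).
#' @param groups two-level factor/vector over samples; the first level is
#'   reported as the "high" group.
#' @param alpha FDR threshold (default 0.05).
#' @return data.frame with columns `gene`, `stat`, `p`, `adjP`,
#'   `significant`.
#' @export
welchTSignificance <- function(X, groups, alpha = 0.05) {
  X <- as.matrix(X)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("'groups' must have exactly two levels")
  iA <- groups == levels(groups)[1]
  iB <- groups == levels(groups)[2]
  if (sum(iA) < 2 || sum(iB) < 2)
    stop("both groups need at least 2 samples")
  nA <- sum(iA); nB <- sum(iB)
  mA <- colMeans(X[iA, , drop = FALSE])
  mB <- colMeans(X[iB, , drop = FALSE])
  vA <- apply(X[iA, , drop = FALSE], 2, stats::var)
  vB <- apply(X[iB, , drop = FALSE], 2, stats::var)
  se2 <- vA / nA + vB / nB
  stat <- ifelse(se2 > 0, (mA - mB) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1)), 1)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(stat), df), 1)
  if (any(se2 == 0))
    message(sum(se2 == 0), " gene(s) with zero variance in both groups; ",
            "p set to 1")
  finishSignificance(colnames(X), stat, p, alpha)
}

#' Per-gene concordance-index significance with BH-FDR control
#'
#' Harrell's concordance index between each gene's expression and survival
#' time (a pair of samples is usable when the smaller time is an observed
#' event; tied expression values contribute 1/2). `c` is oriented as the
#' probability that higher expression accompanies longer survival. The
#' p-value is an asymptotic normal test of c = 0.5 using the variance
#' estimate returned by [survival::concordance()], followed by BH
#' adjustment. A constant gene has c = 0.5 and p = 1.
#'
#' @param X expression matrix (samples x genes, named columns).
#' @param time positive survival/follow-up times.
#' @param event binary event indicator (1 = event observed).
#' @param alpha FDR threshold.
#' @return data.frame with columns `gene`, `stat` (the concordance index),
#'   `p`, `adjP`, `significant`.
#' @export
concordanceSignificance <- function(X, time, event, alpha = 0.05) {
  X <- as.matrix(X)
  if (any(time <= 0)) stop("'time' must be positive")
  if (!all(event %in% c(0, 1))) stop("'event' must be binary")
  if (sum(event) == 0) stop("no events: no usable pairs")
  srv <- survival::Surv(time, event)
  res <- apply(X, 2, function(x) {
    fit <- survival::concordance(srv ~ x)
    cidx <- fit$concordance  # oriented: higher expression, longer survival
    v <- fit$var
    z <- if (is.finite(v) && v > 0) (cidx - 0.5) / sqrt(v) else 0
    c(cidx, 2 * stats::pnorm(-abs(z)))
  })
  finishSignificance(colnames(X), res[1, ], res[2, ], alpha)
}

finishSignificance <- function(genes, stat, p, alpha) {
  if (is.null(genes)) genes <- paste0("g", seq_along(stat))
  adjP <- stats::p.adjust(p, method = "BH")
  # alpha >= 1 is the degenerate "keep everything" threshold (adjP can be
  # exactly 1, which a strict inequality would drop)
  flag <- if (alpha >= 1) rep(TRUE, length(adjP)) else adjP < alpha
  data.frame(gene = genes, stat = unname(stat), p = unname(p),
             adjP = unname(adjP), significant = unname(flag),
             row.names = NULL)
}

#' Build the two group-specific wgLASSO networks
#'
#' Fits one weighted graphical LASSO per group on the (already
#' significance-filtered) gene set, each with its own penalty selected by
#' k-fold cross-validation under the one-standard-error rule, and extracts
#' the undirected networks. `weights = NULL` reduces each fit to a plain
#' graphical LASSO (the pipeline with no prior knowledge).
#'
#' @param X expression matrix (samples x genes, named columns).
#' @param groups two-level factor; the first level is the "high" group.
#' @param weights prior weight matrix aligned to `colnames(X)`, or NULL.
#' @param cvFolds folds per group (default 10); each group must have at
#'   least this many samples.
#' @param seed integer seed (fold shuffles per group are derived from it).
#' @param grid optional shared penalty grid; by default each group derives
#'   its own from its correlation matrix.
#' @return list with `networkHigh`, `networkLow` ([GeneNetwork-class]),
#'   `lambdaHigh`, `lambdaLow`, and the two [CVResult-class] objects.
#' @export
buildGroupNetworks <- function(X, groups, weights = NULL, cvFolds = 10L,
                               seed = 1L, grid = NULL) {
  X <- as.matrix(X)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("'groups' must have exactly two levels")
  genes <- colnames(X)
  if (is.null(genes)) genes <- colnames(X) <- paste0("g", seq_len(ncol(X)))
  if (!is.null(weights)) checkWeightMatrix(as.matrix(weights), ncol(X))
  fitGroup <- function(idx) {
    if (sum(idx) < cvFolds)
      stop("a group has fewer samples than 'cvFolds'")
    Xg <- standardizeColumns(X[idx, , drop = FALSE])
    # the same fold-shuffle seed in both groups keeps the procedure
    # symmetric: identical group data yield identical networks
    cv <- tuneLambdaCV(Xg, weights = weights, kFolds = cvFolds,
                       grid = grid, seed = seed)
    est <- wglassoFit(crossprod(Xg), lambdaOpt(cv), weights = weights)
    list(net = networkFromEstimate(est, nodes = genes), cv = cv, est = est)
  }
  hi <- fitGroup(groups == levels(groups)[1])
  lo <- fitGroup(groups == levels(groups)[2])
  list(networkHigh = hi$net, networkLow = lo$net,
       lambdaHigh = lambdaOpt(hi$cv), lambdaLow = lambdaOpt(lo$cv),
       cvHigh = hi$cv, cvLow = lo$cv)
}

#' Differential network scores from two group networks
#'
#' For every gene, `dns = |sd_h - sd_l|`, the absolute difference of its
#' scaled node degrees in the two group-specific networks. Genes are ranked
#' by `dns` in decreasing order; ties are broken by ascending adjusted
#' p-value (when a significance table is supplied), then by gene identifier.
#'
#' @param networkHigh,networkLow [GeneNetwork-class] objects over the same
#'   gene set.
#' @param significance optional data.frame from [welchTSignificance()] or
#'   [concordanceSignificance()] (columns `gene`, `stat`, `p`, `adjP`).
#' @return data.frame with columns `gene`, `stat`, `p`, `adjP`, `dH`, `dL`,
#'   `sdH`, `sdL`, `dns`, `rank`, ordered by rank.
#' @export
differentialNetworkScores <- function(networkHigh, networkLow,
                                      significance = NULL) {
  gH <- nodeNames(networkHigh)
  gL <- nodeNames(networkLow)
  if (!identical(sort(gH), sort(gL)))
    stop("the two networks must share the same gene set")
  ord <- match(gH, gL)
  sdH <- scaledDegrees(networkHigh)
  sdL <- scaledDegrees(networkLow)[ord]
  out <- data.frame(
    gene = gH,
    stat = NA_real_, p = NA_real_, adjP = NA_real_,
    dH = unname(degrees(networkHigh)),
    dL = unname(degrees(networkLow)[ord]),
    sdH = unname(sdH), sdL = unname(sdL),
    dns = unname(abs(sdH - sdL)), row.names = NULL)
  if (!is.null(significance)) {
    m <- match(out$gene, significance$gene)
    out$stat <- significance$stat[m]
    out$p <- significance$p[m]
    out$adjP <- significance$adjP[m]
  }
  o <- order(-out$dns, out$adjP, out$gene)
  out <- out[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Network-based differential gene expression analysis (dwgLASSO)
#'
#' End-to-end pipeline: (1) per-gene significance testing -- Welch t
#' between the two groups, or concordance index against survival time when
#' `time`/`event` are given -- with BH-FDR control at `alpha`; (2) weighted
#' graphical LASSO network per group on the significant genes, penalties
#' tuned independently by cross-validation with the one-standard-error
#' rule; (3) differential network score `dns = |sd_h - sd_l|` per gene and
#' a prioritized table in decreasing `dns` order.
#'
#' @param X expression matrix (samples x genes, named columns).
#' @param groups two-level factor; the first level is the "high" group.
#' @param time,event optional survival input; when supplied, significance
#'   uses the concordance index instead of the Welch t-test.
#' @param weights prior weight matrix over all genes of `X` (rows/columns
#'   for genes without prior evidence zero), or NULL for no prior.
#' @param alpha FDR threshold for the significance stage (default 0.05).
#' @param cvFolds,seed,grid passed to [buildGroupNetworks()].
#' @param topK how many top-ranked genes to report in `topGenes`.
#' @return list with `scores` (the prioritized table), `topGenes`,
#'   `significance` (full table), `networks`
#'   (result of [buildGroupNetworks()]), and the calling parameters.
#' @export
runDwglasso <- function(X, groups, time = NULL, event = NULL,
                        weights = NULL, alpha = 0.05, cvFolds = 10L,
                        seed = 1L, grid = NULL, topK = 10L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("g", seq_len(ncol(X)))
  sig <- if (!is.null(time))
    concordanceSignificance(X, time, event, alpha = alpha)
  else welchTSignificance(X, groups, alpha = alpha)
  keep <- sig$significant
  if (sum(keep) < 2)
    stop("fewer than 2 genes pass the significance threshold (alpha = ",
         alpha, ")")
  genes <- sig$gene[keep]
  Xs <- X[, genes, drop = FALSE]
  Ws <- NULL
  if (!is.null(weights)) {
    W <- as.matrix(weights)
    if (is.null(rownames(W)))
      rownames(W) <- colnames(W) <- colnames(X)
    Ws <- W[genes, genes, drop = FALSE]
  }
  nets <- buildGroupNetworks(Xs, groups, weights = Ws, cvFolds = cvFolds,
                             seed = seed, grid = grid)
  scores <- differentialNetworkScores(nets$networkHigh, nets$networkLow,
                                      significance = sig)
  list(scores = scores,
       topGenes = utils::head(scores$gene, topK),
       significance = sig,
       networks = nets,
       parameters = list(alpha = alpha, cvFolds = cvFolds, seed = seed,
                         topK = topK, prior = !is.null(weights)))
}
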