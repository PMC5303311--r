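#' Generate a scale-free graph by preferential attachment
#'
#' Builds a connected tree on `p` nodes by linear preferential attachment
#' (one new edge per arriving node), the topology commonly used to emulate
#' biological interaction networks, whose degree distributions are
#' heavy-tailed. A tree has `p - 1` edges, so the edge density is exactly
#' `2/p` of the `p(p-1)/2` possible pairs (0.02 at p = 100, 0.004 at
#' p = 500).
#'
#' @param p number of nodes (at least 3).
#' @param seed integer seed; the result is deterministic given the seed.
#' @return symmetric binary adjacency matrix with zero diagonal.
#' @export
generateScaleFreeGraph <- function(p, seed = 1L) {
  if (!is.numeric(p) || length(p) != 1 || p < 3)
    stop("'p' must be a single integer >= 3")
  p <- as.integer(p)
  g <- withSeed(seed, igraph::sample_pa(p, power = 1, m = 1,
                                        directed = FALSE))
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  A[A > 1] <- 1
  dimnames(A) <- NULL
  storage.mode(A) <- "double"
  A
}

#' Build a true precision matrix on a given topology
#'
#' Places magnitude `v` on every adjacent off-diagonal entry, sets the
#' diagonal to the absolute value of the most negative eigenvalue of that
#' off-diagonal part plus `0.1 + u` (guaranteeing positive definiteness),
#' inverts to a covariance, rescales the covariance to a correlation matrix
#' and recomputes the precision matrix of the rescaled covariance. The
#' rescaling is applied analytically (`theta_ij * s_i * s_j` with
#' `s_i = sqrt(Sigma_ii)`), so the support is preserved exactly.
#'
#' @param adjacency symmetric binary matrix, zero diagonal.
#' @param v off-diagonal magnitude (default 0.3).
#' @param u diagonal boost (default 0.1).
#' @return a [PrecisionTruth-class] object.
#' @export
buildPrecisionMatrix <- function(adjacency, v = 0.3, u = 0.1) {
  if (!is.matrix(adjacency) || !isSymmetric(unname(adjacency)))
    stop("'adjacency' must be a symmetric matrix")
  if (any(diag(adjacency) != 0) || !all(adjacency %in% c(0, 1)))
    stop("'adjacency' must be binary with zero diagonal")
  A <- unname(adjacency)
  truthFromOmega(v * A, A, u)
}

# Shared construction: given the off-diagonal part of Omega (possibly with
# heterogeneous magnitudes) and its support, set the diagonal for positive
# definiteness, rescale to a correlation model and package the truth.
truthFromOmega <- function(omega, A, u) {
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  diag(omega) <- abs(min(ev)) + 0.1 + u
  sigma <- solve(omega)
  s <- sqrt(diag(sigma))
  sigmaCor <- sigma / tcrossprod(s)      # cov2cor
  theta <- omega * tcrossprod(s)         # inverse of the correlation matrix
  theta <- (theta + t(theta)) / 2
  sigmaCor <- (sigmaCor + t(sigmaCor)) / 2
  diag(sigmaCor) <- 1
  new("PrecisionTruth", adjacency = A, thetaTrue = theta,
      sigmaTrue = sigmaCor, edges = edgePairs(A))
}

#' Sample multivariate normal expression data
#'
#' Draws `n` i.i.d. rows from N(0, `sigma`), then centers each column and
#' scales it to unit sum of squares, the convention under which the Gram
#' matrix `t(X) %*% X` is the sample correlation matrix used by the
#' penalized likelihood.
#'
#' @param sigma true covariance (positive definite).
#' @param n sample count (at least 2).
#' @param seed integer seed.
#' @return n x p data matrix with zero column sums and unit column sums of
#'   squares.
#' @export
sampleData <- function(sigma, n, seed = 1L) {
  if (n < 2) stop("'n' must be at least 2")
  if (is(sigma, "PrecisionTruth")) sigma <- sigmaTrue(sigma)
  X <- withSeed(seed,
    MASS::mvrnorm(n = n, mu = rep(0, nrow(sigma)), Sigma = sigma))
  standardizeColumns(X)
}

#' Corrupt a prior weight matrix to a given accuracy
#'
#' Emulates an interaction database holding spurious entries. The returned
#' matrix has exactly as many nonzero pairs as the truth has edges;
#' `round((1 - acc) * m)` of them (round half up) are uniformly sampled
#' non-edges with confidence scores drawn from U(0, 0.5), the remaining
#' pairs are true edges with scores drawn from U(0, 1). `acc = 1` keeps the
#' support equal to the true edge set.
#'
#' @param truth a [PrecisionTruth-class] object with at least one edge.
#' @param acc fraction of the support that is correct, in (0, 1].
#' @param seed integer seed.
#' @return symmetric p x p weight matrix with entries in `[0, 1]` and zero
#'   diagonal.
#' @export
corruptWeightMatrix <- function(truth, acc, seed = 1L) {
  if (!is.numeric(acc) || length(acc) != 1 || acc <= 0 || acc > 1)
    stop("'acc' must lie in (0, 1]")
  A <- adjacency(truth)
  p <- nrow(A)
  trueEdges <- edgeMatrix(truth)
  m <- nrow(trueEdges)
  if (m < 1) stop("truth must have at least one edge")
  nonEdges <- edgePairs(1 - A - diag(p))
  nIncorrect <- roundHalfUp((1 - acc) * m)
  nCorrect <- m - nIncorrect
  withSeed(seed, {
    keep <- trueEdges[sample.int(m, nCorrect), , drop = FALSE]
    wrong <- nonEdges[sample.int(nrow(nonEdges), nIncorrect), , drop = FALSE]
    W <- matrix(0, p, p)
    W[keep] <- runif(nCorrect, 0, 1)
    W[wrong] <- runif(nIncorrect, 0, 0.5)
    W[lower.tri(W)] <- t(W)[lower.tri(W)]
    W
  })
}

#' Generate two-group data with planted differential hubs
#'
#' Builds a shared scale-free backbone, then plants `nDifferentialHubs`
#' nodes that gain `extraEdges` additional partners in exactly one of the
#' two groups (alternating between groups), so their true scaled node
#' degree differs between groups while the backbone stays common. The
#' planted hub edges carry precision magnitude `vHub` (stronger than the
#' backbone's `v`), emulating a regulator whose interactions are both new
#' and strong in one condition; with the defaults the planted partial
#' correlations are about 0.37 versus about 0.19 on the backbone. Each
#' group's precision matrix and Gaussian data are then generated as in the
#' single-group simulator.
#'
#' @param p number of genes (>= 10).
#' @param nPerGroup samples per group (>= 10).
#' @param nDifferentialHubs number of planted hubs (< p).
#' @param seed integer seed.
#' @param extraEdges extra partners per planted hub (default 14).
#' @param vHub precision magnitude on planted hub edges (default 0.6).
#' @param v,u precision construction parameters, see
#'   [buildPrecisionMatrix()].
#' @return list with elements `xA`, `xB` (data matrices) and `truth`
#'   (a [TwoGroupTruth-class]).
#' @export
generateTwoGroupData <- function(p, nPerGroup, nDifferentialHubs, seed = 1L,
                                 extraEdges = 14L, vHub = 0.6, v = 0.3,
                                 u = 0.1) {
  if (p < 10) stop("'p' must be at least 10")
  if (nPerGroup < 10) stop("'nPerGroup' must be at least 10")
  if (nDifferentialHubs >= p)
    stop("'nDifferentialHubs' must be smaller than 'p'")
  seeds <- deriveSeeds(seed, 4L)
  A0 <- generateScaleFreeGraph(p, seeds[1])
  adjA <- A0
  adjB <- A0
  extraA <- matrix(0, p, p)
  extraB <- matrix(0, p, p)
  hubs <- integer(0)
  if (nDifferentialHubs > 0) {
    withSeed(seeds[2], {
      # plant hubs at peripheral backbone nodes (degree <= 2), so the
      # rewiring actually moves their scaled degree; established backbone
      # hubs would stay near the degree maximum in both groups
      deg0 <- rowSums(A0)
      candidates <- which(deg0 <= 2)
      if (length(candidates) < nDifferentialHubs)
        candidates <- order(deg0)[seq_len(nDifferentialHubs)]
      hubs <- sort(candidates[sample.int(length(candidates),
                                         nDifferentialHubs)])
      # cap the boost so the two groups keep >= 70% of their edge union in
      # common (backbone m = p - 1 edges, extras at most 3m/7 in total)
      extraEdges <- max(1L, min(extraEdges,
                                floor((p - 1) * 3 / 7) %/%
                                  nDifferentialHubs))
      for (k in seq_along(hubs)) {
        h <- hubs[k]
        inA <- k %% 2 == 1
        adj <- if (inA) adjA else adjB
        candidates <- setdiff(which(adj[h, ] == 0), h)
        add <- candidates[sample.int(length(candidates),
                                     min(extraEdges, length(candidates)))]
        adj[h, add] <- 1
        adj[add, h] <- 1
        if (inA) {
          adjA <- adj
          extraA[h, add] <- extraA[add, h] <- 1
        } else {
          adjB <- adj
          extraB[h, add] <- extraB[add, h] <- 1
        }
      }
    })
  }
  truthA <- truthFromOmega(v * adjA + (vHub - v) * extraA, adjA, u)
  truthB <- truthFromOmega(v * adjB + (vHub - v) * extraB, adjB, u)
  sdA <- scaledDegreeOf(adjA)
  sdB <- scaledDegreeOf(adjB)
  truth <- new("TwoGroupTruth", truthA = truthA, truthB = truthB,
               differentialNodes = as.integer(hubs),
               trueDns = abs(sdA - sdB))
  xA <- sampleData(sigmaTrue(truthA), nPerGroup, seeds[3])
  xB <- sampleData(sigmaTrue(truthB), nPerGroup, seeds[4])
  colnames(xA) <- colnames(xB) <- paste0("g", seq_len(p))
  list(xA = xA, xB = xB, truth = truth)
}

# degree / max degree from an adjacency matrix
scaledDegreeOf <- function(A) {
  d <- rowSums(A != 0)
  if (max(d) == 0) return(rep(0, nrow(A)))
  d / max(d)
}
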