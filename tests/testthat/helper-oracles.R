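# Shared fixtures and independent oracles.

# random positive-definite correlation-like matrix
randomCovariance <- function(p, n = 10 * p, seed = 1) {
  set.seed(seed)
  stats::cor(matrix(stats::rnorm(n * p), n, p))
}

# random symmetric weight matrix in [0,1], zero diagonal
randomWeights <- function(p, seed = 1) {
  set.seed(seed)
  W <- matrix(stats::runif(p * p), p, p)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

# Penalized negative log-likelihood of the weighted problem (infinite
# outside the positive-definite cone).
wglassoObjective <- function(Th, S, lambda, W = NULL,
                             penalizeDiagonal = TRUE) {
  p <- nrow(S)
  if (is.null(W)) W <- matrix(0, p, p)
  L <- lambda * (1 - W)
  diag(L) <- if (penalizeDiagonal) lambda else 0
  ev <- eigen(Th, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) return(Inf)
  -determinant(Th, logarithm = TRUE)$modulus[1] + sum(S * Th) +
    sum(L * abs(Th))
}

# Brute-force minimizer of the weighted objective over symmetric matrices
# (Nelder-Mead on the upper-triangular parameterization, multi-start).
# Only usable for p <= 4.
bruteForceObjective <- function(S, lambda, W = NULL,
                                penalizeDiagonal = TRUE, starts = NULL) {
  p <- nrow(S)
  ut <- upper.tri(diag(p), diag = TRUE)
  toTheta <- function(v) {
    Th <- matrix(0, p, p)
    Th[ut] <- v
    Th + t(Th) - diag(diag(Th))
  }
  f <- function(v) wglassoObjective(toTheta(v), S, lambda, W,
                                    penalizeDiagonal)
  if (is.null(starts))
    starts <- list(diag(p)[ut], solve(S + lambda * diag(p))[ut],
                   (2 * diag(p))[ut])
  best <- Inf
  for (v0 in starts) {
    o <- stats::optim(v0, f, method = "Nelder-Mead",
                      control = list(maxit = 50000, reltol = 1e-14))
    # Nelder-Mead restarts: re-expand the simplex around the incumbent
    # until no further improvement
    repeat {
      o2 <- stats::optim(o$par, f, method = "Nelder-Mead",
                         control = list(maxit = 50000, reltol = 1e-14))
      if (o$value - o2$value < 1e-9) { o <- o2; break }
      o <- o2
    }
    if (o$value < best) best <- o$value
  }
  best
}

# O(n^2) Harrell concordance between expression x and survival (time,
# event): a pair is usable iff the smaller time is an observed event;
# concordant when the longer-lived sample has the higher expression; ties
# in expression count 1/2.
concordanceByEnumeration <- function(x, time, event) {
  n <- length(x)
  num <- 0
  den <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- if (time[i] < time[j]) i else j
      b <- if (time[i] < time[j]) j else i
      if (time[i] == time[j]) next
      if (event[a] == 0) next       # shorter time censored: unusable
      den <- den + 1
      if (x[b] > x[a]) num <- num + 1
      else if (x[b] == x[a]) num <- num + 0.5
    }
  }
  num / den
}

# build a GeneNetwork with a prescribed edge list (any orientation)
networkFromPairs <- function(pairs, nodes) {
  if (nrow(pairs)) {
    pairs <- cbind(pmin(pairs[, 1], pairs[, 2]),
                   pmax(pairs[, 1], pairs[, 2]))
    pairs <- unique(pairs)
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  }
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  dwglasso:::makeGeneNetwork(pairs, nodes)
}

# a PrecisionEstimate wrapper around a given theta matrix (for support /
# degree extraction tests)
estimateFromTheta <- function(Th, lambda = 0.1) {
  new("PrecisionEstimate", thetaHat = Th, sigmaHat = solve(Th),
      lambda = lambda, weights = NULL, penalizeDiagonal = TRUE,
      objectiveValue = NA_real_, converged = TRUE, iterations = 1L)
}
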