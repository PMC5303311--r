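test_that("all-ones weights with unpenalized diagonal recover the MLE", {
  S <- randomCovariance(5, seed = 21)
  W1 <- matrix(1, 5, 5)
  diag(W1) <- 0
  fit <- wglassoFit(S, 0.4, weights = W1, penalizeDiagonal = FALSE,
                    tol = 1e-8)
  expect_lt(max(abs(thetaHat(fit) - solve(S))), 1e-6)
})

test_that("a dominating penalty empties the network", {
  S <- randomCovariance(6, seed = 22)
  lam <- max(abs(S[upper.tri(S)])) * 1.01
  fit <- glassoFit(S, lam, tol = 1e-8)
  Th <- thetaHat(fit)
  expect_equal(sum(abs(Th[upper.tri(Th)]) > 1e-12), 0)
  # penalized diagonal fixes sigmaHat_ii = S_ii + lambda
  expect_lt(max(abs(diag(sigmaHat(fit)) - (diag(S) + lam))), 1e-10)
  net <- networkFromEstimate(fit)
  expect_equal(nrow(edgeMatrix(net)), 0)
  expect_equal(unname(scaledDegrees(net)), rep(0, 6))
})

test_that("the unweighted fit is the zero-weight special case, exactly", {
  S <- randomCovariance(6, seed = 23)
  f1 <- glassoFit(S, 0.2)
  f2 <- wglassoFit(S, 0.2, weights = matrix(0, 6, 6))
  expect_identical(thetaHat(f1), thetaHat(f2))
  expect_identical(f1@objectiveValue, f2@objectiveValue)
})

test_that("p = 2 entries follow the analytic soft-threshold solution", {
  s <- 0.5
  S <- matrix(c(1, s, s, 1), 2)
  fb <- glassoFit(S, 0.6, tol = 1e-10)      # lambda > |s|: no edge
  expect_identical(thetaHat(fb)[1, 2], 0)
  fa <- glassoFit(S, 0.4, tol = 1e-10)      # lambda < |s|: edge survives
  # closed form: sigma12 = s - lambda, diagonal S_ii + lambda
  sig12 <- s - 0.4
  thOracle <- solve(matrix(c(1.4, sig12, sig12, 1.4), 2))
  expect_lt(max(abs(thetaHat(fa) - thOracle)), 1e-8)
})

test_that("objective value matches a brute-force minimizer for small p", {
  for (seed in 1:4) {
    p <- if (seed %% 2) 3 else 4
    S <- randomCovariance(p, seed = 30 + seed)
    W <- randomWeights(p, seed = 40 + seed)
    fit <- wglassoFit(S, 0.2, weights = W, tol = 1e-9)
    oracle <- bruteForceObjective(S, 0.2, W)
    expect_lt(abs(fit@objectiveValue - oracle), 1e-4)
    # oracle is a minimum: the solver can't be beaten beyond tolerance
    expect_gt(oracle - fit@objectiveValue, -1e-4)
  }
})

test_that("KKT subgradient certificate holds on random instances", {
  set.seed(77)
  for (rep in 1:15) {
    p <- sample(c(3, 5, 10), 1)
    S <- randomCovariance(p, seed = 100 + rep)
    W <- if (rep %% 2) randomWeights(p, seed = 200 + rep) else NULL
    lam <- stats::runif(1, 0.05, 0.5)
    fit <- wglassoFit(S, lam, weights = W, tol = 1e-7)
    expect_lt(kktViolation(fit, S), 1e-5)
    expect_true(fit@converged)
    expect_lt(max(abs(thetaHat(fit) - t(thetaHat(fit)))), 1e-8)
  }
})

test_that("edge count decreases monotonically along the penalty path", {
  tr <- buildPrecisionMatrix(generateScaleFreeGraph(20, seed = 31))
  X <- sampleData(tr, 60, seed = 32)
  S <- crossprod(X)
  grid <- lambdaGrid(S, length = 50)
  edges <- integer(length(grid))
  warm <- NULL
  for (g in seq_along(grid)) {
    fit <- glassoFit(S, grid[g], warmStart = warm)
    warm <- fit
    edges[g] <- nrow(edgeMatrix(networkFromEstimate(fit)))
  }
  expect_true(all(diff(edges) >= 0))       # grid descends, edges grow
})

test_that("estimates are equivariant under variable permutation", {
  p <- 8
  S <- randomCovariance(p, seed = 33)
  W <- randomWeights(p, seed = 34)
  perm <- sample(p)
  f1 <- wglassoFit(S, 0.15, weights = W, tol = 1e-8)
  f2 <- wglassoFit(S[perm, perm], 0.15, weights = W[perm, perm], tol = 1e-8)
  expect_lt(max(abs(thetaHat(f1)[perm, perm] - thetaHat(f2))), 1e-8)
})

test_that("the zero-penalty singular problem raises a singularity error", {
  set.seed(66)
  X <- matrix(rnorm(3 * 10), 3, 10)        # n < p: singular Gram
  S <- crossprod(scale(X, scale = FALSE))
  S <- S / max(diag(S))
  expect_error(glassoFit(S, 0), "singular")
})

test_that("neighbor selection matches glmnet coefficients", {
  skip_if_not_installed("glmnet")
  set.seed(55)
  n <- 40; p <- 7
  X <- dwglasso:::standardizeColumns(matrix(rnorm(n * p), n, p))
  lam <- 0.12
  B <- dwglasso:::nsCoefficients(X, lam)
  for (j in 1:p) {
    g <- glmnet::glmnet(X[, -j], X[, j], lambda = lam / n,
                        standardize = FALSE, intercept = FALSE,
                        thresh = 1e-12)
    full <- numeric(p)
    full[-j] <- as.numeric(stats::coef(g))[-1]
    expect_lt(max(abs(full - B[, j])), 1e-6)
  }
})

test_that("the and-rule network is nested in the or-rule network", {
  tr <- buildPrecisionMatrix(generateScaleFreeGraph(15, seed = 41))
  X <- sampleData(tr, 40, seed = 42)
  for (lam in c(0.05, 0.15, 0.3)) {
    netOr <- neighborSelectionFit(X, lam, rule = "or")
    netAnd <- neighborSelectionFit(X, lam, rule = "and")
    eOr <- paste(edgeMatrix(netOr)[, 1], edgeMatrix(netOr)[, 2])
    eAnd <- paste(edgeMatrix(netAnd)[, 1], edgeMatrix(netAnd)[, 2])
    expect_true(all(eAnd %in% eOr))
  }
  # a penalty beyond every per-regression critical value empties both
  S <- crossprod(dwglasso:::standardizeColumns(X))
  lamBig <- max(abs(S[upper.tri(S)])) * 1.05
  expect_equal(nrow(edgeMatrix(neighborSelectionFit(X, lamBig, "or"))), 0)
  expect_error(neighborSelectionFit(cbind(X, 1), 0.1), "constant")
})

test_that("neighbor selection recovers a 3-node path at tuned sparsity", {
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1
  tr <- buildPrecisionMatrix(A)
  hits <- 0
  for (s in 1:100) {
    X <- sampleData(tr, 50, seed = 500 + s)
    fit <- suppressWarnings(
      tuneLambdaToSparsity(X, 2, method = "ns-or"))
    E <- edgeMatrix(fit$network)
    ok <- nrow(E) == 2 &&
      all(paste(E[, 1], E[, 2]) %in% c("1 2", "2 3"))
    hits <- hits + ok
  }
  expect_gte(hits, 90)
})

test_that("network extraction computes degrees and scaled degrees", {
  # diagonal estimate: empty network
  est0 <- estimateFromTheta(diag(4))
  net0 <- networkFromEstimate(est0)
  expect_equal(nrow(edgeMatrix(net0)), 0)
  expect_equal(unname(degrees(net0)), rep(0L, 4))
  expect_equal(unname(scaledDegrees(net0)), rep(0, 4))
  # star on 5 nodes: hub scaled degree 1, leaves 1/4
  Th <- diag(5) * 2
  Th[1, 2:5] <- Th[2:5, 1] <- -0.3
  net <- networkFromEstimate(estimateFromTheta(Th))
  expect_equal(unname(scaledDegrees(net)), c(1, .25, .25, .25, .25))
  expect_equal(unname(degrees(net)), c(4L, 1L, 1L, 1L, 1L))
})

test_that("scaled degree 2/7 reproduces the printed three-decimal value", {
  # a gene of degree 2 in a network whose maximum degree is 7
  nodes <- paste0("n", 1:9)
  pairs <- rbind(cbind(1L, 2:8),        # n1 is the degree-7 hub
                 cbind(2L, 9L))        # n2 has degree 2
  net <- networkFromPairs(pairs, nodes)
  expect_equal(unname(degrees(net)[1:2]), c(7L, 2L))
  expect_equal(round(unname(scaledDegrees(net)[2]), 3), 0.286)
})
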