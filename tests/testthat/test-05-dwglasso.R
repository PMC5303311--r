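test_that("Welch t raw p-values are calibrated under the null", {
  set.seed(81)
  flagged <- 0
  total <- 0
  for (r in 1:50) {
    X <- matrix(rnorm(40 * 200), 40, 200)
    colnames(X) <- paste0("g", 1:200)
    sig <- welchTSignificance(X, rep(c("a", "b"), each = 20))
    flagged <- flagged + sum(sig$p < 0.05)
    total <- total + 200
  }
  expect_gte(flagged / total, 0.03)
  expect_lte(flagged / total, 0.07)
})

test_that("a 3-SD shift is detected essentially always", {
  hits <- sapply(1:20, function(s) {
    set.seed(900 + s)
    X <- matrix(rnorm(60 * 200), 60, 200)
    colnames(X) <- paste0("g", 1:200)
    X[1:30, 1] <- X[1:30, 1] + 3
    sig <- welchTSignificance(X, rep(c("a", "b"), each = 30))
    sig$significant[1]
  })
  expect_gte(mean(hits), 0.99)
})

test_that("BH adjustment and degenerate genes follow the conventions", {
  out <- dwglasso:::finishSignificance(paste0("g", 1:4), 1:4,
                                       c(0.01, 0.02, 0.03, 0.04), 0.05)
  expect_equal(out$adjP, rep(0.04, 4))
  expect_true(all(out$adjP >= out$p))
  # zero variance in both groups: p = 1 by convention
  X <- cbind(gA = rep(1, 20), gB = rnorm(20))
  expect_message(
    sig <- welchTSignificance(X, rep(c("a", "b"), each = 10)),
    "zero variance")
  expect_equal(sig$p[sig$gene == "gA"], 1)
  expect_error(welchTSignificance(X[1:3, ], rep(c("a", "b"), c(2, 1))),
               "at least 2")
})

test_that("concordance significance matches the enumeration oracle", {
  set.seed(83)
  n <- 40
  time <- rexp(n) + 0.1
  event <- rbinom(n, 1, 0.7)
  X <- cbind(gA = rnorm(n), gB = 0.8 * time + rnorm(n, sd = 0.4))
  sig <- concordanceSignificance(X, time, event)
  for (g in 1:2) {
    cOracle <- concordanceByEnumeration(X[, g], time, event)
    expect_equal(sig$stat[g], cOracle, tolerance = 1e-10)
  }
  expect_lt(sig$adjP[2], 0.05)      # gB tracks survival
})

test_that("concordance handles perfect, constant and null genes", {
  n <- 60
  time <- seq_len(n) + 0.5
  event <- rep(1, n)
  X <- cbind(perfect = time, const = rep(2, n))
  sig <- concordanceSignificance(X, time, event)
  expect_equal(sig$stat[1], 1.0)
  expect_equal(sig$stat[2], 0.5)   # all pairs tied: 1/2 each
  expect_equal(sig$p[2], 1)
  # independence: c near 1/2 at large n
  set.seed(84)
  tBig <- rexp(500) + 0.1
  XBig <- cbind(g = rnorm(500))
  s2 <- concordanceSignificance(XBig, tBig, rep(1, 500))
  expect_lt(abs(s2$stat - 0.5), 0.05)
  expect_error(concordanceSignificance(XBig, -tBig, rep(1, 500)), "positive")
  expect_error(concordanceSignificance(XBig, tBig, rep(0, 500)), "events")
})

test_that("dns is the absolute scaled-degree difference, ranked", {
  # build two networks giving sd pairs (0.286, 0.778) and (1.0, 0.444)
  nodes <- paste0("n", 1:12)
  # high: max degree 7 via n2; n1 degree 2
  eH <- rbind(cbind(2L, c(3L, 4L, 5L, 6L, 7L, 8L, 9L)),
              cbind(1L, c(10L, 11L)))
  netH <- networkFromPairs(eH, nodes)
  # low: max degree 9 via n3; n1 degree 7; n2 degree 4
  eL <- rbind(cbind(3L, c(1L, 2L, 4L, 5L, 6L, 7L, 8L, 9L, 10L)),
              cbind(1L, c(4L, 5L, 6L, 7L, 11L, 12L)),
              cbind(2L, c(10L, 11L, 12L)))
  netL <- networkFromPairs(eL, nodes)
  expect_equal(unname(degrees(netH)[1:2]), c(2L, 7L))
  expect_equal(unname(degrees(netL)[1:3]), c(7L, 4L, 9L))
  sc <- differentialNetworkScores(netH, netL)
  r1 <- sc[sc$gene == "n1", ]
  r2 <- sc[sc$gene == "n2", ]
  expect_equal(round(c(r1$sdH, r1$sdL), 3), c(0.286, 0.778))
  expect_equal(round(r1$dns, 3), 0.492)
  expect_equal(round(c(r2$sdH, r2$sdL), 3), c(1.0, 0.444))
  expect_equal(round(r2$dns, 3), 0.556)
  # group-label symmetry and range
  scSwap <- differentialNetworkScores(netL, netH)
  expect_equal(sort(sc$dns), sort(scSwap$dns))
  expect_true(all(sc$dns >= 0 & sc$dns <= 1))
  expect_equal(sc$rank, seq_len(nrow(sc)))
  expect_true(all(diff(sc$dns) <= 0))
})

test_that("identical networks give all-zero scores ranked by adjusted p", {
  nodes <- paste0("g", 1:5)
  pairs <- rbind(c(1L, 2L), c(2L, 3L))
  net <- networkFromPairs(pairs, nodes)
  sig <- data.frame(gene = nodes, stat = 1:5,
                    p = c(0.5, 0.01, 0.2, 0.03, 0.9),
                    adjP = c(0.5, 0.05, 0.25, 0.07, 0.9))
  sc <- differentialNetworkScores(net, net, sig)
  expect_true(all(sc$dns == 0))
  expect_equal(sc$gene, c("g2", "g4", "g3", "g1", "g5"))
  bad <- networkFromPairs(pairs, paste0("x", 1:5))
  expect_error(differentialNetworkScores(net, bad), "gene set")
})

test_that("group networks are reproducible and respect the W = 0 reduction", {
  tg <- generateTwoGroupData(20, 24, 0, seed = 91)
  X <- rbind(tg$xA, tg$xA)              # identical data in both groups
  colnames(X) <- paste0("g", 1:20)
  groups <- rep(c("h", "l"), each = 24)
  nets <- buildGroupNetworks(X, groups, cvFolds = 4, seed = 92)
  expect_identical(edgeMatrix(nets$networkHigh),
                   edgeMatrix(nets$networkLow))
  # an explicit zero weight matrix equals the no-prior call
  W0 <- matrix(0, 20, 20)
  netsW <- buildGroupNetworks(X, groups, weights = W0, cvFolds = 4,
                              seed = 92)
  expect_identical(edgeMatrix(nets$networkHigh),
                   edgeMatrix(netsW$networkHigh))
  expect_equal(nets$lambdaHigh, netsW$lambdaHigh)
  expect_error(buildGroupNetworks(X, groups, cvFolds = 30, seed = 1),
               "fewer samples")
})

test_that("the pipeline runs end to end and is byte-reproducible", {
  tg <- generateTwoGroupData(30, 20, 2, seed = 93)
  X <- rbind(tg$xA, tg$xB)
  groups <- factor(rep(c("A", "B"), each = 20))
  grid <- lambdaGrid(crossprod(dwglasso:::standardizeColumns(X)),
                     length = 8, ratio = 0.2)
  r1 <- runDwglasso(X, groups, alpha = 1.0, cvFolds = 4, seed = 94,
                    grid = grid, topK = 5)
  r2 <- runDwglasso(X, groups, alpha = 1.0, cvFolds = 4, seed = 94,
                    grid = grid, topK = 5)
  expect_identical(r1$scores, r2$scores)
  expect_length(r1$topGenes, 5)
  expect_equal(nrow(r1$scores), 30)     # alpha = 1 keeps every gene
  expect_true(all(r1$scores$dns >= 0 & r1$scores$dns <= 1))
  # too strict a threshold aborts with a clear message
  set.seed(95)
  Xnull <- matrix(rnorm(40 * 10), 40, 10,
                  dimnames = list(NULL, paste0("g", 1:10)))
  expect_error(runDwglasso(Xnull, rep(c("A", "B"), each = 20),
                           alpha = 1e-6),
               "fewer than 2")
})

test_that("the prior changes networks but never the significance stage", {
  tg <- generateTwoGroupData(25, 20, 1, seed = 96)
  X <- rbind(tg$xA, tg$xB)
  groups <- factor(rep(c("A", "B"), each = 20))
  grid <- lambdaGrid(crossprod(dwglasso:::standardizeColumns(X)),
                     length = 8, ratio = 0.2)
  W <- corruptWeightMatrix(tg$truth@truthA, 0.9, seed = 97)
  rownames(W) <- colnames(W) <- colnames(X)
  rNo <- runDwglasso(X, groups, alpha = 1.0, cvFolds = 4, seed = 98,
                     grid = grid)
  rW <- runDwglasso(X, groups, weights = W, alpha = 1.0, cvFolds = 4,
                    seed = 98, grid = grid)
  expect_identical(rNo$significance, rW$significance)
})
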