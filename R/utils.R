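# Internal helpers.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("'seed' must be a single integer")
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive reproducible sub-stream seeds from one master seed.
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# round() uses round-half-even; the corruption count uses round-half-up.
roundHalfUp <- function(x) floor(x + 0.5)

# Edge list (i < j) from the upper triangle of a logical/0-1 matrix.
edgePairs <- function(A) {
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(matrix(integer(), 0, 2, dimnames = list(NULL, c("i", "j"))))
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  dimnames(idx) <- list(NULL, c("i", "j"))
  idx
}

adjacencyFromPairs <- function(pairs, p) {
  A <- matrix(0, p, p)
  if (nrow(pairs)) {
    A[pairs] <- 1
    A[pairs[, c(2, 1), drop = FALSE]] <- 1
  }
  A
}

checkWeightMatrix <- function(w, p = nrow(w)) {
  if (!is.matrix(w) || nrow(w) != p || ncol(w) != p)
    stop("weight matrix must be a square matrix matching the data dimension")
  if (max(abs(w - t(w))) > 1e-12) stop("weight matrix must be symmetric")
  if (min(w) < 0 || max(w) > 1) stop("weights must lie in [0, 1]")
  invisible(w)
}

# Center columns and scale each to unit sum of squares.
standardizeColumns <- function(X) {
  X <- sweep(X, 2, colMeans(X), "-")
  ss <- sqrt(colSums(X^2))
  if (any(ss == 0)) stop("constant column cannot be standardized")
  sweep(X, 2, ss, "/")
}
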