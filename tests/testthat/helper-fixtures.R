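# Shared fixtures, built in code at test time.

# Small complete family population with both growth traits.
smallPop <- function(nMarkers = 600, nFamilies = 6, nSampled = 60,
                     offspringPerFamily = 12, seed = 42,
                     nQtl = max(10, nMarkers %/% 6), ...) {
  simulatePopulation(nMarkers = nMarkers, nFamilies = nFamilies,
                     nSampled = nSampled,
                     offspringPerFamily = offspringPerFamily,
                     nQtl = nQtl, seed = seed, ...)
}

# Unstructured genotypes: independent HWE markers, unrelated individuals.
unrelatedGenotypes <- function(n, m, maf = NULL, seed = 1) {
  set.seed(seed)
  p <- if (is.null(maf)) runif(m, 0.1, 0.5) else rep_len(maf, m)
  d <- sapply(p, function(pp) rbinom(n, 2, pp))
  genotypeData(matrix(d, nrow = n))
}

# Independent brute-force restricted likelihood (direct solve/determinant
# route, no eigen-rotation) for the animal model with intercept only.
bruteForceREMLGrid <- function(G, y, h2grid = seq(0, 1, by = 0.01)) {
  n <- length(y)
  X <- matrix(1, n, 1)
  ll <- sapply(h2grid, function(hh) suppressWarnings({
    V <- hh * G + (1 - hh) * diag(n)
    Vi <- tryCatch(solve(V), error = function(e) NULL)
    if (is.null(Vi)) return(-Inf)
    XtViX <- as.numeric(t(X) %*% Vi %*% X)
    beta <- as.numeric(t(X) %*% Vi %*% y) / XtViX
    r <- y - beta
    q <- as.numeric(t(r) %*% Vi %*% r)
    s2 <- q / (n - 1)
    ld <- determinant(V, logarithm = TRUE)$modulus
    val <- -0.5 * ((n - 1) * (log(2 * pi) + log(s2) + 1) + ld + log(XtViX))
    if (!is.finite(val)) -Inf else val
  }))
  list(h2 = h2grid[which.max(ll)], ll = ll, grid = h2grid)
}

# Adjusted Rand index between two labelings (direct contingency formula).
adjustedRandIndex <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  sumi <- sum(choose(rowSums(tab), 2))
  sumj <- sum(choose(colSums(tab), 2))
  expected <- sumi * sumj / choose(n, 2)
  maxidx <- (sumi + sumj) / 2
  (sumij - expected) / (maxidx - expected)
}

# Batch-means Monte-Carlo standard error of posterior means from stored
# thinned Gibbs samples.
batchSE <- function(samples, nBatch = 20) {
  n <- nrow(samples)
  idx <- cut(seq_len(n), nBatch, labels = FALSE)
  bm <- apply(samples, 2, function(v) tapply(v, idx, mean))
  apply(bm, 2, sd) / sqrt(nBatch)
}

# Standardized deviations of posterior means from a closed form should
# behave like unit-scale Monte-Carlo noise: essentially all within 3 SE
# (allowing the expected tail exceedances of a 3-sigma band), none far
# outside it, and the aggregate size consistent with the SEs.
expectWithinMcError <- function(est, truth, se) {
  r <- abs(est - truth) / (se + 1e-12)
  expect_lte(sum(r > 3), max(1, round(0.01 * length(r))))
  expect_lt(max(r), 4)
  expect_lt(sqrt(sum((est - truth)^2)), 3 * sqrt(sum(se^2)))
}
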