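# RR-BLUP closed form, the GBLUP equivalence, the two Gibbs samplers and
# GEBV prediction.

test_that("RR-BLUP matches a direct linear-solve oracle on a small design", {
  d <- matrix(c(0, 1, 2, 1, 0,
                2, 2, 0, 1, 1,
                0, 0, 1, 2, 2), 5, 3)
  rownames(d) <- paste0("i", 1:5)
  colnames(d) <- paste0("m", 1:3)
  y <- c(3.1, 4.0, 2.2, 5.5, 4.8)
  g <- genotypeData(d)
  vr <- 2.5          # V_E / V_A on the G scale
  fit <- fitRRBLUP(g, y, varianceRatio = vr)
  p <- colMeans(d) / 2
  lambda <- vr * 2 * sum(p * (1 - p))
  Z <- sweep(d, 2, colMeans(d))
  oracle <- solve(crossprod(Z) + diag(lambda, 3), crossprod(Z, y - mean(y)))
  expect_equal(unname(markerEffects(fit)), as.vector(oracle),
               tolerance = 1e-10)
  expect_equal(intercept(fit), mean(y))
})

test_that("RR-BLUP degenerate cases: constant phenotype and infinite
           shrinkage", {
  pop <- smallPop(nMarkers = 50, seed = 70)
  g <- pop$genotypes
  fit0 <- fitRRBLUP(g, rep(4.2, nIndividuals(g)))
  expect_true(all(markerEffects(fit0) == 0))
  expect_equal(intercept(fit0), 4.2)
  fitInf <- fitRRBLUP(g, pop$phenotypes$body_weight_g, varianceRatio = Inf)
  expect_true(all(markerEffects(fitInf) == 0))
})

test_that("X ghat from RR-BLUP reproduces the G-matrix BLUP of breeding
           values", {
  for (s in 1:3) {
    n <- c(40, 70, 100)[s]
    pop <- smallPop(nMarkers = 500, nFamilies = 10, nSampled = n,
                    offspringPerFamily = 12, seed = 80 + s)
    y <- pop$phenotypes$body_weight_g
    vr <- 1.7
    fit <- fitRRBLUP(pop$genotypes, y, varianceRatio = vr)
    gebv <- predictGebv(fit, pop$genotypes)
    ublup <- gblupBreedingValues(grmVanRaden(pop$genotypes), y,
                                 varianceRatio = vr)
    expect_lt(max(abs(gebv - ublup)) / max(abs(ublup)), 1e-6)
  }
})

test_that("BayesA ranks a planted large-effect marker first in most
           replicates", {
  hits <- 0
  for (s in 1:20) {
    g <- unrelatedGenotypes(120, 80, maf = 0.4, seed = 300 + s)
    X <- dosage(g)
    set.seed(400 + s)
    y <- 1.2 * X[, 17] + rnorm(120, 0, 1)
    fit <- fitBayesA(g, y, mcmcConfig(nIter = 1500, burnIn = 500,
                                      seed = 500 + s))
    if (which.max(abs(markerEffects(fit))) == 17) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("with variances frozen, BayesA matches the implied ridge closed
           form within Monte-Carlo error", {
  g <- unrelatedGenotypes(80, 40, seed = 91)
  X <- dosage(g)
  set.seed(92)
  y <- as.vector(scale(X[, 1:5] %*% rnorm(5))) + rnorm(80)
  s2g <- 0.02; s2e <- 0.8
  fit <- fitBayesA(g, y, mcmcConfig(nIter = 12000, burnIn = 2000,
                                    seed = 93, keepSamples = TRUE),
                   fixSigma2Marker = s2g, fixSigma2E = s2e)
  Z <- sweep(X, 2, colMeans(X))
  # joint posterior mean of (mu, g) given fixed variances: ridge with
  # lambda = s2e / s2g on the centered design, intercept = ybar
  ridge <- solve(crossprod(Z) + diag(s2e / s2g, 40), crossprod(Z, y - mean(y)))
  se <- batchSE(fit@settings$gSamples)
  expectWithinMcError(markerEffects(fit), as.vector(ridge), se)
})

test_that("with tau2 frozen, the Bayesian LASSO matches the weighted-ridge
           closed form within Monte-Carlo error", {
  g <- unrelatedGenotypes(80, 30, seed = 94)
  X <- dosage(g)
  set.seed(95)
  y <- as.vector(scale(X[, 1:4] %*% rnorm(4))) + rnorm(80)
  tau2 <- rep(c(0.01, 0.05, 0.2), length.out = 30)
  fit <- fitBayesLasso(g, y, mcmcConfig(nIter = 12000, burnIn = 2000,
                                        seed = 96, keepSamples = TRUE),
                       fixTau2 = tau2)
  Z <- sweep(X, 2, colMeans(X))
  ridge <- solve(crossprod(Z) + diag(1 / tau2), crossprod(Z, y - mean(y)))
  se <- batchSE(fit@settings$gSamples)
  expectWithinMcError(markerEffects(fit), as.vector(ridge), se)
})

test_that("a null phenotype keeps Bayesian LASSO effects near zero", {
  ok <- 0
  for (s in 1:10) {
    g <- unrelatedGenotypes(100, 60, seed = 600 + s)
    set.seed(700 + s)
    y <- rnorm(100)
    fit <- fitBayesLasso(g, y, mcmcConfig(nIter = 2000, burnIn = 500,
                                          seed = 800 + s))
    if (max(abs(markerEffects(fit)) - 3 * fit@posteriorSD) < 0) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("Gibbs chains are identical under identical seeds", {
  pop <- smallPop(nMarkers = 60, seed = 71)
  y <- pop$phenotypes$body_weight_g
  cfgA <- mcmcConfig(nIter = 500, burnIn = 100, seed = 11)
  f1 <- fitBayesA(pop$genotypes, y, cfgA)
  f2 <- fitBayesA(pop$genotypes, y, cfgA)
  expect_identical(markerEffects(f1), markerEffects(f2))
  f3 <- fitBayesLasso(pop$genotypes, y, cfgA)
  f4 <- fitBayesLasso(pop$genotypes, y, cfgA)
  expect_identical(markerEffects(f3), markerEffects(f4))
})

test_that("GEBV prediction follows GEBV = Xg on the deviation scale", {
  d <- matrix(c(0, 1, 2), 3, 1)
  rownames(d) <- paste0("i", 1:3); colnames(d) <- "m1"
  g <- genotypeData(d)
  eff <- new("MarkerEffects", model = "rrblup",
             effects = c(m1 = 0.5), intercept = 10, centers = c(m1 = 1),
             posteriorSD = NA_real_, settings = list())
  expect_equal(unname(predictGebv(eff, g)), c(-0.5, 0, 0.5))
  zero <- new("MarkerEffects", model = "rrblup",
              effects = c(m1 = 0), intercept = 0, centers = c(m1 = 1),
              posteriorSD = NA_real_, settings = list())
  expect_true(all(predictGebv(zero, g) == 0))
  # marker mismatch is a hard error
  d2 <- d; colnames(d2) <- "other"
  expect_error(predictGebv(eff, genotypeData(d2)), "match")
})

test_that("all three models agree closely on polygenic family data", {
  pop <- simulatePopulation(nMarkers = 1000, nFamilies = 8, nSampled = 120,
                            offspringPerFamily = 25, nQtl = 200, seed = 72)
  y <- pop$phenotypes$body_weight_g
  cfg <- mcmcConfig(nIter = 6000, burnIn = 2000, seed = 5)
  gr <- predictGebv(fitRRBLUP(pop$genotypes, y), pop$genotypes)
  ga <- predictGebv(fitBayesA(pop$genotypes, y, cfg), pop$genotypes)
  gl <- predictGebv(fitBayesLasso(pop$genotypes, y, cfg), pop$genotypes)
  expect_gt(cor(gr, ga), 0.9)
  expect_gt(cor(gr, gl), 0.9)
  expect_gt(cor(ga, gl), 0.9)
  # in-sample fit quality is sane
  expect_gt(cor(gr, y), 0)
})
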