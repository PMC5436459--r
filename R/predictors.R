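# The three genomic-prediction models. Marker effects are always fitted on
# a training design whose dosage columns are centered by their training
# means; GEBVs are reported on the deviation scale (intercept excluded).
#
# RR-BLUP is the ridge closed form, with the shrinkage parameter tied to
# the REML variance ratio through the VanRaden denominator so that X ghat
# reproduces the G-matrix BLUP of breeding values exactly. BayesA and the
# Bayesian LASSO are single-site Gibbs samplers implemented in C++ (see
# src/samplers.cpp).

.trainDesign <- function(genotypes, phenotypes, trait = NULL) {
  requireComplete(genotypes, "model fitting")
  X <- genotypes@dosage
  y <- alignPhenotype(rownames(X), phenotypes, trait)
  if (nrow(X) < 2) stop("need at least 2 training individuals")
  centers <- colMeans(X)
  list(X = X, Zc = sweep(X, 2, centers), y = y, centers = centers)
}

#' Fit RR-BLUP marker effects
#'
#' Solves the ridge problem `ghat = (Z'Z + lambda I)^-1 Z' (y - ybar)` on
#' the centered design (evaluated through the equivalent n x n dual form).
#' `lambda` is `V_E / V_A` times the VanRaden denominator, i.e. the total
#' additive variance is split evenly across markers; when `varianceRatio`
#' is not supplied it is estimated by REML from the matching G matrix.
#'
#' @param genotypes complete training [GenotypeData-class].
#' @param phenotypes training phenotypes (vector / named vector /
#'   data.frame + `trait`).
#' @param varianceRatio optional `V_E / V_A` on the G-matrix scale
#'   (`Inf` shrinks all effects to zero).
#' @param trait column name when `phenotypes` is a data.frame.
#' @return a [MarkerEffects-class].
#' @export
fitRRBLUP <- function(genotypes, phenotypes, varianceRatio = NULL,
                      trait = NULL) {
  td <- .trainDesign(genotypes, phenotypes, trait)
  m <- ncol(td$X)
  n <- nrow(td$X)
  mu <- mean(td$y)
  yc <- td$y - mu
  settings <- list()
  if (stats::var(td$y) == 0) {
    g <- rep(0, m)
  } else {
    p <- colMeans(td$X) / 2
    denom <- 2 * sum(p * (1 - p))
    if (denom <= 0) stop("monomorphic training panel")
    if (is.null(varianceRatio)) {
      vc <- remlH2(grmVanRaden(genotypes), td$y)
      varianceRatio <- if (vc@varA <= 0) Inf else vc@varE / vc@varA
      settings$reml <- vc
    }
    settings$varianceRatio <- varianceRatio
    if (!is.finite(varianceRatio)) {
      g <- rep(0, m)
    } else {
      lambda <- max(varianceRatio * denom, denom * 1e-10)
      settings$lambda <- lambda
      K <- tcrossprod(td$Zc)
      sol <- solve(K + diag(lambda, n), yc)
      g <- as.vector(crossprod(td$Zc, sol))
    }
  }
  new("MarkerEffects", model = "rrblup",
      effects = stats::setNames(g, colnames(td$X)), intercept = mu,
      centers = td$centers, posteriorSD = rep(NA_real_, m),
      settings = settings)
}

#' GBLUP breeding values from a G matrix
#'
#' BLUP of the additive values under `y = 1 mu + u + e`,
#' `u ~ N(0, G V_A)`: `uhat = G (G + delta I)^-1 (y - ybar)` with
#' `delta = V_E / V_A` (REML-estimated when not supplied). Used as the
#' independent route in the RR-BLUP equivalence check and available for
#' direct genomic prediction.
#'
#' @param grm a [GRM-class].
#' @param phenotypes phenotypes aligned with the GRM.
#' @param varianceRatio optional `V_E / V_A`.
#' @param trait column name when `phenotypes` is a data.frame.
#' @return named numeric vector of breeding values (deviation scale).
#' @export
gblupBreedingValues <- function(grm, phenotypes, varianceRatio = NULL,
                                trait = NULL) {
  G <- kinshipValues(grm)
  y <- alignPhenotype(rownames(G), phenotypes, trait)
  if (is.null(varianceRatio)) {
    vc <- remlH2(grm, y)
    varianceRatio <- if (vc@varA <= 0) Inf else vc@varE / vc@varA
  }
  yc <- y - mean(y)
  if (!is.finite(varianceRatio))
    return(stats::setNames(rep(0, length(y)), rownames(G)))
  u <- G %*% solve(G + diag(varianceRatio, nrow(G)), yc)
  stats::setNames(as.vector(u), rownames(G))
}

# Shared front end of the two Gibbs samplers.
.fitGibbs <- function(genotypes, phenotypes, config, model, trait = NULL,
                      fixSigma2Marker = NA, fixSigma2E = NA,
                      fixTau2 = numeric(0)) {
  stopifnot(is(config, "McmcConfig"))
  td <- .trainDesign(genotypes, phenotypes, trait)
  m <- ncol(td$Zc)
  vy <- stats::var(td$y)
  if (vy <= 0) stop("zero-variance phenotype")
  msx <- sum(apply(td$Zc, 2, stats::var))
  if (msx <= 0) stop("monomorphic training panel")
  r2 <- config@r2

  # BayesA scale: prior E[sigma2_j] = df * S / (df - 2) chosen so the
  # markers jointly explain r2 of the phenotypic variance.
  scaleA <- config@scale
  if (is.na(scaleA))
    scaleA <- r2 * vy * (config@df - 2) / (config@df * msx)
  # BL penalty hyperprior: Gamma mode at lambda0^2 = 2 (1 - r2) MSx / r2,
  # the value at which the Laplace prior variance matches the same split.
  lambda20 <- 2 * (1 - r2) * msx / r2
  lambda2Rate <- config@lambda2Rate
  if (is.na(lambda2Rate))
    lambda2Rate <- (config@lambda2Shape - 1) / lambda20
  dfE <- 5
  scaleE <- (1 - r2) * vy * (dfE - 2) / dfE

  if (!is.na(config@seed)) set.seed(config@seed)
  fit <- .gibbs_marker_sampler(
    td$Zc, td$y, as.integer(config@nIter), as.integer(config@burnIn),
    if (model == "bayesa") 0L else 1L, config@df, scaleA, dfE, scaleE,
    config@lambda2Shape, lambda2Rate, lambda20,
    model == "bl" && length(fixTau2) == 0, as.numeric(fixSigma2Marker),
    as.numeric(fixSigma2E), as.numeric(fixTau2), config@keepSamples,
    as.integer(config@thin))

  settings <- list(config = config, scaleA = scaleA,
                   lambda2Rate = lambda2Rate,
                   sigma2e = fit$sigma2_e_mean,
                   lambda2 = fit$lambda2_mean, nKept = fit$n_kept)
  if (config@keepSamples) {
    settings$gSamples <- fit$g_samples
    settings$muSamples <- fit$mu_samples
  }
  new("MarkerEffects", model = model,
      effects = stats::setNames(as.vector(fit$g_mean), colnames(td$Zc)),
      intercept = fit$mu_mean, centers = td$centers,
      posteriorSD = as.vector(fit$g_sd), settings = settings)
}

#' Fit BayesA marker effects by Gibbs sampling
#'
#' Marker-specific variances carry a scaled-inverse-chi-squared prior
#' (marginally scaled-t effects). Full conditionals are sampled in a fixed
#' order (intercept, each effect in index order, marker variances, residual
#' variance); posterior means over the post-burn-in draws are returned.
#'
#' @param genotypes complete training [GenotypeData-class].
#' @param phenotypes training phenotypes.
#' @param config an [McmcConfig-class] (40,000 iterations / 10,000 burn-in
#'   by default).
#' @param trait column name when `phenotypes` is a data.frame.
#' @param fixSigma2Marker,fixSigma2E test hooks freezing the marker /
#'   residual variances at constants (NA = sample them).
#' @return a [MarkerEffects-class].
#' @export
fitBayesA <- function(genotypes, phenotypes, config = mcmcConfig(),
                      trait = NULL, fixSigma2Marker = NA, fixSigma2E = NA) {
  .fitGibbs(genotypes, phenotypes, config, "bayesa", trait,
            fixSigma2Marker = fixSigma2Marker, fixSigma2E = fixSigma2E)
}

#' Fit Bayesian LASSO marker effects by Gibbs sampling
#'
#' Double-exponential prior on the effects via the normal scale-mixture
#' representation: per-marker `tau2_j` with inverse-Gaussian full
#' conditionals and a Gamma hyperprior on the penalty `lambda^2`.
#'
#' @inheritParams fitBayesA
#' @param fixTau2 test hook: per-marker `tau2` values (recycled) frozen for
#'   the whole chain; length 0 samples them.
#' @return a [MarkerEffects-class].
#' @export
fitBayesLasso <- function(genotypes, phenotypes, config = mcmcConfig(),
                          trait = NULL, fixSigma2E = NA,
                          fixTau2 = numeric(0)) {
  .fitGibbs(genotypes, phenotypes, config, "bl", trait,
            fixSigma2E = fixSigma2E, fixTau2 = fixTau2)
}

#' Predict genomic estimated breeding values
#'
#' `GEBV = (X - training centers) g`, the deviation-scale form of
#' `GEBV = X g`; adding the intercept would shift every candidate equally
#' and never affects accuracy correlations. Candidate markers must match
#' the training markers exactly in identity and order.
#'
#' @param effects a [MarkerEffects-class].
#' @param genotypes complete candidate [GenotypeData-class].
#' @return named numeric vector of GEBVs.
#' @export
predictGebv <- function(effects, genotypes) {
  stopifnot(is(effects, "MarkerEffects"), is(genotypes, "GenotypeData"))
  requireComplete(genotypes, "prediction")
  if (!identical(markerIds(genotypes), names(effects@effects)))
    stop("candidate markers do not match the training markers ",
         "(identity and order must be identical)")
  Z <- sweep(genotypes@dosage, 2, effects@centers)
  stats::setNames(as.vector(Z %*% effects@effects),
                  individualIds(genotypes))
}

# Dispatch used by the cross-validation drivers.
.fitModel <- function(genotypes, phenotypes, model, config, trait = NULL) {
  switch(model,
         rrblup = fitRRBLUP(genotypes, phenotypes, trait = trait),
         bayesa = fitBayesA(genotypes, phenotypes, config, trait = trait),
         bl = fitBayesLasso(genotypes, phenotypes, config, trait = trait),
         stop("unknown model: ", model))
}
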