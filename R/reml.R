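# Spectral REML for the G-matrix animal model
#   y = 1 mu + u + e,  u ~ N(0, G V_A),  e ~ N(0, I V_E)
# The restricted likelihood is profiled over the variance ratio
# delta = V_E / V_A after one eigendecomposition of G, and maximised by
# Brent search over log(delta) on [-10, 10] (so h2 = 1 / (1 + delta) spans
# essentially (0, 1); solutions pinned at either end are flagged as
# boundary estimates).

#' REML heritability under the G-matrix animal model
#'
#' @param grm a [GRM-class] (or symmetric PSD matrix with id dimnames).
#' @param phenotypes one trait: numeric vector, named vector, or a
#'   data.frame plus `trait` column name.
#' @param trait column name when `phenotypes` is a data.frame.
#' @param interval search interval for `log(V_E / V_A)`.
#' @param tol convergence tolerance of the Brent search.
#' @return a [VarianceComponents-class].
#' @export
remlH2 <- function(grm, phenotypes, trait = NULL, interval = c(-10, 10),
                   tol = 1e-8) {
  G <- if (is.matrix(grm)) grm else kinshipValues(grm)
  ids <- rownames(G)
  y <- alignPhenotype(ids, phenotypes, trait)
  n <- length(y)
  if (n < 10) stop("need at least 10 individuals for REML")
  if (nrow(G) != n) stop("GRM and phenotypes are not aligned")
  if (stats::var(y) <= 0) stop("phenotype has zero variance")

  eg <- eigen(G, symmetric = TRUE)
  D <- pmax(eg$values, 0)
  yt <- as.vector(crossprod(eg$vectors, y))
  xt <- as.vector(crossprod(eg$vectors, rep(1, n)))
  np <- n - 1

  restrictedLL <- function(logDelta) {
    w <- D + exp(logDelta)
    xwx <- sum(xt^2 / w)
    beta <- sum(xt * yt / w) / xwx
    r <- yt - xt * beta
    s2 <- sum(r^2 / w) / np
    -0.5 * (np * (log(2 * pi) + log(s2) + 1) + sum(log(w)) + log(xwx))
  }

  opt <- stats::optimize(function(l) -restrictedLL(l), interval = interval,
                         tol = tol)
  l <- opt$minimum
  delta <- exp(l)
  w <- D + delta
  xwx <- sum(xt^2 / w)
  beta <- sum(xt * yt / w) / xwx
  s2a <- sum((yt - xt * beta)^2 / w) / np
  boundary <- (l - interval[1] < 1e-3) || (interval[2] - l < 1e-3)
  new("VarianceComponents", varA = s2a, varE = delta * s2a,
      h2 = 1 / (1 + delta), logLik = -opt$objective, converged = TRUE,
      boundary = boundary)
}

#' Heritability as a function of marker density
#'
#' For each density, `nReps` uniform random marker subsets are drawn
#' without replacement from the full panel, the GRM is rebuilt on each
#' subset and REML re-run; the per-density summary is the mean (and SD)
#' over replicates. Subset seeds are derived independently per
#' (density, replicate) from the master seed.
#'
#' @param genotypes complete [GenotypeData-class].
#' @param phenotypes one trait (see [remlH2()]).
#' @param densities marker counts to subsample (each must not exceed the
#'   panel size).
#' @param nReps random subsets per density (default 50).
#' @param trait column name when `phenotypes` is a data.frame.
#' @param seed master seed.
#' @return data.frame `(density, replicate, h2, varA, varE, boundary)` with
#'   the per-density summary attached as attribute `"summary"`.
#' @export
h2DensityCurve <- function(genotypes, phenotypes, densities, nReps = 50,
                           trait = NULL, seed = 1) {
  m <- nMarkers(genotypes)
  if (any(densities > m))
    stop("density exceeds the marker count (", m, ")")
  y <- alignPhenotype(individualIds(genotypes), phenotypes, trait)
  rows <- vector("list", length(densities) * nReps)
  k <- 0
  for (d in densities) {
    for (r in seq_len(nReps)) {
      set.seed(deriveSeed(seed, "h2curve", d, r))
      idx <- if (d == m) seq_len(m) else sort(sample.int(m, d))
      vc <- remlH2(grmVanRaden(genotypes[, idx]), y)
      k <- k + 1
      rows[[k]] <- data.frame(density = d, replicate = r, h2 = vc@h2,
                              varA = vc@varA, varE = vc@varE,
                              boundary = vc@boundary)
    }
  }
  out <- do.call(rbind, rows)
  s <- stats::aggregate(h2 ~ density, out,
                        function(v) c(mean = mean(v), sd = stats::sd(v)))
  attr(out, "summary") <- data.frame(density = s$density,
                                     mean_h2 = s$h2[, "mean"],
                                     sd_h2 = s$h2[, "sd"])
  out
}
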