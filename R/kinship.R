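# Marker-based relationship matrices: the VanRaden additive genomic
# relationship matrix (G) and the identity-by-state kinship matrix.

#' VanRaden genomic relationship matrix
#'
#' Method-1 scaling with sample-estimated allele frequencies: the dosage
#' matrix is column-centered by `2 p_j` and
#' `G = Z Z' / (2 sum_j p_j (1 - p_j))`. Fractional (imputed) dosages are
#' accepted; missing entries are not.
#'
#' @param genotypes complete [GenotypeData-class] with at least two
#'   polymorphic markers.
#' @return a [GRM-class].
#' @examples
#' g <- genotypeData(matrix(c(0, 2, 2, 0), 2, 2))
#' kinshipValues(grmVanRaden(g))  # [[1, -1], [-1, 1]]
#' @export
grmVanRaden <- function(genotypes) {
  stopifnot(is(genotypes, "GenotypeData"))
  requireComplete(genotypes, "computing the GRM")
  d <- genotypes@dosage
  p <- colMeans(d) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all markers are monomorphic; the VanRaden denominator is zero")
  Z <- sweep(d, 2, 2 * p)
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  new("GRM", values = G, alleleFreq = unname(p), denominator = denom)
}

#' Identity-by-state kinship matrix
#'
#' Entry (i, k) is the mean over markers of `1 - |d_i - d_k| / 2`, the
#' proportion of alleles shared identical by state. Missing calls are
#' skipped pairwise (pairwise-complete mean); the intended input is the
#' raw post-QC matrix, before fractional imputation. Fractional dosages
#' are rounded with a warning.
#'
#' @param genotypes a [GenotypeData-class] (missing entries allowed).
#' @return an [IBSMatrix-class].
#' @export
ibsMatrix <- function(genotypes) {
  stopifnot(is(genotypes, "GenotypeData"))
  d <- genotypes@dosage
  obs <- d[!is.na(d)]
  if (any(obs != round(obs))) {
    warning("fractional dosages rounded for IBS computation")
    d <- round(d)
  }
  M <- !is.na(d)
  I0 <- (d == 0) & M; I0[!M] <- FALSE
  I1 <- (d == 1) & M; I1[!M] <- FALSE
  I2 <- (d == 2) & M; I2[!M] <- FALSE
  storage.mode(I0) <- storage.mode(I1) <- storage.mode(I2) <- "double"
  Mn <- M; storage.mode(Mn) <- "double"
  P01 <- tcrossprod(I0, I1)
  P12 <- tcrossprod(I1, I2)
  P02 <- tcrossprod(I0, I2)
  absDiffSum <- P01 + t(P01) + P12 + t(P12) + 2 * (P02 + t(P02))
  nPairs <- tcrossprod(Mn)
  ibs <- 1 - absDiffSum / (2 * nPairs)
  ibs[nPairs == 0] <- NA_real_
  if (anyNA(ibs))
    warning("individual pairs with no jointly called marker (IBS = NA)")
  diag(ibs) <- 1
  ibs <- (ibs + t(ibs)) / 2
  dimnames(ibs) <- list(rownames(d), rownames(d))
  new("IBSMatrix", values = ibs)
}
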