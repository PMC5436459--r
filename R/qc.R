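# SNP quality control: allele frequencies, missing-rate/MAF filtering, and
# simple dosage imputation.

#' Per-marker allele frequencies, MAF and missing rate
#'
#' The alternate-allele frequency is the mean non-missing dosage divided by
#' 2; MAF is `min(p, 1 - p)`. Markers with no non-missing call get `NA`
#' frequencies (flagged, not fatal).
#'
#' @param genotypes a [GenotypeData-class].
#' @return data.frame with `marker_id`, `alt_freq`, `maf`, `missing_rate`,
#'   `n_called`.
#' @examples
#' g <- genotypeData(matrix(c(0, NA, 1, 2), 4, 1))
#' alleleFrequencies(g)  # p = 0.5, missing rate 0.25
#' @export
alleleFrequencies <- function(genotypes) {
  d <- genotypes@dosage
  nCalled <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * nCalled)
  p[nCalled == 0] <- NA_real_
  data.frame(marker_id = colnames(d), alt_freq = unname(p),
             maf = unname(pmin(p, 1 - p)),
             missing_rate = unname(1 - nCalled / nrow(d)),
             n_called = unname(nCalled), stringsAsFactors = FALSE)
}

#' Filter markers on missing rate and minor allele frequency
#'
#' A marker is removed when its missing rate exceeds `maxMissing` or its
#' MAF falls below `minMaf`; both statistics are computed on the same input
#' pass, boundary values are kept, and individuals are never removed.
#'
#' @param genotypes a [GenotypeData-class].
#' @param maxMissing maximum tolerated per-marker missing rate (default
#'   0.05).
#' @param minMaf minimum tolerated MAF (default 0.05).
#' @return list with `genotypes` (filtered [GenotypeData-class]) and
#'   `report` (counts plus the per-marker statistics table with a `kept`
#'   column).
#' @export
qcFilter <- function(genotypes, maxMissing = 0.05, minMaf = 0.05) {
  stopifnot(maxMissing >= 0, maxMissing <= 1, minMaf >= 0, minMaf <= 1)
  af <- alleleFrequencies(genotypes)
  # strict removal conditions, with a float guard so exact-boundary markers
  # (missing rate == maxMissing, MAF == minMaf) are kept
  eps <- 1e-9
  failMissing <- af$missing_rate > maxMissing + eps
  failMaf <- is.na(af$maf) | af$maf < minMaf - eps
  keep <- !(failMissing | failMaf)
  af$kept <- keep
  report <- list(n_markers_in = nrow(af),
                 n_removed_missing = sum(failMissing),
                 n_removed_maf = sum(failMaf),
                 n_removed = sum(!keep),
                 n_markers_out = sum(keep),
                 max_missing = maxMissing, min_maf = minMaf,
                 per_marker = af)
  list(genotypes = genotypes[, keep], report = report)
}

#' Impute missing dosages
#'
#' `mean_dosage` replaces each missing entry by the marker's mean observed
#' dosage; `family_mean` uses the within-family marker mean when at least
#' two family members are called, falling back to the global marker mean.
#' Observed calls are never altered; imputed entries may be fractional.
#'
#' @param genotypes a [GenotypeData-class]; every marker must have at least
#'   one non-missing call (run [qcFilter()] first).
#' @param method `"mean_dosage"` or `"family_mean"` (the latter requires a
#'   pedigree with a `family` column).
#' @return a complete [GenotypeData-class].
#' @export
imputeMissing <- function(genotypes,
                          method = c("mean_dosage", "family_mean")) {
  method <- match.arg(method)
  d <- genotypes@dosage
  if (!anyNA(d)) return(genotypes)
  nCalled <- colSums(!is.na(d))
  if (any(nCalled == 0))
    stop("all-missing marker(s): ",
         paste(utils::head(colnames(d)[nCalled == 0], 5), collapse = ", "),
         " (filter before imputing)")
  colMean <- colSums(d, na.rm = TRUE) / nCalled
  if (method == "mean_dosage") {
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- colMean[idx[, 2]]
  } else {
    ped <- genotypes@pedigree
    if (!nrow(ped) || is.null(ped$family))
      stop("family_mean imputation needs a pedigree with a family column")
    fam <- ped$family[match(rownames(d), ped$id)]
    for (f in unique(fam)) {
      rows <- which(fam == f)
      sub <- d[rows, , drop = FALSE]
      nf <- colSums(!is.na(sub))
      fMean <- colSums(sub, na.rm = TRUE) / nf
      fill <- ifelse(nf >= 2, fMean, colMean)
      idx <- which(is.na(sub), arr.ind = TRUE)
      if (nrow(idx)) {
        sub[idx] <- fill[idx[, 2]]
        d[rows, ] <- sub
      }
    }
  }
  initialize(genotypes, dosage = d)
}
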