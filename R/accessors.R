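#' Construct a GenotypeData object
#'
#' @param dosage individuals x markers numeric matrix (0/1/2, `NA` missing).
#'   Row and column names are used as individual and marker ids; defaults
#'   are generated when absent.
#' @param markers optional marker metadata data.frame (`marker_id`, `chrom`,
#'   `pos`, `ref`, `alt`, optionally `pos_morgan`); a minimal one is built
#'   when omitted.
#' @param pedigree optional data.frame with `id`, `sire`, `dam`, `family`.
#' @return a [GenotypeData-class] object.
#' @examples
#' g <- genotypeData(matrix(c(0, 1, 2, 0), 2, 2))
#' nMarkers(g)
#' @export
genotypeData <- function(dosage, markers = NULL, pedigree = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("ind%03d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("snp%05d", seq_len(ncol(dosage)))
  if (is.null(markers)) {
    markers <- data.frame(marker_id = colnames(dosage), chrom = "1",
                          pos = seq_len(ncol(dosage)), ref = "A", alt = "B",
                          stringsAsFactors = FALSE)
  }
  markers$marker_id <- as.character(markers$marker_id)
  if (is.null(pedigree))
    pedigree <- data.frame(id = character(), sire = character(),
                           dam = character(), family = integer(),
                           stringsAsFactors = FALSE)
  new("GenotypeData", dosage = dosage, markers = markers, pedigree = pedigree)
}

#' @rdname GenotypeData-class
#' @export
setMethod("dosage", "GenotypeData", function(x) x@dosage)

#' @rdname GenotypeData-class
#' @export
setMethod("individualIds", "GenotypeData", function(x) rownames(x@dosage))

#' @rdname GenotypeData-class
#' @export
setMethod("markerIds", "GenotypeData", function(x) colnames(x@dosage))

#' @rdname GenotypeData-class
#' @export
setMethod("markerInfo", "GenotypeData", function(x) x@markers)

#' @rdname GenotypeData-class
#' @export
setMethod("pedigree", "GenotypeData", function(x) x@pedigree)

#' @rdname GenotypeData-class
#' @export
setMethod("nIndividuals", "GenotypeData", function(x) nrow(x@dosage))

#' @rdname GenotypeData-class
#' @export
setMethod("nMarkers", "GenotypeData", function(x) ncol(x@dosage))

#' @describeIn GenotypeData-class subset individuals (i) and/or markers (j).
#' @param i,j individual / marker indices (integer, logical or character).
#' @param drop ignored.
#' @export
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@dosage))
  if (missing(j)) j <- seq_len(ncol(x@dosage))
  d <- x@dosage[i, j, drop = FALSE]
  mk <- x@markers[match(colnames(d), x@markers$marker_id), , drop = FALSE]
  rownames(mk) <- NULL
  ped <- x@pedigree
  if (nrow(ped)) ped <- ped[ped$id %in% rownames(d), , drop = FALSE]
  new("GenotypeData", dosage = d, markers = mk, pedigree = ped)
})

setMethod("show", "GenotypeData", function(object) {
  d <- object@dosage
  nmiss <- sum(is.na(d))
  cat("GenotypeData:", nrow(d), "individuals x", ncol(d), "markers\n")
  cat(sprintf("  missing entries: %d (%.2f%%)\n", nmiss,
              100 * nmiss / length(d)))
  if (nrow(object@pedigree))
    cat("  pedigree:", length(unique(object@pedigree$family)), "families\n")
})

setMethod("show", "GeneticMap", function(object) {
  cat("GeneticMap:", nrow(object@chromosomes), "chromosomes,",
      nrow(object@positions), "markers,",
      sprintf("%.1f", sum(object@chromosomes$length_morgan)),
      "Morgans total\n")
})

setMethod("show", "FounderPopulation", function(object) {
  cat("FounderPopulation:", length(object@ids), "founders x",
      ncol(object@hap1), "markers (phased)\n")
})

#' Founder genotypes as a GenotypeData object
#'
#' Collapses the phased founder haplotypes into dosages.
#' @param founders a [FounderPopulation-class].
#' @return a [GenotypeData-class].
#' @export
founderGenotypes <- function(founders) {
  stopifnot(is(founders, "FounderPopulation"))
  d <- founders@hap1 + founders@hap2
  rownames(d) <- founders@ids
  po <- founders@map@positions
  mk <- data.frame(marker_id = po$marker_id, chrom = po$chrom,
                   pos = round(po$pos_morgan * 1e6) + 1L, ref = "A",
                   alt = "B", pos_morgan = po$pos_morgan,
                   stringsAsFactors = FALSE)
  colnames(d) <- mk$marker_id
  genotypeData(d, markers = mk)
}

#' @rdname VarianceComponents-class
#' @export
setMethod("varA", "VarianceComponents", function(x) x@varA)

#' @rdname VarianceComponents-class
#' @export
setMethod("varE", "VarianceComponents", function(x) x@varE)

#' @rdname VarianceComponents-class
#' @export
setMethod("varP", "VarianceComponents", function(x) x@varA + x@varE)

#' @rdname VarianceComponents-class
#' @export
setMethod("h2", "VarianceComponents", function(x) x@h2)

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf(
    "VarianceComponents: V_A = %.4g, V_E = %.4g, V_P = %.4g, h2 = %.3f%s\n",
    object@varA, object@varE, object@varA + object@varE, object@h2,
    if (object@boundary) " (boundary)" else ""))
})

#' @rdname MarkerEffects-class
#' @export
setMethod("markerEffects", "MarkerEffects", function(x) x@effects)

#' @rdname MarkerEffects-class
#' @export
setMethod("intercept", "MarkerEffects", function(x) x@intercept)

setMethod("show", "MarkerEffects", function(object) {
  cat(sprintf("MarkerEffects: model %s, %d markers, intercept %.4g\n",
              object@model, length(object@effects), object@intercept))
})

#' @rdname kinshipValues
#' @export
setMethod("kinshipValues", "GRM", function(x, ...) x@values)

#' @rdname kinshipValues
#' @export
setMethod("kinshipValues", "IBSMatrix", function(x, ...) x@values)

setMethod("show", "GRM", function(object) {
  n <- nrow(object@values)
  cat(sprintf("GRM (VanRaden): %d x %d, mean diagonal %.3f\n", n, n,
              mean(diag(object@values))))
})

setMethod("show", "IBSMatrix", function(object) {
  n <- nrow(object@values)
  off <- object@values[upper.tri(object@values)]
  cat(sprintf("IBSMatrix: %d x %d, mean off-diagonal %.3f\n", n, n,
              mean(off, na.rm = TRUE)))
})

#' Construct Gibbs-sampler settings
#'
#' @param nIter,burnIn,thin chain length, burn-in and stored-sample thinning.
#' @param seed integer chain seed (`NA` leaves the RNG state alone).
#' @param df BayesA degrees of freedom for the scaled-inverse-chi-squared
#'   prior on marker variances.
#' @param scale BayesA prior scale; `NA` resolves from the data so that the
#'   prior expected marker variance explains `r2` of the phenotypic variance.
#' @param lambda2Shape,lambda2Rate Gamma hyperprior on the Bayesian LASSO
#'   penalty `lambda^2`; `lambda2Rate = NA` resolves via the same `r2`
#'   heuristic.
#' @param r2 prior proportion of phenotypic variance attributed to markers.
#' @param keepSamples store thinned post-burn-in samples of the effects.
#' @return an [McmcConfig-class].
#' @export
mcmcConfig <- function(nIter = 40000, burnIn = 10000, thin = 1, seed = NA,
                       df = 5, scale = NA, lambda2Shape = 1.1,
                       lambda2Rate = NA, r2 = 0.5, keepSamples = FALSE) {
  new("McmcConfig", nIter = nIter, burnIn = burnIn, thin = thin,
      seed = as.numeric(seed), df = df, scale = as.numeric(scale),
      lambda2Shape = lambda2Shape, lambda2Rate = as.numeric(lambda2Rate),
      r2 = r2, keepSamples = keepSamples)
}
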