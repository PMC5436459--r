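#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib famGS, .registration = TRUE
NULL

#' Genetic map of marker positions
#'
#' Holds the chromosome layout (lengths in Morgans) and per-marker genetic
#' positions used by the gene-drop simulator for Mendelian recombination.
#'
#' @slot chromosomes data.frame with columns `chrom` and `length_morgan`.
#' @slot positions data.frame with columns `marker_id`, `chrom`,
#'   `pos_morgan`; markers are sorted within chromosome.
#' @export
setClass("GeneticMap",
  representation(chromosomes = "data.frame", positions = "data.frame"))

setValidity("GeneticMap", function(object) {
  ch <- object@chromosomes
  po <- object@positions
  if (!all(c("chrom", "length_morgan") %in% names(ch)))
    return("chromosomes needs columns chrom, length_morgan")
  if (!all(c("marker_id", "chrom", "pos_morgan") %in% names(po)))
    return("positions needs columns marker_id, chrom, pos_morgan")
  if (anyDuplicated(po$marker_id)) return("duplicate marker ids")
  if (any(po$pos_morgan < 0)) return("negative genetic positions")
  len <- stats::setNames(ch$length_morgan, ch$chrom)
  if (any(is.na(len[po$chrom]))) return("marker on unknown chromosome")
  if (any(po$pos_morgan > len[po$chrom] + 1e-12))
    return("marker position beyond chromosome length")
  for (cc in unique(po$chrom)) {
    p <- po$pos_morgan[po$chrom == cc]
    if (is.unsorted(p)) return(sprintf("markers unsorted on chromosome %s", cc))
  }
  TRUE
})

#' Genotype dosage matrix with marker and pedigree metadata
#'
#' The central data container: an individuals x markers matrix of allele
#' dosages coded 0/1/2 (copies of the alternate allele; `NA` for missing,
#' fractional values allowed after imputation), per-marker metadata, and an
#' optional pedigree (`id`, `sire`, `dam`, `family`).
#'
#' @slot dosage numeric matrix, individuals in rows (rownames = individual
#'   ids), markers in columns (colnames = marker ids).
#' @slot markers data.frame of marker metadata (`marker_id`, `chrom`, `pos`,
#'   `ref`, `alt`, and `pos_morgan` when a genetic map is known).
#' @slot pedigree data.frame with columns `id`, `sire`, `dam`, `family`
#'   (zero rows when unknown).
#' @export
setClass("GenotypeData",
  representation(dosage = "matrix", markers = "data.frame",
                 pedigree = "data.frame"))

setValidity("GenotypeData", function(object) {
  d <- object@dosage
  if (!is.numeric(d)) return("dosage must be numeric")
  if (is.null(rownames(d)) || is.null(colnames(d)))
    return("dosage needs individual ids as rownames and marker ids as colnames")
  if (anyDuplicated(rownames(d))) return("duplicate individual ids")
  if (anyDuplicated(colnames(d))) return("duplicate marker ids")
  v <- d[!is.na(d)]
  if (length(v) && (min(v) < 0 || max(v) > 2))
    return("dosages must lie in [0, 2]")
  if (nrow(object@markers) != ncol(d))
    return("markers metadata does not match marker count")
  if (!identical(object@markers$marker_id, colnames(d)))
    return("markers$marker_id must match dosage colnames")
  ped <- object@pedigree
  if (nrow(ped) && !all(rownames(d) %in% ped$id))
    return("pedigree is missing some genotyped individuals")
  TRUE
})

#' Founder population with phased haplotypes
#'
#' Phased biallelic haplotypes for the founder sires and dams, kept separate
#' from [GenotypeData-class] because meiosis needs phase.
#'
#' @slot hap1,hap2 integer matrices (founders x markers) of 0/1 alleles.
#' @slot ids founder ids (rownames of both haplotype matrices).
#' @slot map the [GeneticMap-class] the haplotypes were simulated on.
#' @export
setClass("FounderPopulation",
  representation(hap1 = "matrix", hap2 = "matrix", ids = "character",
                 map = "GeneticMap"))

setValidity("FounderPopulation", function(object) {
  if (!identical(dim(object@hap1), dim(object@hap2)))
    return("haplotype matrices differ in dimension")
  if (nrow(object@hap1) != length(object@ids))
    return("ids do not match haplotype rows")
  if (!all(object@hap1 %in% 0:1) || !all(object@hap2 %in% 0:1))
    return("haplotypes must be 0/1")
  if (ncol(object@hap1) != nrow(object@map@positions))
    return("marker count does not match the map")
  TRUE
})

#' Additive trait architecture
#'
#' @slot nQtl number of causal loci.
#' @slot qtlIndices marker indices of the causal loci.
#' @slot effects additive effect per QTL (trait units per allele copy).
#' @slot targetH2 narrow-sense heritability in `[0, 1]` imposed on the
#'   realized sample.
#' @slot targetMean,targetSd phenotype scale (trait units).
#' @slot trait label, e.g. "body_weight_g".
#' @export
setClass("TraitArchitecture",
  representation(nQtl = "numeric", qtlIndices = "numeric",
                 effects = "numeric", targetH2 = "numeric",
                 targetMean = "numeric", targetSd = "numeric",
                 trait = "character"))

setValidity("TraitArchitecture", function(object) {
  if (object@nQtl < 1) return("need at least one QTL")
  if (length(object@qtlIndices) != object@nQtl ||
      length(object@effects) != object@nQtl)
    return("qtlIndices/effects length must equal nQtl")
  if (object@targetH2 < 0 || object@targetH2 > 1)
    return("targetH2 must be in [0, 1]")
  if (object@targetSd <= 0) return("targetSd must be positive")
  TRUE
})

#' Genomic relationship matrix (VanRaden)
#'
#' @slot values n x n relationship matrix (dimnames = individual ids).
#' @slot alleleFreq per-marker alternate-allele frequencies used for
#'   centering.
#' @slot denominator the VanRaden scaling `2 * sum(p (1 - p))`.
#' @export
setClass("GRM",
  representation(values = "matrix", alleleFreq = "numeric",
                 denominator = "numeric"))

setValidity("GRM", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("GRM must be square")
  if (max(abs(v - t(v))) > 1e-10) return("GRM must be symmetric")
  TRUE
})

#' Identity-by-state kinship matrix
#'
#' Entries are the proportion of alleles shared identical by state,
#' pairwise-complete over non-missing markers.
#'
#' @slot values n x n matrix in `[0, 1]` with unit diagonal.
#' @export
setClass("IBSMatrix", representation(values = "matrix"))

setValidity("IBSMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("IBS matrix must be square")
  if (max(abs(v - t(v))) > 1e-10) return("IBS matrix must be symmetric")
  ok <- v[!is.na(v)]
  if (length(ok) && (min(ok) < -1e-10 || max(ok) > 1 + 1e-10))
    return("IBS entries must lie in [0, 1]")
  if (any(abs(diag(v) - 1) > 1e-10)) return("IBS diagonal must be 1")
  TRUE
})

#' REML variance components for one trait
#'
#' @slot varA additive genetic variance (trait units squared, on the scale
#'   of the relationship matrix supplied).
#' @slot varE residual variance.
#' @slot h2 narrow-sense heritability `varA / (varA + varE)`.
#' @slot logLik restricted log-likelihood at the optimum.
#' @slot converged logical.
#' @slot boundary TRUE when the estimate sits at the edge of the allowed
#'   variance-ratio range (h2 effectively 0 or 1).
#' @export
setClass("VarianceComponents",
  representation(varA = "numeric", varE = "numeric", h2 = "numeric",
                 logLik = "numeric", converged = "logical",
                 boundary = "logical"))

setValidity("VarianceComponents", function(object) {
  if (object@varA < 0 || object@varE < 0) return("variances must be >= 0")
  if (object@h2 < 0 || object@h2 > 1) return("h2 must be in [0, 1]")
  TRUE
})

#' Gibbs sampler settings for the Bayesian marker-effect models
#'
#' Defaults follow common practice for these samplers: 40,000 iterations
#' with the first 10,000 discarded as burn-in. `df`/`scale` parameterize the
#' scaled-inverse-chi-squared prior on BayesA marker variances;
#' `lambda2Shape`/`lambda2Rate` the Gamma hyperprior on the Bayesian LASSO
#' penalty; `r2` is the prior proportion of phenotypic variance attributed
#' to markers, used to resolve the `NA` scale defaults from the data.
#'
#' @slot nIter,burnIn,thin chain length, burn-in, thinning of stored samples.
#' @slot seed integer seed for the chain (NA = leave the RNG state alone).
#' @slot df,scale BayesA hyperparameters (`scale = NA` resolves via `r2`).
#' @slot lambda2Shape,lambda2Rate Bayesian LASSO hyperparameters
#'   (`lambda2Rate = NA` resolves via `r2`).
#' @slot r2 prior marker R-squared used by the scale heuristics.
#' @slot keepSamples store thinned post-burn-in effect samples (memory!).
#' @export
setClass("McmcConfig",
  representation(nIter = "numeric", burnIn = "numeric", thin = "numeric",
                 seed = "numeric", df = "numeric", scale = "numeric",
                 lambda2Shape = "numeric", lambda2Rate = "numeric",
                 r2 = "numeric", keepSamples = "logical"))

setValidity("McmcConfig", function(object) {
  if (object@nIter < 1 || object@burnIn < 0 || object@thin < 1)
    return("counts must be positive")
  if (object@burnIn >= object@nIter) return("burnIn must be < nIter")
  if (object@r2 <= 0 || object@r2 >= 1) return("r2 must be in (0, 1)")
  TRUE
})

#' Fitted marker effects
#'
#' Additive per-marker effects from one of the three models, plus the
#' column centers of the training design so that candidates are predicted
#' on the same scale (GEBVs are reported as deviations; the intercept is
#' carried separately).
#'
#' @slot model "rrblup", "bayesa" or "bl".
#' @slot effects named numeric vector of per-marker additive effects.
#' @slot intercept fitted intercept (trait units).
#' @slot centers training-mean dosage per marker used for centering.
#' @slot posteriorSD per-effect posterior SD (NA for RR-BLUP).
#' @slot settings list of fitting details (variance ratio, hyperparameters,
#'   chain summaries, optional stored samples).
#' @export
setClass("MarkerEffects",
  representation(model = "character", effects = "numeric",
                 intercept = "numeric", centers = "numeric",
                 posteriorSD = "numeric", settings = "list"))

setValidity("MarkerEffects", function(object) {
  if (length(object@effects) != length(object@centers))
    return("effects and centers must have equal length")
  if (any(!is.finite(object@effects))) return("non-finite marker effects")
  TRUE
})
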