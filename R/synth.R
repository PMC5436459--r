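# Synthetic multi-family population generator: founder haplotypes with
# tunable LD, Mendelian gene drop through full-sib families, additive
# polygenic traits at a target heritability, and missingness injection.

#' Build a genetic map with evenly spaced markers
#'
#' The default layout is shrimp-like: 44 chromosomes of 1 Morgan each, with
#' markers spread as evenly as possible across and within chromosomes.
#'
#' @param nMarkers total marker count.
#' @param nChromosomes number of chromosomes.
#' @param chromosomeLength length of each chromosome in Morgans (scalar or
#'   per-chromosome vector).
#' @return a [GeneticMap-class].
#' @export
geneticMap <- function(nMarkers, nChromosomes = 44, chromosomeLength = 1) {
  stopifnot(nMarkers >= 1, nChromosomes >= 1)
  len <- rep_len(chromosomeLength, nChromosomes)
  chrom <- sprintf("chr%02d", seq_len(nChromosomes))
  counts <- diff(round(seq(0, nMarkers, length.out = nChromosomes + 1)))
  pos <- vector("list", nChromosomes)
  for (k in seq_len(nChromosomes)) {
    if (counts[k] > 0)
      pos[[k]] <- (seq_len(counts[k]) - 0.5) / counts[k] * len[k]
  }
  positions <- data.frame(
    marker_id = sprintf("snp%05d", seq_len(nMarkers)),
    chrom = rep(chrom, counts),
    pos_morgan = unlist(pos),
    stringsAsFactors = FALSE)
  new("GeneticMap",
      chromosomes = data.frame(chrom = chrom, length_morgan = len,
                               stringsAsFactors = FALSE),
      positions = positions)
}

#' Default full-sib family structure
#'
#' One sire and one dam per family, no founder sharing across families
#' (every family is a distinct full-sib group).
#'
#' @param nFamilies number of full-sib families (default 13).
#' @return data.frame with columns `family`, `sire`, `dam`.
#' @export
familyStructure <- function(nFamilies = 13) {
  data.frame(family = seq_len(nFamilies),
             sire = sprintf("S%02d", seq_len(nFamilies)),
             dam = sprintf("D%02d", seq_len(nFamilies)),
             stringsAsFactors = FALSE)
}

#' Simulate phased founder haplotypes
#'
#' Haplotypes follow a first-order Markov process along each chromosome:
#' the latent uniform driving marker j is copied from marker j-1 with
#' probability `exp(-d_cM / ldDecay)` (d = genetic distance) and redrawn
#' otherwise, so adjacent-marker correlation decays with distance while the
#' per-marker allele frequency is preserved exactly. `ldDecay` is the LD
#' correlation length in centimorgans; 0 gives fully independent markers,
#' and markers at identical positions are perfectly correlated for any
#' positive value.
#'
#' @param map a [GeneticMap-class].
#' @param nSires,nDams founder counts (default 13 + 13).
#' @param mafSpec minor/alternate allele frequency specification: a function
#'   of the marker count returning frequencies in (0, 0.5], a vector, or a
#'   scalar.
#' @param ldDecay LD correlation length in cM (>= 0).
#' @param seed integer seed (NULL = leave RNG state alone).
#' @return a [FounderPopulation-class].
#' @export
simulateFounders <- function(map, nSires = 13, nDams = 13,
                             mafSpec = function(m) stats::runif(m, 0.05, 0.5),
                             ldDecay = 5, seed = NULL) {
  stopifnot(is(map, "GeneticMap"), nSires >= 1, nDams >= 1, ldDecay >= 0)
  if (!is.null(seed)) set.seed(seed)
  po <- map@positions
  m <- nrow(po)
  p <- if (is.function(mafSpec)) mafSpec(m) else rep_len(mafSpec, m)
  if (any(p <= 0) || any(p > 0.5))
    stop("mafSpec must yield frequencies in (0, 0.5]")
  nF <- nSires + nDams
  nH <- 2L * nF

  # copy probability for each marker given its predecessor on the chromosome
  newchrom <- c(TRUE, po$chrom[-1] != po$chrom[-m])
  d_cM <- c(0, diff(po$pos_morgan)) * 100
  r <- numeric(m)
  if (ldDecay > 0) r <- exp(-d_cM / ldDecay)
  r[newchrom] <- 0

  alleles <- matrix(0L, nH, m)
  u <- stats::runif(nH)
  alleles[, 1] <- as.integer(u < p[1])
  if (m > 1) {
    for (j in 2:m) {
      if (r[j] > 0) {
        keep <- stats::runif(nH) < r[j]
        fresh <- stats::runif(nH)
        u <- ifelse(keep, u, fresh)
      } else {
        u <- stats::runif(nH)
      }
      alleles[, j] <- as.integer(u < p[j])
    }
  }

  ids <- c(sprintf("S%02d", seq_len(nSires)), sprintf("D%02d", seq_len(nDams)))
  hap1 <- alleles[seq(1, nH, by = 2), , drop = FALSE]
  hap2 <- alleles[seq(2, nH, by = 2), , drop = FALSE]
  rownames(hap1) <- rownames(hap2) <- ids
  colnames(hap1) <- colnames(hap2) <- po$marker_id
  new("FounderPopulation", hap1 = hap1, hap2 = hap2, ids = ids, map = map)
}

# One gamete from parent `idx`: Poisson-count crossovers per chromosome at
# the Morgan scale, uniform crossover positions, random starting haplotype.
.gamete <- function(founders, idx, chromMarkers, chromLen, chromPos) {
  m <- ncol(founders@hap1)
  out <- integer(m)
  h1 <- founders@hap1[idx, ]
  h2 <- founders@hap2[idx, ]
  for (k in seq_along(chromMarkers)) {
    jj <- chromMarkers[[k]]
    if (!length(jj)) next
    nco <- stats::rpois(1, chromLen[k])
    start <- as.integer(stats::runif(1) < 0.5)
    if (nco == 0) {
      seg <- rep.int(start, length(jj))
    } else {
      co <- sort(stats::runif(nco) * chromLen[k])
      seg <- (start + findInterval(chromPos[[k]], co)) %% 2L
    }
    out[jj] <- ifelse(seg == 0L, h1[jj], h2[jj])
  }
  out
}

#' Drop gametes through full-sib families
#'
#' Each offspring receives one recombinant gamete from its sire and one from
#' its dam. Conceptually `offspringPerFamily` offspring exist per family and
#' `nSampled` of them are drawn uniformly without replacement across all
#' families; only the sampled genomes are instantiated.
#'
#' @param founders a [FounderPopulation-class].
#' @param structure data.frame (`family`, `sire`, `dam`) as from
#'   [familyStructure()].
#' @param offspringPerFamily offspring produced per family (default 50).
#' @param nSampled number of individuals kept (default 200).
#' @param seed integer seed.
#' @return a [GenotypeData-class] whose pedigree records id, sire, dam and
#'   family of every sampled offspring.
#' @export
makeFamilies <- function(founders, structure = familyStructure(),
                         offspringPerFamily = 50, nSampled = 200,
                         seed = NULL) {
  stopifnot(is(founders, "FounderPopulation"))
  if (offspringPerFamily < 1) stop("offspringPerFamily must be >= 1")
  bad <- setdiff(c(structure$sire, structure$dam), founders@ids)
  if (length(bad))
    stop("unknown parent id(s): ", paste(bad, collapse = ", "))
  nFam <- nrow(structure)
  total <- nFam * offspringPerFamily
  if (nSampled > total)
    stop("nSampled exceeds total offspring (", total, ")")
  if (!is.null(seed)) set.seed(seed)

  po <- founders@map@positions
  ch <- founders@map@chromosomes
  chromMarkers <- split(seq_len(nrow(po)), factor(po$chrom, ch$chrom))
  chromPos <- split(po$pos_morgan, factor(po$chrom, ch$chrom))
  chromLen <- ch$length_morgan

  slots <- sort(sample.int(total, nSampled))
  fam <- (slots - 1L) %/% offspringPerFamily + 1L
  within <- (slots - 1L) %% offspringPerFamily + 1L
  ids <- sprintf("F%02d_%02d", fam, within)

  d <- matrix(0, nSampled, nrow(po), dimnames = list(ids, po$marker_id))
  sireIdx <- match(structure$sire, founders@ids)
  damIdx <- match(structure$dam, founders@ids)
  for (i in seq_len(nSampled)) {
    f <- fam[i]
    d[i, ] <- .gamete(founders, sireIdx[f], chromMarkers, chromLen, chromPos) +
      .gamete(founders, damIdx[f], chromMarkers, chromLen, chromPos)
  }

  ped <- data.frame(id = ids, sire = structure$sire[fam],
                    dam = structure$dam[fam], family = fam,
                    stringsAsFactors = FALSE)
  mk <- data.frame(marker_id = po$marker_id, chrom = po$chrom,
                   pos = round(po$pos_morgan * 1e6) + 1L, ref = "A",
                   alt = "B", pos_morgan = po$pos_morgan,
                   stringsAsFactors = FALSE)
  genotypeData(d, markers = mk, pedigree = ped)
}

#' Construct a trait architecture
#'
#' @param nMarkers total marker count of the genotype panel.
#' @param nQtl number of causal loci (default 500 small-effect loci).
#' @param targetH2 narrow-sense heritability imposed on the realized sample.
#' @param targetMean,targetSd phenotype scale in trait units.
#' @param trait trait label.
#' @param qtlIndices,effects optional explicit QTL positions/effects;
#'   sampled (uniform indices, standard Gaussian effects) when NULL.
#' @param seed integer seed for the sampling.
#' @return a [TraitArchitecture-class].
#' @export
traitArchitecture <- function(nMarkers, nQtl = 500, targetH2 = 0.4,
                              targetMean = 0, targetSd = 1,
                              trait = "trait", qtlIndices = NULL,
                              effects = NULL, seed = NULL) {
  if (nQtl > nMarkers) stop("nQtl exceeds marker count")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(qtlIndices)) qtlIndices <- sort(sample.int(nMarkers, nQtl))
  if (is.null(effects)) effects <- stats::rnorm(nQtl)
  new("TraitArchitecture", nQtl = nQtl, qtlIndices = qtlIndices,
      effects = effects, targetH2 = targetH2, targetMean = targetMean,
      targetSd = targetSd, trait = trait)
}

#' Default growth-trait scales
#'
#' Phenotype calibration of the emulated study population: body weight
#' 5.56 g (SD 2.16) at h2 0.321, body length 76.99 mm (SD 9.95) at h2
#' 0.452.
#'
#' @return named list of per-trait defaults (h2, mean, sd, label).
#' @export
growthTraitDefaults <- function() {
  list(weight = list(h2 = 0.321, mean = 5.56, sd = 2.16,
                     trait = "body_weight_g"),
       length = list(h2 = 0.452, mean = 76.99, sd = 9.95,
                     trait = "body_length_mm"))
}

#' Simulate an additive polygenic trait
#'
#' Genetic values are `u = X[, qtl] %*% effects`; environmental noise is
#' drawn with variance `var(u) (1 - h2) / h2` so the realized sample sits at
#' the target heritability, and the phenotype is then affinely standardized
#' to the target mean/SD exactly (the genetic values receive the same scale
#' factor, leaving h2 untouched).
#'
#' @param genotypes complete [GenotypeData-class] (no missing entries).
#' @param arch a [TraitArchitecture-class].
#' @param seed integer seed.
#' @return data.frame with `id`, the observed phenotype (named after the
#'   trait label) and the true genetic value `tgv` (deviation scale, for
#'   testing).
#' @export
simulateTraits <- function(genotypes, arch, seed = NULL) {
  stopifnot(is(genotypes, "GenotypeData"), is(arch, "TraitArchitecture"))
  requireComplete(genotypes, "simulating traits")
  if (max(arch@qtlIndices) > nMarkers(genotypes))
    stop("QTL indices exceed marker count")
  if (!is.null(seed)) set.seed(seed)
  X <- genotypes@dosage
  u <- as.vector(X[, arch@qtlIndices, drop = FALSE] %*% arch@effects)
  n <- length(u)
  h2t <- arch@targetH2
  if (h2t == 0) {
    z <- stats::rnorm(n)
  } else {
    vu <- stats::var(u)
    if (vu <= 0)
      stop("zero genetic variance with targetH2 > 0; add polymorphic QTL")
    if (h2t == 1) {
      z <- u
    } else {
      # draw noise, then project out its sample covariance with u and
      # rescale so the realized sample satisfies
      # var(u) / (var(u) + V_E) = targetH2 exactly
      e <- stats::rnorm(n)
      uc <- u - mean(u)
      e <- e - mean(e) - uc * sum((e - mean(e)) * uc) / sum(uc^2)
      e <- e * sqrt(vu * (1 - h2t) / h2t / stats::var(e))
      z <- u + e
    }
  }
  sdz <- stats::sd(z)
  if (sdz <= 0) stop("degenerate phenotype (zero variance)")
  b <- arch@targetSd / sdz
  y <- arch@targetMean + b * (z - mean(z))
  out <- data.frame(id = individualIds(genotypes), y = y,
                    tgv = b * (u - mean(u)), stringsAsFactors = FALSE)
  names(out)[2] <- arch@trait
  names(out)[3] <- paste0("tgv_", arch@trait)
  out
}

#' Simulate the two growth traits with a shared-QTL genetic correlation
#'
#' Body weight and body length are generated from overlapping QTL sets: a
#' fraction of the QTL (default 0.7) is shared with identical effects,
#' which induces a positive genetic correlation between the traits.
#'
#' @param genotypes complete [GenotypeData-class].
#' @param nQtl causal loci per trait (default 500).
#' @param sharedQtlFraction fraction of QTL common to both traits.
#' @param h2Weight,h2Length target heritabilities (defaults 0.321 / 0.452).
#' @param seed integer seed.
#' @return phenotype data.frame with columns `id`, `body_weight_g`,
#'   `body_length_mm` and the matching `tgv_` columns; the two
#'   [TraitArchitecture-class] objects are attached as attribute
#'   `"architectures"`.
#' @export
simulateGrowthTraits <- function(genotypes, nQtl = 500,
                                 sharedQtlFraction = 0.7, h2Weight = 0.321,
                                 h2Length = 0.452, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- nMarkers(genotypes)
  defs <- growthTraitDefaults()
  nShared <- round(sharedQtlFraction * nQtl)
  nOwn <- nQtl - nShared
  pool <- sample.int(m, nShared + 2 * nOwn)
  shared <- pool[seq_len(nShared)]
  own1 <- pool[nShared + seq_len(nOwn)]
  own2 <- pool[nShared + nOwn + seq_len(nOwn)]
  effShared <- stats::rnorm(nShared)
  archW <- traitArchitecture(m, nQtl, targetH2 = h2Weight,
                             targetMean = defs$weight$mean,
                             targetSd = defs$weight$sd,
                             trait = defs$weight$trait,
                             qtlIndices = c(shared, own1),
                             effects = c(effShared, stats::rnorm(nOwn)))
  archL <- traitArchitecture(m, nQtl, targetH2 = h2Length,
                             targetMean = defs$length$mean,
                             targetSd = defs$length$sd,
                             trait = defs$length$trait,
                             qtlIndices = c(shared, own2),
                             effects = c(effShared, stats::rnorm(nOwn)))
  pw <- simulateTraits(genotypes, archW)
  pl <- simulateTraits(genotypes, archL)
  out <- cbind(pw, pl[, -1, drop = FALSE])
  attr(out, "architectures") <- list(weight = archW, length = archL)
  out
}

#' Inject missing genotype calls
#'
#' Entries are masked independently per (individual, marker) at the
#' marker's rate.
#'
#' @param genotypes a [GenotypeData-class].
#' @param rates per-marker missing rate: scalar, per-marker vector, or a
#'   function of the marker count.
#' @param seed integer seed.
#' @return a [GenotypeData-class] with `NA` entries injected.
#' @export
injectMissingness <- function(genotypes, rates = 0.03, seed = NULL) {
  stopifnot(is(genotypes, "GenotypeData"))
  m <- nMarkers(genotypes)
  r <- if (is.function(rates)) rates(m) else rep_len(rates, m)
  if (any(r < 0) || any(r > 1)) stop("missing rates must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  d <- genotypes@dosage
  n <- nrow(d)
  mask <- matrix(stats::runif(n * m), n, m) <
    matrix(r, n, m, byrow = TRUE)
  d[mask] <- NA_real_
  initialize(genotypes, dosage = d)
}

#' Simulate a complete study population in one call
#'
#' Founders, full-sib families, both growth traits, and optional
#' missingness, with all stage seeds derived from one master seed. Defaults
#' emulate the study population: 200 individuals sampled from 13 full-sib
#' families (13 sires x 13 dams, 50 offspring each), 23,049 SNPs on 44
#' chromosomes of 1 Morgan, 500 small-effect QTL per trait, h2 0.321
#' (weight) and 0.452 (length). Missingness defaults to 0 (the panel
#' emulates post-QC markers); set `missingRate` to exercise QC.
#'
#' @param nMarkers,nFamilies,offspringPerFamily,nSampled population layout.
#' @param nChromosomes,chromosomeLength genetic map layout.
#' @param mafSpec,ldDecay founder haplotype parameters
#'   (see [simulateFounders()]).
#' @param nQtl,sharedQtlFraction,h2Weight,h2Length trait architecture.
#' @param missingRate per-marker missing rate (0 = complete data).
#' @param seed master seed; stage seeds are derived deterministically.
#' @return list with `genotypes` ([GenotypeData-class]), `phenotypes`
#'   (data.frame), `founders` and `map`.
#' @examples
#' pop <- simulatePopulation(nMarkers = 500, nSampled = 60,
#'                           offspringPerFamily = 10, seed = 1)
#' dim(dosage(pop$genotypes))
#' @export
simulatePopulation <- function(nMarkers = 23049, nFamilies = 13,
                               offspringPerFamily = 50, nSampled = 200,
                               nChromosomes = 44, chromosomeLength = 1,
                               mafSpec = function(m) stats::runif(m, 0.05, 0.5),
                               ldDecay = 5, nQtl = 500,
                               sharedQtlFraction = 0.7, h2Weight = 0.321,
                               h2Length = 0.452, missingRate = 0, seed = 1) {
  map <- geneticMap(nMarkers, nChromosomes, chromosomeLength)
  founders <- simulateFounders(map, nSires = nFamilies, nDams = nFamilies,
                               mafSpec = mafSpec, ldDecay = ldDecay,
                               seed = deriveSeed(seed, "founders"))
  geno <- makeFamilies(founders, familyStructure(nFamilies),
                       offspringPerFamily = offspringPerFamily,
                       nSampled = nSampled,
                       seed = deriveSeed(seed, "families"))
  phen <- simulateGrowthTraits(geno, nQtl = nQtl,
                               sharedQtlFraction = sharedQtlFraction,
                               h2Weight = h2Weight, h2Length = h2Length,
                               seed = deriveSeed(seed, "traits"))
  observed <- geno
  if (any(missingRate > 0))
    observed <- injectMissingness(geno, rates = missingRate,
                                  seed = deriveSeed(seed, "missing"))
  list(genotypes = observed, phenotypes = phen, founders = founders,
       map = map)
}
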