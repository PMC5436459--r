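# Synthetic population generator: founder LD model, Mendelian gene drop,
# trait calibration and missingness injection.

test_that("founder allele frequencies converge to the MAF spec without LD", {
  map <- geneticMap(200, nChromosomes = 4)
  f <- simulateFounders(map, nSires = 5000, nDams = 5000, mafSpec = 0.5,
                        ldDecay = 0, seed = 1)
  freq <- colMeans(rbind(f@hap1, f@hap2))
  expect_true(all(abs(freq - 0.5) < 0.02))
})

test_that("co-located markers are perfectly correlated under strong LD", {
  map <- new("GeneticMap",
             chromosomes = data.frame(chrom = "chr01", length_morgan = 1),
             positions = data.frame(marker_id = c("a", "b"), chrom = "chr01",
                                    pos_morgan = c(0.5, 0.5)))
  f <- simulateFounders(map, nSires = 500, nDams = 500, mafSpec = 0.5,
                        ldDecay = 1e9, seed = 2)
  haps <- rbind(f@hap1, f@hap2)
  expect_equal(cor(haps[, 1], haps[, 2]), 1)
})

test_that("founder simulation is bit-reproducible under a fixed seed", {
  map <- geneticMap(1000, nChromosomes = 10)
  f1 <- simulateFounders(map, seed = 7)
  f2 <- simulateFounders(map, seed = 7)
  expect_identical(f1@hap1, f2@hap1)
  expect_identical(f1@hap2, f2@hap2)
  g1 <- makeFamilies(f1, offspringPerFamily = 10, nSampled = 50, seed = 3)
  g2 <- makeFamilies(f2, offspringPerFamily = 10, nSampled = 50, seed = 3)
  expect_identical(dosage(g1), dosage(g2))
})

test_that("mafSpec outside (0, 0.5] is rejected", {
  map <- geneticMap(10, nChromosomes = 1)
  expect_error(simulateFounders(map, mafSpec = 0.7), "0.5")
  expect_error(simulateFounders(map, mafSpec = 0), "0.5")
})

test_that("gametes from a homozygous parent are fixed, and zero-length
           chromosomes transmit intact haplotypes", {
  map <- geneticMap(50, nChromosomes = 1)
  f <- simulateFounders(map, nSires = 2, nDams = 2, seed = 5)
  # make sire S01 homozygous alt everywhere
  f@hap1["S01", ] <- 1L
  f@hap2["S01", ] <- 1L
  fam <- data.frame(family = 1, sire = "S01", dam = "D01")
  g <- makeFamilies(f, fam, offspringPerFamily = 20, nSampled = 20, seed = 6)
  # each offspring carries exactly one alt allele from the sire at every
  # marker, so dosage - dam gamete = 1 and dosage >= 1 everywhere
  expect_true(all(dosage(g) >= 1))

  map0 <- new("GeneticMap",
              chromosomes = data.frame(chrom = "chr01", length_morgan = 0),
              positions = data.frame(marker_id = sprintf("m%02d", 1:30),
                                     chrom = "chr01", pos_morgan = rep(0, 30)))
  f0 <- simulateFounders(map0, nSires = 1, nDams = 1, seed = 8)
  g0 <- makeFamilies(f0, data.frame(family = 1, sire = "S01", dam = "D01"),
                     offspringPerFamily = 30, nSampled = 30, seed = 9)
  # with no crossovers every maternal/paternal contribution is an intact
  # parental haplotype, so each offspring dosage row must be one of the four
  # possible haplotype sums
  sums <- rbind(f0@hap1["S01", ] + f0@hap1["D01", ],
                f0@hap1["S01", ] + f0@hap2["D01", ],
                f0@hap2["S01", ] + f0@hap1["D01", ],
                f0@hap2["S01", ] + f0@hap2["D01", ])
  match <- apply(dosage(g0), 1, function(row)
    any(apply(sums, 1, function(s) all(s == row))))
  expect_true(all(match))
})

test_that("offspring genotypes are Mendelian-consistent with their parents", {
  pop <- smallPop(nMarkers = 300, seed = 21)
  geno <- pop$genotypes
  ped <- pedigree(geno)
  fg <- dosage(founderGenotypes(pop$founders))
  d <- dosage(geno)
  for (i in seq_len(nrow(d))) {
    s <- fg[ped$sire[match(rownames(d)[i], ped$id)], ]
    dd <- fg[ped$dam[match(rownames(d)[i], ped$id)], ]
    lo <- (s == 2) + (dd == 2)
    hi <- 2 - ((s == 0) + (dd == 0))
    expect_true(all(d[i, ] >= lo & d[i, ] <= hi))
  }
})

test_that("unknown parent ids and oversampling are rejected", {
  map <- geneticMap(20, nChromosomes = 1)
  f <- simulateFounders(map, nSires = 2, nDams = 2, seed = 1)
  expect_error(makeFamilies(f, data.frame(family = 1, sire = "S09",
                                          dam = "D01")), "unknown parent")
  expect_error(makeFamilies(f, data.frame(family = 1, sire = "S01",
                                          dam = "D01"),
                            offspringPerFamily = 2, nSampled = 5),
               "exceeds")
})

test_that("full sibs average G about 0.5 and across-family pairs about 0", {
  pop <- smallPop(nMarkers = 5000, nFamilies = 13, nSampled = 130,
                  offspringPerFamily = 10, seed = 31)
  G <- kinshipValues(grmVanRaden(pop$genotypes))
  ped <- pedigree(pop$genotypes)
  fam <- ped$family[match(rownames(G), ped$id)]
  same <- outer(fam, fam, "==")
  ut <- upper.tri(G)
  expect_lt(abs(mean(G[same & ut]) - 0.5), 0.05)
  expect_lt(abs(mean(G[!same & ut])), 0.05)
})

test_that("trait simulation hits the limiting heritabilities", {
  pop <- smallPop(nMarkers = 400, seed = 11)
  geno <- pop$genotypes
  m <- nMarkers(geno)
  arch0 <- traitArchitecture(m, nQtl = 50, targetH2 = 0, seed = 1)
  cors <- sapply(1:20, function(s) {
    ph <- simulateTraits(geno, arch0, seed = s)
    cor(ph$tgv_trait, ph$trait)
  })
  expect_lt(abs(mean(cors)), 0.1)
  arch1 <- traitArchitecture(m, nQtl = 50, targetH2 = 1, seed = 1)
  ph1 <- simulateTraits(geno, arch1, seed = 1)
  expect_equal(cor(ph1$tgv_trait, ph1$trait), 1)
})

test_that("simulated phenotypes are calibrated to the configured scale", {
  pop <- smallPop(nMarkers = 400, seed = 12)
  defs <- growthTraitDefaults()
  means <- sds <- matrix(NA_real_, 10, 2)
  for (s in 1:10) {
    ph <- simulateGrowthTraits(pop$genotypes, nQtl = 80, seed = s)
    means[s, ] <- c(mean(ph$body_weight_g), mean(ph$body_length_mm))
    sds[s, ] <- c(sd(ph$body_weight_g), sd(ph$body_length_mm))
  }
  expect_equal(colMeans(means), c(defs$weight$mean, defs$length$mean),
               tolerance = 1e-10)
  expect_equal(colMeans(sds), c(defs$weight$sd, defs$length$sd),
               tolerance = 1e-10)
  # realized heritability matches the target exactly by construction
  ph <- simulateGrowthTraits(pop$genotypes, nQtl = 80, seed = 3)
  expect_equal(var(ph$tgv_body_weight_g) / var(ph$body_weight_g), 0.321,
               tolerance = 1e-8)
  expect_equal(var(ph$tgv_body_length_mm) / var(ph$body_length_mm), 0.452,
               tolerance = 1e-8)
})

test_that("shared QTL induce a positive genetic correlation", {
  pop <- smallPop(nMarkers = 800, seed = 13)
  ph <- simulateGrowthTraits(pop$genotypes, sharedQtlFraction = 0.7,
                             seed = 2)
  expect_gt(cor(ph$tgv_body_weight_g, ph$tgv_body_length_mm), 0.3)
})

test_that("missingness injection is exact at the rate limits", {
  pop <- smallPop(nMarkers = 100, seed = 14)
  g0 <- injectMissingness(pop$genotypes, rates = 0, seed = 1)
  expect_identical(dosage(g0), dosage(pop$genotypes))
  r <- c(1, rep(0, 99))
  g1 <- injectMissingness(pop$genotypes, rates = r, seed = 1)
  expect_true(all(is.na(dosage(g1)[, 1])))
  expect_true(!anyNA(dosage(g1)[, -1]))
  expect_error(injectMissingness(pop$genotypes, rates = 1.2), "0, 1")
})

test_that("markers exceeding the QC missingness bound match the binomial
           prediction", {
  nInd <- 200; nMark <- 2000; rate <- 0.03
  pop <- simulatePopulation(nMarkers = nMark, nSampled = nInd,
                            offspringPerFamily = 20, seed = 15)
  g <- injectMissingness(pop$genotypes, rates = rate, seed = 16)
  over <- sum(colSums(is.na(dosage(g))) > 0.05 * nInd)
  ptail <- pbinom(10, nInd, rate, lower.tail = FALSE)  # P(X > 10)
  expected <- ptail * nMark
  sdev <- sqrt(nMark * ptail * (1 - ptail))
  expect_lt(abs(over - expected), 4 * sdev + 1)
})
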