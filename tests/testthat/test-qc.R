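# Genotype IO, allele frequencies, QC filtering and imputation.

makeToy <- function() {
  d <- matrix(c(0, 1, 2, NA, 0,
                2, 2, NA, 1, 0,
                0, 0, 1, 2, 2,
                1, NA, 1, 1, 1), nrow = 5, ncol = 4)
  rownames(d) <- paste0("i", 1:5)
  colnames(d) <- paste0("m", 1:4)
  ped <- data.frame(id = rownames(d), sire = c("s1", "s1", "s1", "s2", "s2"),
                    dam = c("d1", "d1", "d1", "d2", "d2"),
                    family = c(1, 1, 1, 2, 2))
  genotypeData(d, pedigree = ped)
}

test_that("dosage TSV round-trips losslessly, including missing entries", {
  g <- makeToy()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeGenotypes(g, path, "dosage_tsv")
  g2 <- readGenotypes(path, "dosage_tsv")
  expect_identical(dosage(g2), dosage(g))
})

test_that("VCF round-trips GT calls and rejects bad inputs", {
  g <- makeToy()
  path <- withr::local_tempfile(fileext = ".vcf")
  writeGenotypes(g, path, "vcf")
  g2 <- readGenotypes(path, "vcf")
  expect_identical(dosage(g2), dosage(g))
  expect_identical(markerInfo(g2)$marker_id, markerIds(g))

  # multi-allelic record is refused by name
  lines <- readLines(path)
  lines[6] <- sub("\tB\t", "\tB,C\t", lines[6])
  bad <- withr::local_tempfile(fileext = ".vcf")
  writeLines(lines, bad)
  expect_error(readGenotypes(bad, "vcf"), "multi-allelic.*m2")

  # fractional dosages cannot be serialised as GT
  gf <- imputeMissing(g, "mean_dosage")
  expect_error(writeGenotypes(gf, path, "vcf"), "fractional")
})

test_that("phenotype and family tables round-trip", {
  ph <- data.frame(id = paste0("i", 1:3), body_weight_g = c(5.1, 6.2, 4.4),
                   body_length_mm = c(70, 81, 66))
  path <- withr::local_tempfile(fileext = ".tsv")
  writePhenotypes(ph, path)
  expect_equal(readPhenotypes(path), ph)
  fam <- data.frame(id = paste0("i", 1:3), sire = "s1", dam = "d1",
                    family = 1L)
  writeFamilies(fam, path)
  expect_equal(readFamilies(path), fam)
})

test_that("kinship matrices round-trip through TSV", {
  g <- smallPop(nMarkers = 100, seed = 5)$genotypes
  grm <- grmVanRaden(g)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeKinship(grm, path)
  m <- readKinship(path)
  expect_equal(m, kinshipValues(grm), tolerance = 1e-12)
})

test_that("allele frequencies, MAF and missing rates follow the hand counts", {
  af <- alleleFrequencies(makeToy())
  # m1: dosages 0,1,2,NA,0 -> p = 3/8, missing 1/5
  expect_equal(af$alt_freq[1], 3 / 8)
  expect_equal(af$maf[1], 3 / 8)
  expect_equal(af$missing_rate[1], 0.2)
  # m2: 2,2,NA,1,0 -> p = 5/8
  expect_equal(af$alt_freq[2], 5 / 8)
  expect_equal(af$maf[2], 3 / 8)
  # fixed marker
  g <- genotypeData(matrix(c(2, 2, 2, 2), 4, 1))
  af2 <- alleleFrequencies(g)
  expect_equal(af2$alt_freq, 1)
  expect_equal(af2$maf, 0)
  # all-missing marker is flagged, not fatal
  g3 <- genotypeData(matrix(c(NA, NA, 0, 1), 2, 2))
  af3 <- alleleFrequencies(g3)
  expect_true(is.na(af3$maf[1]))
})

test_that("qc filter removes markers strictly beyond the thresholds and
           keeps boundary markers", {
  set.seed(1)
  d <- matrix(rbinom(20 * 10, 2, 0.4), 20, 10)
  d[1:3, 1] <- NA                      # 15% missing -> removed
  d[, 2] <- 0; d[1, 2] <- 1            # MAF 1/40 = 0.025 -> removed
  d[1, 3] <- NA                        # 5% missing exactly -> kept
  d[, 4] <- 0; d[1:2, 4] <- 1          # MAF 2/40 = 0.05 exactly -> kept
  g <- genotypeData(d)
  out <- qcFilter(g, maxMissing = 0.05, minMaf = 0.05)
  expect_false(any(c("snp00001", "snp00002") %in% markerIds(out$genotypes)))
  expect_true(all(c("snp00003", "snp00004") %in% markerIds(out$genotypes)))
  rep <- out$report
  expect_equal(rep$n_markers_out, rep$n_markers_in - rep$n_removed)
  expect_equal(rep$n_markers_out, 8)

  # a marker failing both filters is counted once in the total
  d2 <- d
  d2[1:3, 5] <- NA
  d2[4:20, 5] <- 0
  out2 <- qcFilter(genotypeData(d2))
  expect_equal(out2$report$n_removed, 3)
  expect_equal(out2$report$n_markers_out, 7)

  # clean input passes through unchanged
  clean <- smallPop(nMarkers = 50, seed = 2,
                    mafSpec = function(m) runif(m, 0.3, 0.5))$genotypes
  out3 <- qcFilter(clean)
  expect_identical(dosage(out3$genotypes), dosage(clean))
  expect_equal(out3$report$n_removed, 0)
})

test_that("qc filtering is idempotent", {
  pop <- smallPop(nMarkers = 500, seed = 3)
  g <- injectMissingness(pop$genotypes, rates = runif(500, 0, 0.1),
                         seed = 4)
  once <- qcFilter(g)
  twice <- qcFilter(once$genotypes)
  expect_identical(dosage(twice$genotypes), dosage(once$genotypes))
  expect_equal(twice$report$n_removed, 0)
})

test_that("imputation fills means and never touches observed calls", {
  g <- makeToy()
  expect_identical(dosage(imputeMissing(smallPop(nMarkers = 20,
                                                 seed = 6)$genotypes)),
                   dosage(smallPop(nMarkers = 20, seed = 6)$genotypes))
  gm <- imputeMissing(g, "mean_dosage")
  d0 <- dosage(g); dm <- dosage(gm)
  expect_false(anyNA(dm))
  expect_identical(dm[!is.na(d0)], d0[!is.na(d0)])
  # m1 mean = 3/4
  expect_equal(dm["i4", "m1"], 0.75)

  # family mean when >= 2 members are called, else global mean
  d <- matrix(c(2, 2, 2, NA, 0, 0), 6, 1)
  rownames(d) <- paste0("i", 1:6); colnames(d) <- "m1"
  ped <- data.frame(id = rownames(d), sire = "s", dam = "d",
                    family = c(1, 1, 1, 1, 2, 2))
  gf <- imputeMissing(genotypeData(d, pedigree = ped), "family_mean")
  expect_equal(dosage(gf)["i4", "m1"], 2)
  d2 <- matrix(c(2, NA, 0, 0, 0), 5, 1)
  rownames(d2) <- paste0("i", 1:5); colnames(d2) <- "m1"
  ped2 <- data.frame(id = rownames(d2), sire = "s", dam = "d",
                     family = c(1, 1, 2, 2, 2))
  gf2 <- imputeMissing(genotypeData(d2, pedigree = ped2), "family_mean")
  expect_equal(dosage(gf2)["i2", "m1"], 0.5)  # global mean fallback

  # all-missing marker is a hard error
  dbad <- matrix(c(NA, NA, 1, 1), 2, 2)
  expect_error(imputeMissing(genotypeData(dbad)), "all-missing")
})

test_that("dosage TSV reader reports NA handling and duplicate ids", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tm1\tm2", "a\tNA\t1", "b\t2\t0"), path)
  g <- readGenotypes(path, "dosage_tsv")
  expect_true(is.na(dosage(g)["a", "m1"]))
  expect_equal(dosage(g)["b", "m1"], 2)
  writeLines(c("id\tm1", "a\t1", "a\t2"), path)
  expect_error(readGenotypes(path, "dosage_tsv"), "duplicate")
})
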