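# Readers/writers for the plain-text interchange formats: dosage TSV
# (canonical internal format), GT-only VCF v4.2, phenotype and family TSVs,
# and kinship matrix TSVs.

#' Read a genotype matrix
#'
#' @param path file path.
#' @param format `"dosage_tsv"` (individuals as rows, marker-id header,
#'   `NA` for missing) or `"vcf"` (biallelic GT-only records; `./.` for
#'   missing; multi-allelic sites are rejected).
#' @return a [GenotypeData-class].
#' @export
readGenotypes <- function(path, format = c("dosage_tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "dosage_tsv") .readDosageTsv(path) else .readVcf(path)
}

#' Write a genotype matrix
#'
#' Writing VCF requires integral dosages (fractional imputed values cannot
#' be expressed as GT calls); the dosage TSV accepts either.
#'
#' @param genotypes a [GenotypeData-class].
#' @param path output path.
#' @param format `"dosage_tsv"` or `"vcf"`.
#' @export
writeGenotypes <- function(genotypes, path,
                           format = c("dosage_tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "dosage_tsv") .writeDosageTsv(genotypes, path)
  else .writeVcf(genotypes, path)
  invisible(path)
}

.readDosageTsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = "NA", data.table = FALSE)
  if (names(dt)[1] != "id")
    stop("dosage TSV must start with an 'id' column (", path, ")")
  ids <- as.character(dt$id)
  if (anyDuplicated(ids)) stop("duplicate individual ids in ", path)
  d <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(d)) {
    bad <- which(!vapply(dt[-1], is.numeric, logical(1)))[1]
    stop("non-numeric dosage column '", names(dt)[-1][bad], "' in ", path)
  }
  rownames(d) <- ids
  genotypeData(d)
}

.writeDosageTsv <- function(genotypes, path) {
  d <- genotypes@dosage
  out <- data.frame(id = rownames(d), d, check.names = FALSE,
                    stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
}

.writeVcf <- function(genotypes, path) {
  d <- genotypes@dosage
  v <- d[!is.na(d)]
  if (any(v != round(v)))
    stop("fractional dosages cannot be written as VCF GT calls")
  mk <- genotypes@markers
  gt <- matrix("./.", nrow = ncol(d), ncol = nrow(d))
  codes <- c("0/0", "0/1", "1/1")
  obs <- !is.na(t(d))
  gt[obs] <- codes[t(d)[obs] + 1]
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=famGS",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(d)), collapse = "\t"))
  body <- paste(mk$chrom, mk$pos, mk$marker_id, mk$ref, mk$alt, ".", "PASS",
                ".", "GT", sep = "\t")
  body <- paste(body, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(lines, body), path)
}

.readVcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi))
    stop("multi-allelic VCF record(s) not supported: ",
         paste(utils::head(fix$ID[multi], 5), collapse = ", "))
  if (anyDuplicated(fix$ID)) stop("duplicate marker ids in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ids <- colnames(gt)
  if (anyDuplicated(ids)) stop("duplicate individual ids in ", path)
  gt0 <- gsub("\\|", "/", gt)
  dose <- matrix(NA_real_, nrow(gt0), ncol(gt0))
  dose[gt0 == "0/0"] <- 0
  dose[gt0 == "0/1" | gt0 == "1/0"] <- 1
  dose[gt0 == "1/1"] <- 2
  unknown <- !is.na(gt0) & is.na(dose) & gt0 != "./."
  if (any(unknown)) {
    bad <- which(unknown, arr.ind = TRUE)[1, ]
    stop("malformed GT '", gt0[bad[1], bad[2]], "' at record ", bad[1],
         " (", fix$ID[bad[1]], ")")
  }
  d <- t(dose)
  rownames(d) <- ids
  colnames(d) <- fix$ID
  mk <- data.frame(marker_id = fix$ID, chrom = fix$CHROM,
                   pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                   stringsAsFactors = FALSE)
  genotypeData(d, markers = mk)
}

#' Read / write phenotype tables
#'
#' TSV with columns `id`, `body_weight_g`, `body_length_mm` (additional
#' columns such as true genetic values pass through).
#'
#' @param path file path.
#' @return data.frame.
#' @export
readPhenotypes <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  if (names(dt)[1] != "id") stop("phenotype TSV must start with 'id'")
  if (anyDuplicated(dt$id)) stop("duplicate individual ids in ", path)
  meas <- grep("^(id|tgv_)", names(dt), invert = TRUE, value = TRUE)
  num <- dt[, meas, drop = FALSE]
  if (any(vapply(num, function(v) any(v[!is.na(v)] <= 0), logical(1))))
    warning("non-positive phenotype values in ", path)
  dt
}

#' @rdname readPhenotypes
#' @param phenotypes data.frame with an `id` column.
#' @export
writePhenotypes <- function(phenotypes, path) {
  data.table::fwrite(phenotypes, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read / write family (pedigree) tables
#'
#' TSV with columns `id`, `sire`, `dam`, `family`.
#' @param path file path.
#' @return data.frame.
#' @export
readFamilies <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(dt)))
    stop("family TSV needs columns id, sire, dam")
  dt
}

#' @rdname readFamilies
#' @param families data.frame.
#' @export
writeFamilies <- function(families, path) {
  data.table::fwrite(families, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read / write kinship matrices
#'
#' TSV with individual ids as the header row and first column.
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
readKinship <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- ids
  m
}

#' @rdname readKinship
#' @param kinship a [GRM-class], [IBSMatrix-class] or plain matrix.
#' @export
writeKinship <- function(kinship, path) {
  m <- if (is.matrix(kinship)) kinship else kinshipValues(kinship)
  out <- data.frame(id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
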