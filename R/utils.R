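# Internal helpers shared across modules.

# Deterministically derive a 31-bit stage seed from a master seed and a key.
# Simple polynomial string hash; stays below 2^31 - 1.
deriveSeed <- function(master, ...) {
  key <- paste(c(master, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Align a phenotype vector with a set of individual ids. Accepts an unnamed
# vector (assumed already aligned) or a named vector / data.frame column.
alignPhenotype <- function(ids, phenotypes, trait = NULL) {
  if (is.data.frame(phenotypes)) {
    if (is.null(trait))
      stop("supply `trait` when passing a phenotype data.frame")
    y <- stats::setNames(phenotypes[[trait]], phenotypes$id)
  } else {
    y <- phenotypes
  }
  if (!is.null(names(y))) {
    miss <- setdiff(ids, names(y))
    if (length(miss))
      stop("phenotypes missing for individuals: ",
           paste(utils::head(miss, 5), collapse = ", "))
    y <- y[ids]
  } else if (length(y) != length(ids)) {
    stop("unnamed phenotype vector has wrong length")
  }
  if (any(!is.finite(y))) stop("non-finite phenotypes")
  unname(y)
}

requireComplete <- function(genotypes, what = "this operation") {
  if (anyNA(genotypes@dosage))
    stop("genotypes contain missing entries; impute before ", what)
  invisible(TRUE)
}
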