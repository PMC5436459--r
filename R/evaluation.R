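# Cross-validation protocols and the prediction-accuracy statistic:
# five-fold CV with pooled out-of-fold GEBVs, marker-density subsampled CV,
# and the DIST/RAND relatedness designs built on a subpopulation
# assignment.

#' Genomic prediction accuracy
#'
#' Pearson correlation between GEBVs and observed phenotypes divided by the
#' square root of the trait heritability estimated on the full marker set;
#' the sign is preserved (negative accuracies are reported as-is).
#'
#' @param gebv named (or aligned) numeric vector of GEBVs.
#' @param phenotypes observed phenotypes for the same individuals.
#' @param h2Full full-marker heritability in (0, 1].
#' @return scalar accuracy (`|accuracy| <= 1 / sqrt(h2Full)`).
#' @export
accuracy <- function(gebv, phenotypes, h2Full) {
  if (h2Full <= 0 || h2Full > 1) stop("h2Full must lie in (0, 1]")
  y <- if (!is.null(names(gebv)) && !is.null(names(phenotypes)))
    phenotypes[names(gebv)] else phenotypes
  if (length(y) != length(gebv)) stop("gebv and phenotypes not aligned")
  if (length(y) < 3) stop("need at least 3 pairs")
  if (stats::var(y) == 0 || stats::var(gebv) == 0)
    stop("zero variance in GEBV or phenotype")
  stats::cor(gebv, y) / sqrt(h2Full)
}

# Balanced fold assignment: sizes differ by at most one, remainder folds
# chosen at random.
.foldAssignment <- function(n, nFolds) {
  sizes <- rep(n %/% nFolds, nFolds)
  extra <- n %% nFolds
  if (extra > 0) sizes[sample.int(nFolds, extra)] <- sizes[1] + 1
  rep(seq_len(nFolds), sizes)[sample.int(n)]
}

#' Five-fold cross-validation
#'
#' The sample is randomly partitioned into `nFolds` folds of near-equal
#' size; each fold is predicted by a model trained on the others, so every
#' individual receives exactly one out-of-fold GEBV. The reported accuracy
#' is computed on the pooled out-of-fold GEBVs; per-fold correlations are
#' kept for diagnostics.
#'
#' @param genotypes complete [GenotypeData-class].
#' @param phenotypes one trait.
#' @param model `"rrblup"`, `"bayesa"` or `"bl"`.
#' @param h2Full full-marker heritability for the accuracy denominator
#'   (REML-estimated from these genotypes when NULL).
#' @param seed integer seed for the partition.
#' @param config [McmcConfig-class] for the MCMC models.
#' @param nFolds number of folds (default 5).
#' @param trait column name when `phenotypes` is a data.frame.
#' @return list with `gebv` (named, one per individual), `accuracy`,
#'   `h2Full`, `folds` (assignment) and `perFold` correlations.
#' @export
fiveFoldCv <- function(genotypes, phenotypes, model = "rrblup",
                       h2Full = NULL, seed = 1, config = mcmcConfig(),
                       nFolds = 5, trait = NULL) {
  n <- nIndividuals(genotypes)
  if (n < 10) stop("need at least 10 individuals")
  y <- alignPhenotype(individualIds(genotypes), phenotypes, trait)
  names(y) <- individualIds(genotypes)
  if (is.null(h2Full))
    h2Full <- h2(remlH2(grmVanRaden(genotypes), y))
  set.seed(seed)
  folds <- .foldAssignment(n, nFolds)
  gebv <- stats::setNames(rep(NA_real_, n), individualIds(genotypes))
  perFold <- numeric(nFolds)
  for (f in seq_len(nFolds)) {
    holdout <- folds == f
    fit <- tryCatch(
      .fitModel(genotypes[!holdout, ], y[!holdout], model, config),
      error = function(e) stop("model ", model, " failed in fold ", f,
                               ": ", conditionMessage(e)))
    pred <- predictGebv(fit, genotypes[holdout, ])
    gebv[names(pred)] <- pred
    perFold[f] <- stats::cor(pred, y[names(pred)])
  }
  list(gebv = gebv, accuracy = accuracy(gebv, y, h2Full), h2Full = h2Full,
       folds = stats::setNames(folds, individualIds(genotypes)),
       perFold = perFold)
}

#' Accuracy as a function of marker density
#'
#' For each density, `nReps` uniform marker subsets are drawn; every model
#' runs five-fold CV on the same subset with the same fold partition, so
#' model comparisons are paired. With `includeFull = TRUE` the full panel
#' is run once per model as the reference.
#'
#' @param genotypes complete [GenotypeData-class].
#' @param phenotypes one trait.
#' @param models character vector of model names.
#' @param densities marker counts to subsample.
#' @param nReps subsets per density (default 50).
#' @param h2Full accuracy denominator (full-panel REML estimate when NULL).
#' @param seed master seed.
#' @param config [McmcConfig-class] for the MCMC models.
#' @param includeFull append a single full-panel reference run per model.
#' @param trait column name when `phenotypes` is a data.frame.
#' @return data.frame `(model, density, replicate, accuracy, h2_used)`;
#'   full-panel rows have `replicate = 0`.
#' @export
densityCv <- function(genotypes, phenotypes, models = "rrblup", densities,
                      nReps = 50, h2Full = NULL, seed = 1,
                      config = mcmcConfig(), includeFull = TRUE,
                      trait = NULL) {
  m <- nMarkers(genotypes)
  if (any(densities > m)) stop("density exceeds marker count (", m, ")")
  y <- alignPhenotype(individualIds(genotypes), phenotypes, trait)
  names(y) <- individualIds(genotypes)
  if (is.null(h2Full))
    h2Full <- h2(remlH2(grmVanRaden(genotypes), y))
  rows <- list()
  for (d in densities) {
    for (r in seq_len(nReps)) {
      set.seed(deriveSeed(seed, "densitycv", d, r))
      idx <- if (d == m) seq_len(m) else sort(sample.int(m, d))
      sub <- genotypes[, idx]
      foldSeed <- deriveSeed(seed, "folds", d, r)
      for (mod in models) {
        cv <- fiveFoldCv(sub, y, model = mod, h2Full = h2Full,
                         seed = foldSeed, config = config)
        rows[[length(rows) + 1]] <-
          data.frame(model = mod, density = d, replicate = r,
                     accuracy = cv$accuracy, h2_used = h2Full)
      }
    }
  }
  if (includeFull) {
    foldSeed <- deriveSeed(seed, "folds", m, 0)
    for (mod in models) {
      cv <- fiveFoldCv(genotypes, y, model = mod, h2Full = h2Full,
                       seed = foldSeed, config = config)
      rows[[length(rows) + 1]] <-
        data.frame(model = mod, density = m, replicate = 0,
                   accuracy = cv$accuracy, h2_used = h2Full)
    }
  }
  do.call(rbind, rows)
}

#' Build the DIST and RAND reference/validation designs
#'
#' DIST designs probe extrapolation to a genetically distant validation
#' set: one design per subpopulation larger than `minValidationSize`, with
#' that subpopulation held out entirely and all others combined as
#' training. RAND designs keep reference and validation related: each
#' replicate samples `trainFraction` of every subpopulation (stratified)
#' into training and validates on the remainder.
#'
#' @param assignment clustering from [kmeansClusters()] (or a named vector
#'   of cluster labels).
#' @param minValidationSize a subpopulation must exceed this size to serve
#'   as a DIST validation set (default 30).
#' @param trainFraction stratified training fraction for RAND (default
#'   0.8).
#' @param nRand number of RAND replicates (default 3).
#' @param seed integer seed for the stratified draws.
#' @return list of designs, each `list(name, train, validation)` of
#'   individual ids partitioning the sample.
#' @export
distRandDesigns <- function(assignment, minValidationSize = 30,
                            trainFraction = 0.8, nRand = 3, seed = 1) {
  cl <- if (is.list(assignment)) assignment$cluster else assignment
  if (is.null(names(cl))) stop("assignment needs individual ids as names")
  ids <- names(cl)
  designs <- list()
  sizes <- table(cl)
  big <- names(sizes)[sizes > minValidationSize]
  if (!length(big))
    warning("no subpopulation exceeds ", minValidationSize,
            "; DIST list is empty")
  for (i in seq_along(big)) {
    val <- ids[cl == big[i]]
    designs[[length(designs) + 1]] <-
      list(name = paste0("DIST", i), train = setdiff(ids, val),
           validation = val)
  }
  for (r in seq_len(nRand)) {
    set.seed(deriveSeed(seed, "rand", r))
    train <- character(0)
    for (s in names(sizes)) {
      members <- ids[cl == s]
      nTrain <- floor(trainFraction * length(members) + 1e-9)
      train <- c(train, sample(members, nTrain))
    }
    designs[[length(designs) + 1]] <-
      list(name = paste0("RAND", r), train = train,
           validation = setdiff(ids, train))
  }
  designs
}

#' Run models over a list of reference/validation designs
#'
#' Each model is trained on each design's training set with the full
#' marker panel and its accuracy computed on the design's validation set.
#'
#' @param genotypes complete [GenotypeData-class].
#' @param phenotypes one trait.
#' @param models character vector of model names (may be empty).
#' @param designs list of designs from [distRandDesigns()].
#' @param h2Full accuracy denominator (full-panel REML estimate when NULL).
#' @param config [McmcConfig-class] for the MCMC models.
#' @param trait column name when `phenotypes` is a data.frame.
#' @return data.frame `(design, model, accuracy, n_validation, h2_used)`.
#' @export
runDesigns <- function(genotypes, phenotypes, models, designs,
                       h2Full = NULL, config = mcmcConfig(), trait = NULL) {
  y <- alignPhenotype(individualIds(genotypes), phenotypes, trait)
  names(y) <- individualIds(genotypes)
  if (!length(models) || !length(designs))
    return(data.frame(design = character(), model = character(),
                      accuracy = numeric(), n_validation = integer(),
                      h2_used = numeric()))
  if (is.null(h2Full))
    h2Full <- h2(remlH2(grmVanRaden(genotypes), y))
  rows <- list()
  for (ds in designs) {
    if (stats::var(y[ds$validation]) == 0)
      stop("validation set of design ", ds$name,
           " has zero phenotype variance")
    for (mod in models) {
      fit <- .fitModel(genotypes[ds$train, ], y[ds$train], mod, config)
      pred <- predictGebv(fit, genotypes[ds$validation, ])
      rows[[length(rows) + 1]] <-
        data.frame(design = ds$name, model = mod,
                   accuracy = accuracy(pred, y[ds$validation], h2Full),
                   n_validation = length(ds$validation), h2_used = h2Full)
    }
  }
  do.call(rbind, rows)
}
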