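# End-to-end pipeline: simulate -> QC -> kinship -> heritability ->
# structure -> CV designs -> models -> report tables, driven by one config
# list (YAML-loadable), with stage seeds derived from a single master seed
# and a provenance manifest.

.knownModels <- c("rrblup", "bayesa", "bl")

#' Default pipeline configuration
#'
#' The `"fast"` profile is sized for routine runs (2,000 markers, short
#' chains, few replicates); `"study"` mirrors the emulated study layout
#' (23,049 markers, the full density ladder, 50 replicates, 40,000 / 10,000
#' chains) and takes correspondingly long.
#'
#' @param profile `"fast"` or `"study"`.
#' @return nested configuration list.
#' @export
pipelineConfig <- function(profile = c("fast", "study")) {
  profile <- match.arg(profile)
  fast <- profile == "fast"
  list(
    seed = 1,
    generator = list(
      n_markers = if (fast) 2000 else 23049,
      n_families = 13, offspring_per_family = 50, n_sampled = 200,
      n_chromosomes = 44, chromosome_length = 1, ld_decay = 5,
      n_qtl = 500, shared_qtl_fraction = 0.7,
      h2_weight = 0.321, h2_length = 0.452, missing_rate = 0.03),
    qc = list(max_missing = 0.05, min_maf = 0.05, impute = "mean_dosage"),
    h2 = list(
      densities = if (fast) c(50, 100, 200, 400, 800) else
        c(50, 100, 200, 400, 800, 1600, 3200, 6400, 12800, 20000),
      n_reps = if (fast) 5 else 50),
    structure = list(k = "auto", k_range = 2:10, n_dims = 3, n_starts = 50),
    cv = list(
      models = c("rrblup", "bayesa", "bl"),
      densities = if (fast) c(50, 200, 800) else
        c(50, 100, 200, 400, 800, 1600, 3200, 6400, 12800, 20000),
      n_reps = if (fast) 3 else 50,
      mcmc_iters = if (fast) 4000 else 40000,
      mcmc_burnin = if (fast) 1000 else 10000,
      min_validation_size = 30, train_fraction = 0.8, n_rand = 3))
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the profile defaults.
#'
#' @param path YAML file.
#' @param profile base profile supplying defaults.
#' @return configuration list.
#' @export
readPipelineConfig <- function(path, profile = "fast") {
  user <- yaml::read_yaml(path)
  base <- pipelineConfig(profile)
  merge2 <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge2(a[[nm]], b[[nm]]) else b[[nm]]
    }
    a
  }
  merge2(base, user)
}

#' Validate a pipeline configuration
#'
#' Fails fast (before any stage runs) on unknown model names, inconsistent
#' sizes, or out-of-range thresholds.
#'
#' @param config configuration list.
#' @return the config, invisibly.
#' @export
validatePipelineConfig <- function(config) {
  g <- config$generator
  if (g$n_sampled > g$n_families * g$offspring_per_family)
    stop("config: n_sampled exceeds total offspring")
  bad <- setdiff(config$cv$models, .knownModels)
  if (length(bad))
    stop("config: unknown model name(s): ", paste(bad, collapse = ", "))
  if (config$qc$max_missing < 0 || config$qc$max_missing > 1 ||
      config$qc$min_maf < 0 || config$qc$min_maf > 1)
    stop("config: QC thresholds must lie in [0, 1]")
  if (any(config$h2$densities > g$n_markers) ||
      any(config$cv$densities > g$n_markers))
    stop("config: density exceeds n_markers")
  if (!(identical(config$structure$k, "auto") ||
        is.numeric(config$structure$k)))
    stop("config: structure$k must be \"auto\" or an integer")
  invisible(config)
}

#' Run the full evaluation pipeline
#'
#' Executes simulate -> QC -> imputation -> kinship -> heritability (full
#' panel + density curve, both traits) -> stratification -> five-fold /
#' density / DIST-RAND cross-validation, writing every result as a TSV
#' under `outDir` together with a log and a provenance manifest (config
#' hash, stage seeds, output files). Reruns with the same config reproduce
#' all results exactly.
#'
#' @param config configuration list (see [pipelineConfig()]).
#' @param outDir output directory (created; must be empty or absent).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(config = pipelineConfig("fast"),
                        outDir = "famgs-run") {
  validatePipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(outDir, "pipeline.log")
  cat("", file = logFile)
  files <- character(0)
  t0 <- Sys.time()
  say <- function(stage, ...) {
    msg <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                   paste0(...))
    cat(msg, "\n", file = logFile, append = TRUE)
    message(msg)
  }
  emit <- function(obj, name, writer = writePhenotypes) {
    path <- file.path(outDir, name)
    writer(obj, path)
    files <<- c(files, name)
    path
  }

  cfgPath <- file.path(outDir, "config.yaml")
  yaml::write_yaml(config, cfgPath)
  files <- c(files, "config.yaml")
  cfgHash <- unname(tools::md5sum(cfgPath))
  seed <- config$seed
  g <- config$generator

  say("simulate", g$n_markers, " markers, ", g$n_families, " families, ",
      g$n_sampled, " individuals")
  pop <- simulatePopulation(
    nMarkers = g$n_markers, nFamilies = g$n_families,
    offspringPerFamily = g$offspring_per_family, nSampled = g$n_sampled,
    nChromosomes = g$n_chromosomes, chromosomeLength = g$chromosome_length,
    ldDecay = g$ld_decay, nQtl = g$n_qtl,
    sharedQtlFraction = g$shared_qtl_fraction, h2Weight = g$h2_weight,
    h2Length = g$h2_length, missingRate = g$missing_rate, seed = seed)
  emit(pop$genotypes, "genotypes_raw.tsv",
       function(o, p) writeGenotypes(o, p, "dosage_tsv"))
  emit(pop$phenotypes, "phenotypes.tsv")
  emit(pedigree(pop$genotypes), "families.tsv", writeFamilies)

  qc <- qcFilter(pop$genotypes, maxMissing = config$qc$max_missing,
                 minMaf = config$qc$min_maf)
  say("qc", qc$report$n_markers_in, " -> ", qc$report$n_markers_out,
      " markers (", qc$report$n_removed_missing, " missing-rate, ",
      qc$report$n_removed_maf, " MAF failures)")
  emit(qc$report$per_marker, "qc_report.tsv")
  raw <- qc$genotypes
  geno <- imputeMissing(raw, method = config$qc$impute)
  emit(geno, "genotypes_imputed.tsv",
       function(o, p) writeGenotypes(o, p, "dosage_tsv"))

  say("kinship", "GRM + IBS on ", nMarkers(geno), " markers")
  grm <- grmVanRaden(geno)
  ibs <- ibsMatrix(raw)
  emit(grm, "grm.tsv", writeKinship)
  emit(ibs, "ibs.tsv", writeKinship)

  traits <- c(weight = "body_weight_g", length = "body_length_mm")
  h2Full <- list()
  for (tr in names(traits)) {
    vc <- remlH2(grm, pop$phenotypes, trait = traits[[tr]])
    h2Full[[tr]] <- h2(vc)
    say("h2", tr, " full-panel h2 = ", sprintf("%.3f", h2(vc)))
    dens <- config$h2$densities[config$h2$densities <= nMarkers(geno)]
    curve <- h2DensityCurve(geno, pop$phenotypes, densities = dens,
                            nReps = config$h2$n_reps, trait = traits[[tr]],
                            seed = deriveSeed(seed, "h2", tr))
    emit(cbind(trait = traits[[tr]], curve),
         paste0("h2_density_", tr, ".tsv"))
    emit(cbind(trait = traits[[tr]], attr(curve, "summary")),
         paste0("h2_density_", tr, "_summary.tsv"))
  }

  say("structure", "IBS MDS + k-means")
  mds <- classicalMds(ibs, nDims = config$structure$n_dims)
  if (identical(config$structure$k, "auto")) {
    ck <- chooseK(mds, kRange = config$structure$k_range,
                  nStarts = config$structure$n_starts,
                  seed = deriveSeed(seed, "structure"))
    assignment <- ck$assignment
    emit(ck$diagnostics, "structure_k_diagnostics.tsv")
    say("structure", "silhouette-chosen k = ", ck$k)
  } else {
    assignment <- kmeansClusters(mds, k = config$structure$k,
                                 nStarts = config$structure$n_starts,
                                 seed = deriveSeed(seed, "structure"))
  }
  emit(data.frame(id = mds$ids, mds$coordinates,
                  subpopulation = assignment$cluster[mds$ids]),
       "structure_assignment.tsv")

  mc <- mcmcConfig(nIter = config$cv$mcmc_iters,
                   burnIn = config$cv$mcmc_burnin,
                   seed = deriveSeed(seed, "mcmc"))
  if (config$cv$mcmc_iters < 40000)
    say("cv", "NOTE: reduced MCMC profile (", config$cv$mcmc_iters, "/",
        config$cv$mcmc_burnin, " iterations)")
  designs <- distRandDesigns(
    assignment, minValidationSize = config$cv$min_validation_size,
    trainFraction = config$cv$train_fraction, nRand = config$cv$n_rand,
    seed = deriveSeed(seed, "designs"))

  results <- list(h2_full = h2Full)
  for (tr in names(traits)) {
    say("cv", "density CV, trait ", tr)
    dens <- config$cv$densities[config$cv$densities <= nMarkers(geno)]
    acc <- densityCv(geno, pop$phenotypes, models = config$cv$models,
                     densities = dens, nReps = config$cv$n_reps,
                     h2Full = h2Full[[tr]], trait = traits[[tr]],
                     seed = deriveSeed(seed, "cv", tr), config = mc)
    emit(cbind(trait = traits[[tr]], acc),
         paste0("accuracy_density_", tr, ".tsv"))
    say("cv", "DIST/RAND designs, trait ", tr)
    dr <- runDesigns(geno, pop$phenotypes, models = config$cv$models,
                     designs = designs, h2Full = h2Full[[tr]],
                     trait = traits[[tr]], config = mc)
    emit(cbind(trait = traits[[tr]], dr),
         paste0("accuracy_distrand_", tr, ".tsv"))
    results[[paste0("density_", tr)]] <- acc
    results[[paste0("distrand_", tr)]] <- dr
  }

  manifest <- list(
    config_md5 = cfgHash, master_seed = seed,
    created = format(t0, "%Y-%m-%d %H:%M:%S"),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = sort(files))
  manifestPath <- file.path(outDir, "manifest.yaml")
  yaml::write_yaml(manifest[c("config_md5", "master_seed", "files")],
                   manifestPath)
  say("done", length(files), " output files")
  invisible(c(results, list(manifest = manifest, outDir = outDir,
                            designs = designs)))
}
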