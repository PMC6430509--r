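## Readers/writers for the pipeline's tab-separated formats and the
## orchestrated end-to-end run. All files are UTF-8 TSV with `#`-prefixed
## comment headers carrying seed and config-hash provenance.

## djb2 string hash, reported in provenance headers.
configHash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

writeTsv <- function(df, path, provenance = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste("#", provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

readTsv <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read an ASV feature table from TSV
#'
#' Expects samples as rows: a `sample_id` column followed by one column
#' per ASV. Lines starting with `#` are comments.
#'
#' @param path file path.
#' @return a [FeatureTable-class].
#' @export
readFeatureTable <- function(path) {
  df <- tryCatch(readTsv(path), error = function(e)
    sbiError("parseError", "cannot parse '%s': %s", path,
             conditionMessage(e)))
  if (nrow(df) == 0 || ncol(df) < 2)
    sbiError("emptyTableError", "'%s' holds no counts", path)
  if (names(df)[1] != "sample_id")
    sbiError("parseError", "'%s': first column must be 'sample_id'", path)
  if (anyDuplicated(df$sample_id))
    sbiError("parseError", "'%s': duplicate sample id '%s'", path,
             df$sample_id[duplicated(df$sample_id)][1])
  if (anyDuplicated(names(df)[-1]))
    sbiError("parseError", "'%s': duplicate ASV id '%s'", path,
             names(df)[-1][duplicated(names(df)[-1])][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m))
    sbiError("parseError", "'%s': non-numeric counts", path)
  bad <- which(m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    sbiError("parseError",
             "'%s': negative count at sample '%s', ASV '%s'", path,
             df$sample_id[bad[1, 1]], colnames(m)[bad[1, 2]])
  rownames(m) <- df$sample_id
  FeatureTable(m[order(rownames(m)), , drop = FALSE], samplesAsRows = TRUE)
}

#' Write an ASV feature table to TSV
#'
#' @param ft a [FeatureTable-class].
#' @param path file path (samples as rows on disk).
#' @param provenance optional comment-header string.
#' @export
writeFeatureTable <- function(ft, path, provenance = NULL) {
  stopifnot(is(ft, "FeatureTable"))
  m <- t(counts(ft))
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  writeTsv(df, path, provenance)
}

#' Write a synthetic dataset as pipeline input files
#'
#' Writes `feature_table.tsv`, `metadata.tsv`, `weather.tsv`,
#' `taxonomy.tsv` plus the ground truth (`ground_truth_asvs.tsv`,
#' `ground_truth_samples.tsv`) into a directory.
#'
#' @param ds a [SyntheticDataset-class].
#' @param dir output directory, created if missing.
#' @return the directory, invisibly.
#' @export
writeDataset <- function(ds, dir) {
  stopifnot(is(ds, "SyntheticDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prov <- sprintf("soilSBI synthetic seed=%d config=%s", ds@config@seed,
                  configHash(ds@config))
  writeFeatureTable(ds@features, file.path(dir, "feature_table.tsv"), prov)
  writeTsv(ds@metadata, file.path(dir, "metadata.tsv"), prov)
  wx <- ds@weather
  wx$date <- format(wx$date, "%Y-%m-%d")
  writeTsv(wx, file.path(dir, "weather.tsv"), prov)
  writeTsv(ds@taxonomy, file.path(dir, "taxonomy.tsv"), prov)
  tr <- groundTruth(ds)
  writeTsv(data.frame(
    asv_id = c(tr$positive_set, tr$negative_set),
    sign = rep(c("+", "-"), c(length(tr$positive_set),
                              length(tr$negative_set)))),
    file.path(dir, "ground_truth_asvs.tsv"), prov)
  writeTsv(data.frame(sample_id = names(tr$microbial_component),
                      microbial_component = unname(tr$microbial_component)),
           file.path(dir, "ground_truth_samples.tsv"), prov)
  invisible(dir)
}

#' Assemble a pipeline configuration
#'
#' @param featurePath,metadataPath,weatherPath input TSV paths (see
#'   [writeDataset()] for the layouts).
#' @param taxonomyPath optional taxonomy TSV (`asv_id`, `phylum`).
#' @param outDir output directory.
#' @param alpha significance level for the screen (default 0.05).
#' @param minSamples prevalence filter threshold (default 2).
#' @param method correlation method for the screen (default "pearson").
#' @param normalized apply the orthonormal coefficient to the SBI
#'   (default `TRUE`).
#' @param deltaFrac zero-replacement fraction (default 0.65).
#' @param window optional weather date window (start, end).
#' @param conventionalGDD use the excess-above-base GDD variant
#'   (default `FALSE`).
#' @param seed integer seed recorded in provenance headers.
#' @return a validated config list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(featurePath, metadataPath, weatherPath,
                           taxonomyPath = NULL, outDir, alpha = 0.05,
                           minSamples = 2, method = "pearson",
                           normalized = TRUE, deltaFrac = 0.65,
                           window = NULL, conventionalGDD = FALSE,
                           seed = 0L) {
  if (!(alpha > 0 && alpha < 1))
    sbiError("configError", "alpha must lie in (0, 1)")
  for (p in c(featurePath, metadataPath, weatherPath, taxonomyPath))
    if (!file.exists(p))
      sbiError("configError", "input file not found: %s", p)
  structure(list(featurePath = featurePath, metadataPath = metadataPath,
                 weatherPath = weatherPath, taxonomyPath = taxonomyPath,
                 outDir = outDir, alpha = alpha, minSamples = minSamples,
                 method = method, normalized = normalized,
                 deltaFrac = deltaFrac, window = window,
                 conventionalGDD = conventionalGDD,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

## Run one pipeline stage, tagging any error with the stage name.
stage <- function(name, verbose, expr) {
  if (verbose) message("[soilSBI] stage: ", name)
  withCallingHandlers(expr, error = function(e) {
    e$message <- sprintf("stage '%s': %s", name, conditionMessage(e))
    stop(e)
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: weather indices, soil ilr balances,
#' standardization, the environmental yield model and residual yield,
#' the prevalence filter, zero imputation, clr transform, the
#' correlation screen and signed selection, the species balance index,
#' alpha diversity and index correlations, and the redundancy analysis
#' with the SBI contour surface. Every intermediate artifact is written
#' to `cfg$outDir` as TSV with a provenance header (seed + config hash);
#' stage counts are logged with `verbose = TRUE`.
#'
#' If both selection sets are empty the correlation table is still
#' written before an `sbiUndefinedError` is raised.
#'
#' @param cfg a [pipelineConfig()] list.
#' @param verbose log stage progress to stderr (default `FALSE`).
#' @return invisible list with every major result object.
#' @export
runPipeline <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  ## hash analysis parameters only, not file locations
  prov <- sprintf("soilSBI seed=%d config=%s", cfg$seed,
                  configHash(cfg[setdiff(names(cfg),
                                         c("featurePath", "metadataPath",
                                           "weatherPath", "taxonomyPath",
                                           "outDir"))]))
  out <- function(f) file.path(cfg$outDir, f)

  ft <- stage("read_inputs", verbose, readFeatureTable(cfg$featurePath))
  metadata <- readTsv(cfg$metadataPath)
  metadata <- metadata[order(metadata$sample_id), , drop = FALSE]
  weather <- readTsv(cfg$weatherPath)
  taxonomy <- if (!is.null(cfg$taxonomyPath)) readTsv(cfg$taxonomyPath)
  if (!identical(metadata$sample_id, sampleIds(ft)))
    sbiError("parseError",
             "metadata and feature table sample ids disagree")

  wx <- stage("weather_indices", verbose, {
    w <- weatherIndices(weather, window = cfg$window,
                        conventional = cfg$conventionalGDD)
    writeTsv(w, out("weather_indices.tsv"), prov)
    w
  })

  predictors <- stage("soil_balances", verbose, {
    x <- buildPredictors(metadata, wx)
    writeTsv(data.frame(sample_id = rownames(x), x, check.names = FALSE),
             out("balances.tsv"), prov)
    x
  })

  model <- stage("yield_model", verbose, {
    xs <- standardizePredictors(predictors)
    m <- fitYieldModel(xs, metadata$yield_t_ha)
    writeTsv(data.frame(predictor = names(m@coefficients),
                        slope = unname(m@coefficients),
                        ci_low = unname(m@ciLow),
                        ci_high = unname(m@ciHigh),
                        p = unname(m@pValues)),
             out("coefficients.tsv"), prov)
    writeTsv(data.frame(sample_id = names(residualYield(m)),
                        residual_yield = unname(residualYield(m))),
             out("residuals.tsv"), prov)
    m
  })
  residual <- residualYield(model)

  filtered <- stage("feature_filter", verbose, {
    f <- filterFeatures(ft, cfg$minSamples)
    if (verbose)
      message(sprintf("[soilSBI]   ASVs: %d in, %d kept",
                      length(asvIds(ft)), length(asvIds(f))))
    writeFeatureTable(f, out("filtered_counts.tsv"), prov)
    f
  })

  imputed <- stage("zero_imputation", verbose,
                   imputeZeros(filtered, cfg$deltaFrac))
  clr <- stage("clr_transform", verbose, clrTransform(imputed))

  correlations <- stage("correlation_screen", verbose, {
    co <- correlateAsvs(clr, residual, alpha = cfg$alpha,
                        method = cfg$method)
    writeTsv(co, out("correlations.tsv"), prov)
    co
  })
  sets <- selectSignificant(correlations, alpha = cfg$alpha)
  if (verbose)
    message(sprintf("[soilSBI]   selected: %d positive, %d negative",
                    length(sets$positive), length(sets$negative)))

  sbiRes <- stage("species_balance_index", verbose, {
    r <- computeSBI(imputed, sets$positive, sets$negative,
                    correlations = correlations,
                    normalized = cfg$normalized)
    writeTsv(data.frame(sample_id = names(sbiValues(r)),
                        sbi_py = unname(sbiValues(r))),
             out("sbi.tsv"), prov)
    if (!is.null(taxonomy))
      writeTsv(tallyByPhylum(sets$positive, sets$negative, taxonomy),
               out("phylum_tally.tsv"), prov)
    r
  })

  diversity <- stage("alpha_diversity", verbose, {
    d <- diversityProfile(ft)
    writeTsv(d, out("diversity.tsv"), prov)
    d
  })
  indexCor <- stage("index_correlations", verbose, {
    ic <- correlateIndices(diversity, sbiValues(sbiRes),
                           setNames(metadata$yield_t_ha,
                                    metadata$sample_id), residual)
    writeTsv(ic, out("index_correlations.tsv"), prov)
    ic
  })

  rda <- stage("redundancy_analysis", verbose, {
    r <- fitRda(clr, standardizePredictors(predictors))
    writeTsv(data.frame(
      axis = c(paste0("RDA", seq_along(r@eigConstrained)),
               paste0("PC", seq_along(r@eigUnconstrained))),
      block = rep(c("constrained", "unconstrained"),
                  c(length(r@eigConstrained),
                    length(r@eigUnconstrained))),
      eigenvalue = c(r@eigConstrained, r@eigUnconstrained)),
      out("rda_eigenvalues.tsv"), prov)
    writeTsv(data.frame(sample_id = rownames(r@siteScores), r@siteScores),
             out("rda_site_scores.tsv"), prov)
    writeTsv(data.frame(asv_id = rownames(r@speciesScores),
                        r@speciesScores),
             out("rda_species_scores.tsv"), prov)
    writeTsv(data.frame(predictor = rownames(r@biplotScores),
                        r@biplotScores),
             out("rda_biplot_scores.tsv"), prov)
    r
  })
  surface <- stage("index_surface", verbose, {
    s <- projectIndex(rda, sbiValues(sbiRes)[rownames(rda@siteScores)])
    writeTsv(s$grid, out("sbi_surface_grid.tsv"), prov)
    s
  })

  invisible(list(weatherIndices = wx, predictors = predictors,
                 model = model, filtered = filtered, imputed = imputed,
                 clr = clr, correlations = correlations, sets = sets,
                 sbi = sbiRes, diversity = diversity,
                 indexCorrelations = indexCor, rda = rda,
                 surface = surface))
}
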