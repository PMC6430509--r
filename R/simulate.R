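## Synthetic field-study generator: produces a complete input bundle
## (ASV counts, soil/yield metadata, daily weather, taxonomy) with known
## ground truth, so the whole pipeline is testable without field data.

#' Build a simulation configuration
#'
#' Defaults emulate the targeted study design: 13 potato fields with 4
#' plots each and one plot lost (51 samples), ~2000 ASVs at a mean
#' sequencing depth of 18000, sand-to-loam soil textures, planted yield
#' effects of -4 and -3 t/ha per unit of the two texture balances, and a
#' latent microbial yield component to which 30 positively and 20
#' negatively planted ASVs respond.
#'
#' @param nFields number of fields (default 13).
#' @param plotsPerField plots per field (default 4).
#' @param dropSamples plots removed from one field to mimic a lost
#'   sample (default 1, giving 51 samples at the defaults).
#' @param nAsvs number of ASVs (default 2000).
#' @param nPositivePlanted,nNegativePlanted planted ASVs responding
#'   positively / negatively to the microbial component (defaults 30/20).
#' @param textureEffects named numeric yield slopes per unit of each soil
#'   balance (t/ha); defaults: -4 on `[Clay | Silt,Sand]`, -3 on
#'   `[Silt | Sand]`, 0 elsewhere.
#' @param microbialEffectSd sd of the latent microbial yield component
#'   (t/ha, default 5).
#' @param plantedEffect clr-scale shift of a planted ASV per sd of the
#'   microbial component (log units, default 1.2).
#' @param asvNoiseSd within-sample log-abundance noise sd (default 0.8).
#' @param baselineSd across-ASV baseline log-abundance sd (default 1.5).
#' @param yieldNoiseSd residual yield noise sd (t/ha, default 3).
#' @param yieldIntercept baseline yield (t/ha, default 38).
#' @param sequencingDepth mean library size (default 18000).
#' @param nDays length of the daily weather series (default 120).
#' @param seed mandatory integer seed; all randomness derives from it.
#' @return a validated [SimulationConfig-class].
#' @export
simulationConfig <- function(nFields = 13, plotsPerField = 4,
                             dropSamples = 1, nAsvs = 2000,
                             nPositivePlanted = 30, nNegativePlanted = 20,
                             textureEffects = c(
                               "[Clay,Silt,Sand | N,C]" = 0,
                               "[Clay | Silt,Sand]" = -4,
                               "[Silt | Sand]" = -3,
                               "[N | C]" = 0),
                             microbialEffectSd = 5, plantedEffect = 1.2,
                             asvNoiseSd = 0.8, baselineSd = 1.5,
                             yieldNoiseSd = 3, yieldIntercept = 38,
                             sequencingDepth = 18000, nDays = 120,
                             seed) {
  if (missing(seed))
    sbiError("configError", "an explicit seed is required")
  cfg <- tryCatch(new("SimulationConfig",
             nFields = as.integer(nFields),
             plotsPerField = as.integer(plotsPerField),
             dropSamples = as.integer(dropSamples),
             nAsvs = as.integer(nAsvs),
             nPositivePlanted = as.integer(nPositivePlanted),
             nNegativePlanted = as.integer(nNegativePlanted),
             textureEffects = textureEffects,
             microbialEffectSd = microbialEffectSd,
             plantedEffect = plantedEffect,
             asvNoiseSd = asvNoiseSd, baselineSd = baselineSd,
             yieldNoiseSd = yieldNoiseSd, yieldIntercept = yieldIntercept,
             sequencingDepth = sequencingDepth, nDays = as.integer(nDays),
             seed = as.integer(seed)),
    error = function(e) sbiError("configError", conditionMessage(e)))
  validObject(cfg)
  cfg
}

## Texture class centroids as (sand, silt, clay) percentages of the
## mineral fraction; spans the sand-to-loam range of the study area.
TEXTURE_CENTROIDS <- list(
  sand = c(90, 6, 4), loamy_sand = c(80, 12, 8),
  sandy_loam = c(65, 23, 12), loam = c(42, 38, 20))

#' Simulate a complete field-study dataset
#'
#' Draws (1) per-field soil compositions around sand / loamy-sand /
#' sandy-loam / loam centroids with within-field jitter on the log-ratio
#' scale, plus C, N and pH in realistic agronomic ranges; (2) one daily
#' weather series per field (gamma rainfall, a seasonal temperature
#' curve); (3) a latent microbial yield component per sample, log-normal
#' ASV abundances in which planted ASVs shift with that component, and
#' multinomial counts at the configured depth; (4) plot yields as
#' intercept + texture-balance effects + microbial component + noise.
#' Fully reproducible from the seed.
#'
#' @param cfg a [SimulationConfig-class].
#' @return a [SyntheticDataset-class].
#' @export
simulateDataset <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  set.seed(cfg@seed)
  nf <- cfg@nFields
  fieldIds <- sprintf("F%02d", seq_len(nf))

  ## --- sampling frame: fields x plots, minus dropped plots -------------
  field <- rep(fieldIds, each = cfg@plotsPerField)
  plot <- rep(seq_len(cfg@plotsPerField), times = nf)
  if (cfg@dropSamples > 0) {
    dropField <- fieldIds[min(12L, nf)]   # the field with the lost plot
    idx <- which(field == dropField)
    drop <- utils::tail(idx, min(cfg@dropSamples, length(idx)))
    field <- field[-drop]; plot <- plot[-drop]
  }
  sampleIds <- sprintf("%sP%d", field, plot)
  n <- length(sampleIds)

  ## --- soils ------------------------------------------------------------
  ## Field texture classes roughly in the study's sand-heavy proportions.
  classPool <- rep(c("sand", "loamy_sand", "sandy_loam", "loam"),
                   times = pmax(1, round(nf * c(8, 2, 2, 1) / 13)))
  fieldClass <- rep(classPool, length.out = nf)
  fieldTexture <- t(vapply(fieldClass, function(cl) {
    cen <- TEXTURE_CENTROIDS[[cl]]
    exp(log(cen) + rnorm(3, sd = 0.10))  # field-level clr-scale jitter
  }, numeric(3)))
  fieldC <- runif(nf, 1.5, 2.8)
  fieldPh <- runif(nf, 4.6, 6.2)
  fi <- match(field, fieldIds)
  tex <- fieldTexture[fi, , drop = FALSE] *
    exp(matrix(rnorm(3 * n, sd = 0.05), n, 3))    # plot-level jitter
  tex <- 100 * tex / rowSums(tex)
  c_pct <- pmax(0.6, fieldC[fi] + rnorm(n, sd = 0.20))
  n_pct <- pmax(0.03, c_pct / 13 + rnorm(n, sd = 0.02))
  ph <- fieldPh[fi] + rnorm(n, sd = 0.15)

  ## --- weather (one series per field; plots share it) -------------------
  dates <- as.Date("2013-05-15") + seq_len(cfg@nDays) - 1L
  weather <- do.call(rbind, lapply(fieldIds, function(f) {
    shape <- runif(1, 0.2, 0.5)          # rainfall evenness
    meanRain <- runif(1, 2, 4)           # mm/day
    rain <- rgamma(cfg@nDays, shape = shape, scale = meanRain / shape)
    rain[rain < 0.05] <- 0               # trace amounts read as dry days
    tmean <- 14 + 8 * sin(pi * seq_len(cfg@nDays) / cfg@nDays) +
      rnorm(1, sd = 1) + rnorm(cfg@nDays, sd = 2)
    data.frame(field_id = f, date = dates, rain_mm = rain, tmean_c = tmean)
  }))

  ## --- microbiome with planted signal -----------------------------------
  m <- rnorm(n, sd = cfg@microbialEffectSd)      # latent yield component
  mStd <- if (cfg@microbialEffectSd > 0) m / cfg@microbialEffectSd else
    rep(0, n)
  asvIds <- sprintf("ASV%04d", seq_len(cfg@nAsvs))
  posSet <- asvIds[seq_len(cfg@nPositivePlanted)]
  negSet <- asvIds[cfg@nPositivePlanted + seq_len(cfg@nNegativePlanted)]
  w <- setNames(rep(0, cfg@nAsvs), asvIds)
  w[posSet] <- cfg@plantedEffect
  w[negSet] <- -cfg@plantedEffect
  base <- rnorm(cfg@nAsvs, sd = cfg@baselineSd)
  ## Planted taxa must be observable at the configured depth: an effect
  ## planted in an ASV whose expected count is ~0 is unrecoverable by any
  ## screen, which is not the mechanism being emulated. Fold their
  ## baselines to the upper half of the abundance distribution.
  planted <- c(seq_len(cfg@nPositivePlanted),
               cfg@nPositivePlanted + seq_len(cfg@nNegativePlanted))
  base[planted] <- abs(base[planted])
  logAbund <- matrix(base, n, cfg@nAsvs, byrow = TRUE) +
    outer(mStd, w) +
    matrix(rnorm(n * cfg@nAsvs, sd = cfg@asvNoiseSd), n, cfg@nAsvs)
  probs <- exp(logAbund - apply(logAbund, 1, max))
  probs <- probs / rowSums(probs)
  depth <- pmax(1000, round(rnorm(n, cfg@sequencingDepth,
                                  0.08 * cfg@sequencingDepth)))
  countsM <- t(vapply(seq_len(n),
                      function(j) rmultinom(1, depth[j], probs[j, ])[, 1],
                      numeric(cfg@nAsvs)))
  dimnames(countsM) <- list(sampleIds, asvIds)

  ## --- yield ------------------------------------------------------------
  soil <- closeComposition(cbind(Sand = tex[, 1], Silt = tex[, 2],
                                 Clay = tex[, 3], C = c_pct, N = n_pct))
  rownames(soil) <- sampleIds
  bal <- ilrAll(soil, soilBalancePartition())
  eff <- cfg@textureEffects[colnames(bal)]
  eff[is.na(eff)] <- 0
  yield <- cfg@yieldIntercept + as.vector(bal %*% eff) + m +
    rnorm(n, sd = cfg@yieldNoiseSd)

  metadata <- data.frame(
    sample_id = sampleIds, field_id = field,
    sand_pct = tex[, 1], silt_pct = tex[, 2], clay_pct = tex[, 3],
    c_pct = c_pct, n_pct = n_pct, ph = ph, yield_t_ha = yield,
    row.names = NULL)

  ## --- taxonomy ---------------------------------------------------------
  phyla <- c("Proteobacteria", "Actinobacteria", "Acidobacteria",
             "Chloroflexi", "Bacteroidetes", "Gemmatimonadetes",
             "Verrucomicrobia", "Planctomycetes", "Firmicutes",
             "Nitrospirae", "Saccharibacteria", "Armatimonadetes")
  taxonomy <- data.frame(
    asv_id = asvIds,
    phylum = sample(phyla, cfg@nAsvs, replace = TRUE,
                    prob = c(28, 18, 12, 10, 9, 7, 5, 4, 3, 2, 1, 1)),
    row.names = NULL)

  truth <- list(positive_set = posSet, negative_set = negSet,
                texture_effects = cfg@textureEffects,
                microbial_component = setNames(m, sampleIds),
                yield_intercept = cfg@yieldIntercept)

  ds <- new("SyntheticDataset",
            features = FeatureTable(countsM, samplesAsRows = TRUE),
            metadata = metadata, weather = weather, taxonomy = taxonomy,
            truth = truth, config = cfg)
  validObject(ds)
  ds
}

#' Ground truth of a synthetic dataset
#'
#' @param ds a [SyntheticDataset-class].
#' @return list with `positive_set`, `negative_set` (planted ASV ids),
#'   `texture_effects` (true yield slopes per balance unit),
#'   `microbial_component` (the latent per-sample yield component, t/ha)
#'   and `yield_intercept`.
#' @export
groundTruth <- function(ds) {
  stopifnot(is(ds, "SyntheticDataset"))
  ds@truth
}

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf(
    "SyntheticDataset: %d samples in %d fields, %d ASVs (seed %d)\n",
    nrow(object@metadata), length(unique(object@metadata$field_id)),
    length(asvIds(object@features)), object@config@seed))
  cat(sprintf("  planted: %d positive, %d negative; yields %.1f-%.1f t/ha\n",
              length(object@truth$positive_set),
              length(object@truth$negative_set),
              min(object@metadata$yield_t_ha),
              max(object@metadata$yield_t_ha)))
})
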