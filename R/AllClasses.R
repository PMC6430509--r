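#' @import methods
NULL

#' Balance partition over compositional parts
#'
#' A strictly bifurcating (sequential binary) partition of a set of named
#' compositional parts. Each internal node of the tree splits one part
#' subset into a denominator subset and a numerator subset and defines one
#' isometric log-ratio (ilr) balance; a D-part composition yields D-1
#' balances. Node labels follow the field convention
#' `[denominator | numerator]`, so the balance is positive when the
#' numerator subset dominates.
#'
#' @slot parts character vector of all part names covered by the partition.
#' @slot nodes list of D-1 nodes; each node is a list with character vector
#'   elements `num` (numerator part set), `den` (denominator part set) and a
#'   scalar `label`.
#'
#' @seealso [balancePartition()], [soilBalancePartition()], [ilrBalance()]
#' @export
setClass("BalancePartition",
  representation(parts = "character", nodes = "list"))

setValidity("BalancePartition", function(object) {
  parts <- object@parts
  if (anyDuplicated(parts)) return("part names must be unique")
  if (length(object@nodes) != length(parts) - 1L)
    return(sprintf("a %d-part composition needs %d nodes, got %d",
                   length(parts), length(parts) - 1L, length(object@nodes)))
  ## Strict bifurcation: walk top-down; each node must split a subset that
  ## is either the full part set (root) or a side of an earlier node.
  open <- list(sort(parts))
  for (nd in object@nodes) {
    if (!all(c("num", "den", "label") %in% names(nd)))
      return("each node needs 'num', 'den' and 'label'")
    if (length(intersect(nd$num, nd$den)) > 0)
      return("numerator and denominator sets overlap")
    whole <- sort(c(nd$num, nd$den))
    hit <- which(vapply(open, identical, logical(1), y = whole))
    if (length(hit) == 0)
      return(sprintf("node '%s' does not split an available subset", nd$label))
    open <- open[-hit[1]]
    if (length(nd$num) > 1) open <- c(open, list(sort(nd$num)))
    if (length(nd$den) > 1) open <- c(open, list(sort(nd$den)))
  }
  TRUE
})

#' ASV feature table
#'
#' A samples-by-ASV table of non-negative integer counts, stored in the
#' Bioconductor orientation (features as rows, samples as columns) on top of
#' [SummarizedExperiment::SummarizedExperiment] with a single `counts`
#' assay. Sample identifiers are column names, ASV identifiers row names.
#'
#' @seealso [FeatureTable()], [filterFeatures()], [imputeZeros()]
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  m <- SummarizedExperiment::assay(object, "counts")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("ASV (row) and sample (column) names are required")
  if (anyDuplicated(rownames(m))) return("duplicate ASV ids")
  if (anyDuplicated(colnames(m))) return("duplicate sample ids")
  if (ncol(m) < 2) return("at least 2 samples required")
  if (any(m < 0)) return("counts must be non-negative")
  if (!is_wholenumber(m)) return("counts must be integers")
  TRUE
})

#' Yield detrending model
#'
#' Ordinary least-squares fit of plot yield (t/ha) on standardized
#' environmental and physico-chemical predictors. The residuals are the
#' *residual yield* — the part of yield unexplained by the environment —
#' which downstream modules correlate with the microbiome.
#'
#' @slot coefficients named numeric slopes (t/ha per predictor SD), without
#'   the intercept.
#' @slot intercept numeric scalar.
#' @slot ciLow,ciHigh 95% confidence bounds per slope (t-distribution,
#'   n - p - 1 df).
#' @slot pValues two-sided p-values per slope.
#' @slot residuals per-sample residual yield (t/ha), named by sample.
#' @slot fitted per-sample fitted yield.
#' @slot rSquared coefficient of determination.
#' @slot fit the underlying [stats::lm] object.
#'
#' @seealso [fitYieldModel()], [significantPredictors()]
#' @export
setClass("YieldModel",
  representation(coefficients = "numeric", intercept = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", pValues = "numeric",
                 residuals = "numeric", fitted = "numeric",
                 rSquared = "numeric", fit = "ANY"))

setValidity("YieldModel", function(object) {
  if (abs(sum(object@residuals)) > 1e-8 * max(1, sum(abs(object@residuals))))
    return("residuals must sum to 0")
  if (any(object@ciLow > object@coefficients + 1e-12) ||
      any(object@ciHigh < object@coefficients - 1e-12))
    return("confidence bounds must bracket the coefficients")
  TRUE
})

#' Species balance index result
#'
#' The signed ASV sets selected by the correlation screen together with the
#' per-sample species balance index: the (optionally normalized) log-ratio
#' of geometric means of the positively associated ASVs (numerator) over
#' the negatively associated ones (denominator).
#'
#' @slot positiveSet,negativeSet character vectors of ASV ids.
#' @slot correlations data.frame with columns `asv_id`, `r`, `p`, `sign`.
#' @slot sbi named per-sample index values (log-ratio units).
#' @slot normalized logical; whether the orthonormal balance coefficient
#'   sqrt(rs/(r+s)) was applied.
#'
#' @seealso [computeSBI()], [selectSignificant()]
#' @export
setClass("SbiResult",
  representation(positiveSet = "character", negativeSet = "character",
                 correlations = "data.frame", sbi = "numeric",
                 normalized = "logical"))

setValidity("SbiResult", function(object) {
  if (length(intersect(object@positiveSet, object@negativeSet)) > 0)
    return("positive and negative sets must be disjoint")
  if (length(object@sbi) && any(!is.finite(object@sbi)))
    return("sbi values must be finite")
  TRUE
})

#' Redundancy analysis result
#'
#' Constrained ordination of a (column-centred) response matrix on
#' standardized predictors: a PCA of the multivariate-OLS fitted values
#' (constrained axes) and of the residuals (unconstrained axes), with
#' scaling-1 ("distance scaling") scores for triplots.
#'
#' @slot eigConstrained,eigUnconstrained non-increasing eigenvalue vectors.
#' @slot siteScores samples x 2 scaling-1 site scores (inter-sample
#'   Euclidean distances preserved).
#' @slot speciesScores responses x 2 eigenvector loadings.
#' @slot biplotScores predictors x 2 correlations of predictors with the
#'   constrained axes.
#' @slot proportionConstrained fraction of total variance explained by the
#'   constraints, in [0, 1].
#'
#' @seealso [fitRda()], [projectIndex()]
#' @export
setClass("RdaResult",
  representation(eigConstrained = "numeric", eigUnconstrained = "numeric",
                 siteScores = "matrix", speciesScores = "matrix",
                 biplotScores = "matrix", proportionConstrained = "numeric"))

setValidity("RdaResult", function(object) {
  if (is.unsorted(rev(object@eigConstrained), strict = FALSE))
    return("constrained eigenvalues must be non-increasing")
  if (is.unsorted(rev(object@eigUnconstrained), strict = FALSE))
    return("unconstrained eigenvalues must be non-increasing")
  p <- object@proportionConstrained
  if (p < -1e-9 || p > 1 + 1e-9)
    return("proportionConstrained must lie in [0, 1]")
  TRUE
})

#' Synthetic field-study configuration
#'
#' Parameters of the synthetic data generator. Defaults emulate the study
#' design the pipeline targets: 13 fields x 4 plots with one plot lost
#' (51 samples), ~2000 ASVs at a mean sequencing depth of 18000, sand to
#' loam soil textures, and negative texture-balance effects on yield.
#'
#' @seealso [simulationConfig()], [simulateDataset()]
#' @export
setClass("SimulationConfig",
  representation(nFields = "integer", plotsPerField = "integer",
                 dropSamples = "integer", nAsvs = "integer",
                 nPositivePlanted = "integer", nNegativePlanted = "integer",
                 textureEffects = "numeric", microbialEffectSd = "numeric",
                 plantedEffect = "numeric", asvNoiseSd = "numeric",
                 baselineSd = "numeric", yieldNoiseSd = "numeric",
                 yieldIntercept = "numeric", sequencingDepth = "numeric",
                 nDays = "integer", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@nPositivePlanted + object@nNegativePlanted > object@nAsvs)
    return("planted ASVs exceed nAsvs")
  if (object@sequencingDepth <= 0) return("sequencing depth must be > 0")
  if (length(object@seed) != 1 || is.na(object@seed))
    return("an explicit integer seed is mandatory")
  if (object@nFields < 1 || object@plotsPerField < 1)
    return("need at least one field and one plot")
  TRUE
})

#' Synthetic field-study dataset
#'
#' A complete simulated input bundle with known ground truth: ASV counts,
#' per-plot soil/yield metadata, daily weather per field, a taxonomy map,
#' and the planted truth (signed ASV sets, true texture coefficients and
#' the latent per-sample microbial yield component).
#'
#' @seealso [simulateDataset()], [groundTruth()], [runPipeline()]
#' @export
setClass("SyntheticDataset",
  representation(features = "FeatureTable", metadata = "data.frame",
                 weather = "data.frame", taxonomy = "data.frame",
                 truth = "list", config = "SimulationConfig"))

setValidity("SyntheticDataset", function(object) {
  md <- object@metadata
  if (!identical(sort(md$sample_id),
                 sort(colnames(SummarizedExperiment::assay(object@features)))))
    return("metadata and feature table sample ids disagree")
  tr <- object@truth
  if (length(intersect(tr$positive_set, tr$negative_set)) > 0)
    return("planted sets must be disjoint")
  TRUE
})
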