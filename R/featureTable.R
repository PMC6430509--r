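## FeatureTable construction, accessors and prevalence filtering.

#' Construct an ASV feature table
#'
#' @param counts non-negative integer matrix. Orientation is detected from
#'   `samplesAsRows`; internally ASVs are stored as rows and samples as
#'   columns (the Bioconductor convention).
#' @param samplesAsRows logical; set `TRUE` when `counts` has samples as
#'   rows and ASVs as columns (the on-disk layout).
#' @return a validated [FeatureTable-class].
#' @examples
#' m <- matrix(rpois(12, 5), nrow = 3,
#'             dimnames = list(paste0("ASV", 1:3), paste0("S", 1:4)))
#' FeatureTable(m)
#' @export
FeatureTable <- function(counts, samplesAsRows = FALSE) {
  if (samplesAsRows) counts <- t(counts)
  storage.mode(counts) <- "double"
  ft <- new("FeatureTable",
            SummarizedExperiment::SummarizedExperiment(
              assays = list(counts = counts)))
  validObject(ft)
  ft
}

#' @describeIn FeatureTable the counts matrix (ASVs x samples).
#' @param object a `FeatureTable`.
#' @importFrom BiocGenerics counts
#' @export
setMethod("counts", "FeatureTable", function(object)
  SummarizedExperiment::assay(object, "counts"))

#' @describeIn FeatureTable sample identifiers.
#' @export
sampleIds <- function(object) colnames(counts(object))

#' @describeIn FeatureTable ASV identifiers.
#' @export
asvIds <- function(object) rownames(counts(object))

setMethod("show", "FeatureTable", function(object) {
  m <- counts(object)
  cat(sprintf("FeatureTable: %d ASVs x %d samples\n", nrow(m), ncol(m)))
  cat(sprintf("  total counts: %d; zero cells: %.1f%%\n",
              as.integer(sum(m)), 100 * mean(m == 0)))
})

#' Prevalence ("contingency") filter
#'
#' Keeps ASVs observed (non-zero) in at least `minSamples` samples — the
#' contingency-of-2 rule at the default — to reduce the number of zeros
#' before log-ratio transformation. Samples are never dropped.
#'
#' @param x a [FeatureTable-class].
#' @param minSamples minimum number of samples with a non-zero count
#'   (default 2).
#' @return the filtered [FeatureTable-class].
#' @export
filterFeatures <- function(x, minSamples = 2) {
  stopifnot(is(x, "FeatureTable"))
  keep <- rowSums(counts(x) > 0) >= minSamples
  if (!any(keep))
    sbiError("emptyTableError", "no ASV present in >= %d samples", minSamples)
  x[keep, ]
}
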