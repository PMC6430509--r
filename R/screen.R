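## Microbiome screen: correlate clr-ASVs with residual yield, select
## signed significant sets, build the species balance index, tally phyla.

#' Correlate clr-transformed ASVs with residual yield
#'
#' Computes one correlation per ASV between its clr abundance across
#' samples and the residual yield, with a two-sided p-value from the t
#' statistic `r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#' ASVs with zero clr variance get `sign = "neutral"` and `r = NA`; they
#' can never be selected.
#'
#' @param clr matrix of clr values, samples as rows, ASVs as columns.
#' @param residual named residual-yield vector aligned with the rows.
#' @param alpha significance level attached to the sign labels
#'   (default 0.05).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame with columns `asv_id`, `r`, `p`, `sign`.
#' @export
correlateAsvs <- function(clr, residual, alpha = 0.05,
                          method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.matrix(clr), nrow(clr) == length(residual))
  n <- nrow(clr)
  if (n < 4) sbiError("invalidInputError", "need at least 4 samples")
  if (!is.null(names(residual)) && !is.null(rownames(clr)) &&
      !identical(names(residual), rownames(clr)))
    sbiError("invalidInputError",
             "sample ids of clr table and residual yield disagree")
  sds <- apply(clr, 2, sd)
  ok <- sds > 0
  if (any(!ok))
    warning(sum(!ok), " constant-clr ASV(s) excluded from selection")
  r <- rep(NA_real_, ncol(clr))
  if (method == "spearman") {
    residual_r <- rank(residual)
    r[ok] <- suppressWarnings(
      cor(apply(clr[, ok, drop = FALSE], 2, rank), residual_r))
  } else {
    r[ok] <- as.vector(cor(clr[, ok, drop = FALSE], residual))
  }
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  sign <- rep("neutral", ncol(clr))
  sign[!is.na(p) & p < alpha & r > 0] <- "+"
  sign[!is.na(p) & p < alpha & r < 0] <- "-"
  data.frame(asv_id = colnames(clr), r = r, p = p, sign = sign,
             row.names = NULL)
}

#' Split significant correlations by sign
#'
#' Selection at a raw (uncorrected) two-sided level, as a one-pass
#' screen. Optional false-discovery-rate adjustment is available but off
#' by default.
#'
#' @param correlations output of [correlateAsvs()].
#' @param alpha significance level (default 0.05).
#' @param fdr logical; apply Benjamini-Hochberg adjustment before
#'   thresholding (default `FALSE`).
#' @return list with character vectors `positive` and `negative`.
#' @export
selectSignificant <- function(correlations, alpha = 0.05, fdr = FALSE) {
  stopifnot(all(c("asv_id", "r", "p") %in% names(correlations)))
  p <- if (fdr) p.adjust(correlations$p, "BH") else correlations$p
  sel <- !is.na(p) & p < alpha
  list(positive = correlations$asv_id[sel & correlations$r > 0],
       negative = correlations$asv_id[sel & correlations$r < 0])
}

#' Species balance index
#'
#' The per-sample balance between the selected ASV subsets of a
#' zero-imputed composition: positively associated ASVs in the numerator,
#' negatively associated in the denominator,
#' `SBI = sqrt(r s / (r + s)) * ln(gm(positive) / gm(negative))` with
#' `r`, `s` the two set sizes. With `normalized = FALSE` the plain
#' `ln(gm+ / gm-)` log-ratio is returned; the coefficient is a monotone
#' rescaling, so correlations with the index are unaffected.
#'
#' @param imputed strictly positive proportion matrix, samples as rows,
#'   ASVs as columns (see [imputeZeros()]).
#' @param positive,negative disjoint, non-empty ASV id sets.
#' @param correlations optional correlation table to attach to the result.
#' @param normalized apply the orthonormal coefficient (default `TRUE`).
#' @return an [SbiResult-class].
#' @export
computeSBI <- function(imputed, positive, negative, correlations = NULL,
                       normalized = TRUE) {
  stopifnot(is.matrix(imputed))
  if (length(positive) == 0 || length(negative) == 0)
    sbiError("sbiUndefinedError",
             "both the positive and the negative ASV set must be non-empty")
  missing <- setdiff(c(positive, negative), colnames(imputed))
  if (length(missing) > 0)
    sbiError("unknownFeatureError", "ASV id(s) not in table: %s",
             paste(utils::head(missing, 3), collapse = ", "))
  if (length(intersect(positive, negative)) > 0)
    sbiError("invalidPartitionError", "positive and negative sets overlap")
  if (any(imputed <= 0))
    sbiError("zeroOrNegativePartError",
             "imputed proportions must be strictly positive")
  r <- length(positive)
  s <- length(negative)
  coefN <- if (normalized) sqrt(r * s / (r + s)) else 1
  lx <- log(imputed)
  sbi <- coefN * (rowMeans(lx[, positive, drop = FALSE]) -
                  rowMeans(lx[, negative, drop = FALSE]))
  names(sbi) <- rownames(imputed)
  if (is.null(correlations))
    correlations <- data.frame(asv_id = character(), r = numeric(),
                               p = numeric(), sign = character())
  new("SbiResult", positiveSet = as.character(positive),
      negativeSet = as.character(negative), correlations = correlations,
      sbi = sbi, normalized = normalized)
}

#' @describeIn computeSBI the per-sample index values.
#' @param object an `SbiResult`.
#' @export
sbiValues <- function(object) {
  stopifnot(is(object, "SbiResult"))
  object@sbi
}

#' @describeIn computeSBI the signed ASV id sets.
#' @export
selectedSets <- function(object) {
  stopifnot(is(object, "SbiResult"))
  list(positive = object@positiveSet, negative = object@negativeSet)
}

setMethod("show", "SbiResult", function(object) {
  cat(sprintf(
    "SbiResult: %d positive / %d negative ASVs, %d samples (%s)\n",
    length(object@positiveSet), length(object@negativeSet),
    length(object@sbi),
    if (object@normalized) "normalized balance" else "plain log-ratio"))
  cat(sprintf("  SBI range: [%.3f, %.3f]\n",
              min(object@sbi), max(object@sbi)))
})

#' Tally selected ASVs per phylum
#'
#' @param positive,negative selected ASV id sets.
#' @param taxonomy data.frame with columns `asv_id`, `phylum`; selected
#'   ASVs absent from it are counted as "Unassigned".
#' @return data.frame `phylum`, `n_positive`, `n_negative`, one row per
#'   phylum occurring in either set.
#' @export
tallyByPhylum <- function(positive, negative, taxonomy) {
  stopifnot(all(c("asv_id", "phylum") %in% names(taxonomy)))
  lookup <- function(ids) {
    ph <- taxonomy$phylum[match(ids, taxonomy$asv_id)]
    ph[is.na(ph)] <- "Unassigned"
    ph
  }
  phyla <- sort(unique(c(lookup(positive), lookup(negative))))
  if (length(phyla) == 0)
    return(data.frame(phylum = character(), n_positive = integer(),
                      n_negative = integer()))
  data.frame(
    phylum = phyla,
    n_positive = as.integer(table(factor(lookup(positive), phyla))[phyla]),
    n_negative = as.integer(table(factor(lookup(negative), phyla))[phyla]),
    row.names = NULL)
}
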