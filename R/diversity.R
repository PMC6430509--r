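## Alpha diversity: Shannon entropy, Pielou evenness, Chao1 richness, and
## the comparison of these indices (and the SBI) with yield.

#' Shannon diversity of one sample
#'
#' `H = -sum(p_i ln p_i)` over non-zero proportions, in nats by default.
#'
#' @param x non-negative count (or abundance) vector with positive total.
#' @param base logarithm base (default `exp(1)` for nats, matching the
#'   log-ratio machinery).
#' @return Shannon entropy H.
#' @export
shannonIndex <- function(x, base = exp(1)) {
  if (sum(x) <= 0)
    sbiError("emptySampleError", "sample has zero total count")
  as.numeric(vegan::diversity(x, index = "shannon", base = base))
}

#' Pielou evenness of one sample
#'
#' `J = H / log(S)` with S the observed richness; in (0, 1].
#'
#' @inheritParams shannonIndex
#' @return evenness J.
#' @export
pielouEvenness <- function(x, base = exp(1)) {
  s <- sum(x > 0)
  if (s < 2)
    sbiError("undefinedIndexError",
             "Pielou evenness needs at least 2 observed species, got %d", s)
  shannonIndex(x, base) / log(s, base = base)
}

#' Chao1 richness estimate of one sample
#'
#' Classic Chao1 `S + F1^2 / (2 F2)` when doubletons are present, and the
#' bias-corrected `S + F1 (F1 - 1) / (2 (F2 + 1))` when `F2 = 0`, where
#' F1 and F2 are the singleton and doubleton counts. Computed on raw,
#' unrarefied counts; unlike Shannon, it is not invariant to rescaling
#' the counts.
#'
#' @param x non-negative integer count vector with positive total.
#' @return estimated richness (>= observed richness).
#' @export
chao1Richness <- function(x) {
  if (sum(x) <= 0)
    sbiError("emptySampleError", "sample has zero total count")
  if (!is_wholenumber(x))
    sbiError("invalidInputError", "Chao1 needs integer counts")
  s <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f2 > 0) s + f1^2 / (2 * f2) else s + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Alpha-diversity profile of a feature table
#'
#' @param x a [FeatureTable-class] (raw, unfiltered counts are
#'   appropriate).
#' @return data.frame with one row per sample: `sample_id`, `shannon`
#'   (nats), `pielou`, `chao1`.
#' @export
diversityProfile <- function(x) {
  stopifnot(is(x, "FeatureTable"))
  m <- t(counts(x))                     # samples x ASVs
  data.frame(sample_id = rownames(m),
             shannon = apply(m, 1, shannonIndex),
             pielou = apply(m, 1, pielouEvenness),
             chao1 = apply(m, 1, chao1Richness),
             row.names = NULL)
}

#' Correlate diversity indicators with yield
#'
#' Pearson correlations of each alpha-diversity index and the species
#' balance index against raw and residual yield.
#'
#' @param profiles output of [diversityProfile()].
#' @param sbi named per-sample SBI vector (see [sbiValues()]).
#' @param yield named raw yield vector (t/ha).
#' @param residual named residual-yield vector.
#' @return data.frame `index`, `r_yield`, `r_residual`, one row per
#'   indicator (shannon, pielou, chao1, sbi).
#' @export
correlateIndices <- function(profiles, sbi, yield, residual) {
  ids <- profiles$sample_id
  stopifnot(all(ids %in% names(sbi)), all(ids %in% names(yield)),
            all(ids %in% names(residual)))
  idx <- cbind(shannon = profiles$shannon, pielou = profiles$pielou,
               chao1 = profiles$chao1, sbi = sbi[ids])
  data.frame(index = colnames(idx),
             r_yield = as.vector(cor(idx, yield[ids])),
             r_residual = as.vector(cor(idx, residual[ids])),
             row.names = NULL)
}
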