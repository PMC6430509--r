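## Yield detrending: OLS of plot yield on scaled, centred environmental
## predictors; the residuals ("residual yield") feed the microbiome screen.

#' Centre and scale predictor columns
#'
#' @param x numeric matrix or data.frame, samples as rows, predictors as
#'   columns. Columns must be non-constant.
#' @return matrix with each column of mean 0 and sample standard
#'   deviation 1 (n - 1 denominator).
#' @export
standardizePredictors <- function(x) {
  x <- as.matrix(x)
  sds <- apply(x, 2, sd)
  if (any(sds == 0 | !is.finite(sds)))
    sbiError("constantPredictorError", "constant predictor column '%s'",
             colnames(x)[which(sds == 0 | !is.finite(sds))[1]])
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Fit the environmental yield model
#'
#' Ordinary least squares of yield (t/ha) on standardized predictors,
#' with 95% confidence intervals from the t distribution on n - p - 1
#' degrees of freedom. Slopes are in t/ha per predictor standard
#' deviation. The residuals are the residual yield used as the response
#' of the ASV correlation screen.
#'
#' @param x standardized predictor matrix (see [standardizePredictors()]).
#' @param y yield vector in t/ha, one value per row of `x`.
#' @return a [YieldModel-class].
#' @export
fitYieldModel <- function(x, y) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), all(is.finite(y)))
  if (qr(cbind(1, x))$rank < ncol(x) + 1L)
    sbiError("singularDesignError", "predictor matrix is rank deficient")
  df <- data.frame(.yield = y, x, check.names = FALSE)
  fit <- lm(.yield ~ ., data = df)
  est <- coef(fit)
  ci <- confint(fit, level = 0.95)
  pv <- summary(fit)$coefficients[, "Pr(>|t|)"]
  ## lm backtick-quotes non-syntactic names (e.g. balance labels)
  fixNames <- function(v) gsub("^`|`$", "", v)
  names(est) <- fixNames(names(est))
  rownames(ci) <- fixNames(rownames(ci))
  names(pv) <- fixNames(names(pv))
  keep <- setdiff(names(est), "(Intercept)")
  rs <- resid(fit)
  if (!is.null(rownames(x))) names(rs) <- rownames(x)
  new("YieldModel",
      coefficients = est[keep], intercept = unname(est["(Intercept)"]),
      ciLow = setNames(ci[keep, 1], keep),
      ciHigh = setNames(ci[keep, 2], keep),
      pValues = pv[keep],
      residuals = rs, fitted = fitted(fit),
      rSquared = summary(fit)$r.squared, fit = fit)
}

#' Residual yield
#'
#' @param object a [YieldModel-class].
#' @return named numeric vector of residual yields (t/ha), summing to 0.
#' @export
residualYield <- function(object) {
  stopifnot(is(object, "YieldModel"))
  object@residuals
}

#' Predictors significant at a level
#'
#' @param object a [YieldModel-class].
#' @param alpha two-sided significance level (default 0.05).
#' @return data.frame with columns `predictor`, `slope`, `p`, `sign`
#'   ("+" or "-"), one row per predictor with p < alpha.
#' @export
significantPredictors <- function(object, alpha = 0.05) {
  stopifnot(is(object, "YieldModel"), alpha > 0, alpha <= 1)
  sel <- object@pValues < alpha
  data.frame(predictor = names(object@coefficients)[sel],
             slope = unname(object@coefficients[sel]),
             p = unname(object@pValues[sel]),
             sign = ifelse(object@coefficients[sel] > 0, "+", "-"),
             row.names = NULL)
}

setMethod("show", "YieldModel", function(object) {
  cat(sprintf("YieldModel: %d samples, %d predictors, R^2 = %.3f\n",
              length(object@residuals), length(object@coefficients),
              object@rSquared))
  tab <- data.frame(slope = round(object@coefficients, 3),
                    ci_low = round(object@ciLow, 3),
                    ci_high = round(object@ciHigh, 3),
                    p = signif(object@pValues, 3))
  print(tab)
})

#' Assemble the standard predictor set
#'
#' Joins per-sample soil balances and pH with per-field weather indices
#' into the default predictor matrix: the four soil ilr balances, pH,
#' PPT, SDI and GDD.
#'
#' @param metadata data.frame with columns `sample_id`, `field_id`,
#'   `sand_pct`, `silt_pct`, `clay_pct`, `c_pct`, `n_pct`, `ph`.
#' @param weatherIdx per-field index table from [weatherIndices()].
#' @param partition soil balance partition (default
#'   [soilBalancePartition()]).
#' @return numeric matrix, samples as rows (named by `sample_id`),
#'   8 predictor columns, not yet standardized.
#' @export
buildPredictors <- function(metadata, weatherIdx,
                            partition = soilBalancePartition()) {
  need <- c("sample_id", "field_id", "sand_pct", "silt_pct", "clay_pct",
            "c_pct", "n_pct", "ph")
  stopifnot(all(need %in% names(metadata)))
  soil <- closeComposition(as.matrix(
    metadata[, c("sand_pct", "silt_pct", "clay_pct", "c_pct", "n_pct")]))
  colnames(soil) <- c("Sand", "Silt", "Clay", "C", "N")
  rownames(soil) <- metadata$sample_id
  bal <- ilrAll(soil, partition)
  wx <- weatherIdx[match(metadata$field_id, weatherIdx$field_id), ]
  x <- cbind(bal, pH = metadata$ph, PPT = wx$PPT, SDI = wx$SDI,
             GDD = wx$GDD)
  rownames(x) <- metadata$sample_id
  x
}
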