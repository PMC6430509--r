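## Redundancy analysis: PCA of the multivariate-OLS fitted values
## (constrained axes) and of the residuals (unconstrained axes), with
## scaling-1 scores, plus a polynomial trend surface for index contours.

#' Fit a redundancy analysis
#'
#' Regresses every (column-centred) response on the standardized
#' predictors and eigen-decomposes the fitted-value covariance
#' (constrained axes) and the residual covariance (unconstrained axes).
#' Scores are reported for the first two constrained axes in scaling 1:
#' site scores `U D` (inter-sample Euclidean distances in the fitted
#' space are preserved) and species scores as eigenvector loadings `V`.
#' Axis signs are fixed by forcing the largest-magnitude species loading
#' on each axis to be positive, so results are reproducible up to
#' nothing.
#'
#' @param y response matrix (e.g. clr ASV table), samples as rows.
#'   Columns are centred internally.
#' @param x standardized predictor matrix, full column rank.
#' @return an [RdaResult-class].
#' @export
fitRda <- function(y, x) {
  y <- as.matrix(y)
  x <- as.matrix(x)
  stopifnot(nrow(y) == nrow(x))
  n <- nrow(y)
  if (qr(x)$rank < ncol(x))
    sbiError("singularDesignError", "predictor matrix is rank deficient")
  yc <- scale(y, center = TRUE, scale = FALSE)
  xc <- scale(x, center = TRUE, scale = FALSE)
  qx <- qr(xc)
  fitted <- qr.fitted(qx, yc)
  res <- yc - fitted
  tol <- 1e-10
  decomp <- function(m) {
    s <- svd(m)
    lambda <- s$d^2 / (n - 1)
    keep <- lambda > tol * max(lambda, 1e-300)
    list(lambda = lambda[keep],
         u = s$u[, keep, drop = FALSE],
         d = s$d[keep],
         v = s$v[, keep, drop = FALSE])
  }
  con <- decomp(fitted)
  unc <- decomp(res)
  naxes <- min(2L, length(con$lambda))
  site <- con$u[, seq_len(naxes), drop = FALSE] %*%
    diag(con$d[seq_len(naxes)], naxes)
  species <- con$v[, seq_len(naxes), drop = FALSE]
  for (k in seq_len(naxes)) {            # deterministic axis orientation
    if (species[which.max(abs(species[, k])), k] < 0) {
      species[, k] <- -species[, k]
      site[, k] <- -site[, k]
    }
  }
  biplot <- suppressWarnings(cor(xc, site))
  biplot[!is.finite(biplot)] <- 0
  ax <- paste0("RDA", seq_len(naxes))
  dimnames(site) <- list(rownames(y), ax)
  dimnames(species) <- list(colnames(y), ax)
  dimnames(biplot) <- list(colnames(x), ax)
  totvar <- sum(yc^2) / (n - 1)
  new("RdaResult",
      eigConstrained = con$lambda, eigUnconstrained = unc$lambda,
      siteScores = site, speciesScores = species, biplotScores = biplot,
      proportionConstrained = min(1, sum(con$lambda) / totvar))
}

setMethod("show", "RdaResult", function(object) {
  cat(sprintf(
    "RdaResult: %d constrained + %d unconstrained axes, %.1f%% constrained\n",
    length(object@eigConstrained), length(object@eigUnconstrained),
    100 * object@proportionConstrained))
  cat("  first constrained eigenvalues:",
      paste(signif(utils::head(object@eigConstrained, 4), 4),
            collapse = ", "), "\n")
})

#' Trend surface of an index over the ordination plane
#'
#' Fits a second-degree polynomial surface of per-sample index values
#' (e.g. the SBI) on the first two constrained site-score axes and
#' evaluates it on a regular grid, for contour rendering over a triplot.
#'
#' @param result an [RdaResult-class].
#' @param index per-sample values aligned with the site scores.
#' @param gridSize grid points per axis (default 41).
#' @return list with `grid` (data.frame `axis1`, `axis2`, `value`),
#'   `fittedAtSites` (surface evaluated at the samples) and `model`
#'   (the underlying [stats::lm]).
#' @export
projectIndex <- function(result, index, gridSize = 41) {
  stopifnot(is(result, "RdaResult"))
  sc <- result@siteScores
  if (nrow(sc) < 10)
    sbiError("insufficientDataError",
             "need at least 10 samples to fit a trend surface, got %d",
             nrow(sc))
  stopifnot(length(index) == nrow(sc))
  df <- data.frame(v = as.numeric(index), a1 = sc[, 1], a2 = sc[, 2])
  fit <- lm(v ~ a1 + a2 + I(a1^2) + I(a2^2) + a1:a2, data = df)
  g1 <- seq(min(df$a1), max(df$a1), length.out = gridSize)
  g2 <- seq(min(df$a2), max(df$a2), length.out = gridSize)
  grid <- expand.grid(a1 = g1, a2 = g2)
  grid$value <- predict(fit, newdata = grid)
  names(grid)[1:2] <- c("axis1", "axis2")
  list(grid = grid, fittedAtSites = unname(fitted(fit)), model = fit)
}
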