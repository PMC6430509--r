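## Aitchison-geometry primitives: closure, clr, ilr balances over a
## sequential binary partition, and multiplicative zero replacement.

#' Close a positive vector (or matrix rows) to proportions
#'
#' Rescales strictly positive values so each composition sums to 1. Part
#' order and names are preserved.
#'
#' @param x numeric vector with at least two strictly positive parts, or a
#'   matrix with samples as rows and parts as columns.
#' @return an object of the same shape with (row) sums equal to 1.
#' @examples
#' closeComposition(c(Sand = 1, Silt = 1, Clay = 2))
#' @export
closeComposition <- function(x) {
  if (is.matrix(x)) return(t(apply(x, 1, closeComposition)))
  if (length(x) < 2)
    sbiError("degenerateCompositionError",
             "a composition needs at least 2 parts, got %d", length(x))
  if (any(!is.finite(x)) || any(x <= 0))
    sbiError("zeroOrNegativePartError",
             "all parts must be strictly positive (offending index %d)",
             which(!is.finite(x) | x <= 0)[1])
  x / sum(x)
}

## Validate a closed or unclosed strictly-positive composition vector.
checkParts <- function(x) {
  if (length(x) < 2)
    sbiError("degenerateCompositionError",
             "a composition needs at least 2 parts, got %d", length(x))
  if (any(!is.finite(x)) || any(x <= 0))
    sbiError("zeroOrNegativePartError",
             "all parts must be strictly positive (offending index %d)",
             which(!is.finite(x) | x <= 0)[1])
  invisible(x)
}

#' Centred log-ratio transform
#'
#' Maps each composition to log(part / geometric mean of all parts). The
#' result sums to zero; the transform is invariant to the overall scale of
#' the input, so closed and unclosed positive vectors give identical
#' output.
#'
#' @param x strictly positive numeric vector, or matrix with samples as
#'   rows and parts as columns.
#' @return clr values of the same shape; each (row) sums to 0.
#' @examples
#' clrTransform(c(1, 2, 4)) # -log(2), 0, log(2)
#' @export
clrTransform <- function(x) {
  if (is.matrix(x)) {
    apply(x, 1, checkParts)
    lx <- log(x)
    return(lx - rowMeans(lx))
  }
  checkParts(x)
  lx <- log(x)
  lx - mean(lx)
}

#' Construct a balance partition
#'
#' Builds a [BalancePartition-class] from a list of nodes, each a list with
#' character elements `num` (numerator subset) and `den` (denominator
#' subset). Nodes must form a strictly bifurcating tree over `parts`:
#' the first node splits the full part set and every later node splits one
#' side of an earlier split. Labels are generated as
#' `[denominator | numerator]`.
#'
#' @param parts character vector of all part names.
#' @param nodes list of `list(num =, den =)` nodes, root first.
#' @return a validated [BalancePartition-class].
#' @examples
#' balancePartition(c("Silt", "Sand"),
#'                  list(list(num = "Sand", den = "Silt")))
#' @export
balancePartition <- function(parts, nodes) {
  nodes <- lapply(nodes, function(nd) {
    unknown <- setdiff(c(nd$num, nd$den), parts)
    if (length(unknown) > 0)
      sbiError("unknownPartError", "unknown part(s): %s",
               paste(unknown, collapse = ", "))
    if (length(intersect(nd$num, nd$den)) > 0)
      sbiError("invalidPartitionError",
               "numerator and denominator subsets overlap")
    nd$label <- sprintf("[%s | %s]", paste(nd$den, collapse = ","),
                        paste(nd$num, collapse = ","))
    nd
  })
  obj <- tryCatch(new("BalancePartition", parts = parts, nodes = nodes),
                  error = function(e) sbiError("invalidPartitionError",
                                               conditionMessage(e)))
  validObject(obj)
  obj
}

#' The soil balance partition
#'
#' The strictly bifurcating partition of the five-part soil composition
#' \{Sand, Silt, Clay, C, N\} used throughout the pipeline: the organic
#' parts are first split from the mineral ones, the mineral subset is then
#' split by cohesiveness and grain size, and the organic subset into
#' nitrogen versus carbon. Balances (in order):
#' `[Clay,Silt,Sand | N,C]`, `[Clay | Silt,Sand]`, `[Silt | Sand]`,
#' `[N | C]`.
#'
#' @return a [BalancePartition-class] with 4 nodes over 5 parts.
#' @export
soilBalancePartition <- function() {
  balancePartition(
    parts = c("Sand", "Silt", "Clay", "C", "N"),
    nodes = list(
      list(num = c("N", "C"), den = c("Clay", "Silt", "Sand")),
      list(num = c("Silt", "Sand"), den = "Clay"),
      list(num = "Sand", den = "Silt"),
      list(num = "C", den = "N")))
}

#' Evaluate one ilr balance
#'
#' Computes the isometric log-ratio balance
#' `sqrt(r s / (r + s)) * ln(gm(numerator) / gm(denominator))` where `gm`
#' is the geometric mean, `r` the numerator subset size and `s` the
#' denominator subset size. The value is positive when the numerator
#' subset dominates. Geometric means are evaluated in log space.
#'
#' @param x named strictly positive composition vector (closure optional —
#'   the balance is scale invariant).
#' @param node a single node list with `num` and `den` character subsets
#'   (as stored in a [BalancePartition-class]), or a
#'   [BalancePartition-class] together with `label` selecting the node.
#' @param label node label when `node` is a partition.
#' @return the scalar balance value (log-ratio units).
#' @examples
#' ilrBalance(c(Silt = 0.25, Sand = 0.5, Clay = 0.25),
#'            list(num = "Sand", den = "Silt")) # sqrt(1/2) * log(2)
#' @export
ilrBalance <- function(x, node, label = NULL) {
  if (is(node, "BalancePartition")) {
    labs <- vapply(node@nodes, `[[`, character(1), "label")
    if (is.null(label) || !label %in% labs)
      sbiError("invalidPartitionError", "node label '%s' not found", label)
    node <- node@nodes[[match(label, labs)]]
  }
  if (length(intersect(node$num, node$den)) > 0)
    sbiError("invalidPartitionError",
             "numerator and denominator subsets overlap")
  unknown <- setdiff(c(node$num, node$den), names(x))
  if (length(unknown) > 0)
    sbiError("unknownPartError", "unknown part(s): %s",
             paste(unknown, collapse = ", "))
  checkParts(x)
  r <- length(node$num)
  s <- length(node$den)
  sqrt(r * s / (r + s)) *
    (mean(log(x[node$num])) - mean(log(x[node$den])))
}

#' All ilr balances of a composition table
#'
#' Applies every node of a balance partition to each row of a composition
#' table, producing the samples-by-balances coordinate matrix. For a full
#' partition this is an orthonormal ilr basis, so Euclidean distances
#' between rows equal clr-space (Aitchison) distances.
#'
#' @param x matrix of strictly positive compositions, samples as rows,
#'   named parts as columns.
#' @param partition a [BalancePartition-class] covering exactly the
#'   columns of `x`.
#' @return matrix (samples x D-1) with columns named by node labels.
#' @export
ilrAll <- function(x, partition) {
  stopifnot(is.matrix(x), is(partition, "BalancePartition"))
  if (!setequal(colnames(x), partition@parts))
    sbiError("unknownPartError",
             "partition parts and table columns must match exactly")
  out <- vapply(partition@nodes,
                function(nd) apply(x, 1, ilrBalance, node = nd),
                numeric(nrow(x)))
  out <- matrix(out, nrow = nrow(x),
                dimnames = list(rownames(x),
                                vapply(partition@nodes, `[[`,
                                       character(1), "label")))
  out
}

#' Multiplicative replacement of count zeros
#'
#' Replaces zero counts with small positive pseudo-proportions in the
#' count-zero-multiplicative style: within each sample, every zero becomes
#' `deltaFrac` times the smallest observed non-zero proportion of that
#' sample, and the non-zero parts are shrunk by a common multiplicative
#' factor so the row re-closes to 1. Ratios between non-zero parts within
#' a sample are therefore preserved exactly, and every replaced value lies
#' strictly below the sample's minimum observed proportion.
#'
#' @param x a [FeatureTable-class], or a counts matrix with samples as
#'   rows and features as columns.
#' @param deltaFrac fraction of the row-minimum non-zero proportion used
#'   as the replacement value (default 0.65).
#' @return matrix of strictly positive proportions, samples as rows,
#'   rows summing to 1.
#' @export
imputeZeros <- function(x, deltaFrac = 0.65) {
  if (is(x, "FeatureTable")) x <- t(counts(x))
  stopifnot(is.matrix(x), deltaFrac > 0, deltaFrac < 1)
  if (any(x < 0)) sbiError("zeroOrNegativePartError",
                           "counts must be non-negative")
  rs <- rowSums(x)
  if (any(rs == 0))
    sbiError("emptySampleError", "sample '%s' has all-zero counts",
             rownames(x)[which(rs == 0)[1]])
  cs <- colSums(x)
  if (any(cs == 0))
    sbiError("emptyFeatureError", "feature '%s' has all-zero counts",
             colnames(x)[which(cs == 0)[1]])
  p <- x / rs
  t(apply(p, 1, function(row) {
    z <- row == 0
    if (!any(z)) return(row)
    delta <- deltaFrac * min(row[!z])
    row[z] <- delta
    row[!z] <- row[!z] * (1 - sum(z) * delta)
    row
  }))
}
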