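## Shared fixtures, built in code.

## Small deterministic count table: 4 samples x 5 ASVs with presence
## pattern (4, 3, 2, 1, 0) across the columns.
toyCounts <- function() {
  m <- rbind(
    S1 = c(10, 5, 3, 2, 0),
    S2 = c(8, 4, 1, 0, 0),
    S3 = c(6, 2, 0, 0, 0),
    S4 = c(4, 0, 0, 0, 0))
  colnames(m) <- paste0("ASV", 1:5)
  m
}

## Random strictly positive closed compositions, rows = samples.
randomCompositions <- function(n, d, seed) {
  set.seed(seed)
  m <- matrix(exp(rnorm(n * d)), n, d,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("p", seq_len(d))))
  m / rowSums(m)
}

## Full orthonormal partition over 5 generic parts p1..p5 (for isometry
## checks): mirrors the bifurcation pattern of the soil partition.
fullPartition5 <- function() {
  balancePartition(paste0("p", 1:5), list(
    list(num = c("p4", "p5"), den = c("p1", "p2", "p3")),
    list(num = c("p2", "p3"), den = "p1"),
    list(num = "p3", den = "p2"),
    list(num = "p5", den = "p4")))
}

## One small default synthetic dataset reused by several test files.
cachedDataset <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) ds <<- simulateDataset(simulationConfig(seed = 1))
    ds
  }
})

## Plain reader mirroring the pipeline's TSV dialect (comments start '#').
readTsvForTest <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
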