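test_that("prevalence filter applies the contingency-of-2 boundary", {
  ft <- FeatureTable(toyCounts(), samplesAsRows = TRUE)
  ## presence counts per ASV column: 4, 3, 2, 1, 0
  expect_error(FeatureTable(toyCounts()[, 1:4] - 1, samplesAsRows = TRUE))
  kept <- filterFeatures(ft, minSamples = 2)
  expect_setequal(asvIds(kept), c("ASV1", "ASV2", "ASV3"))
  expect_equal(sampleIds(kept), sampleIds(ft))
  all5 <- filterFeatures(ft, minSamples = 1)
  expect_setequal(asvIds(all5), paste0("ASV", 1:4)) # ASV5 all-zero anyway
  expect_error(filterFeatures(ft, minSamples = 10),
               class = "emptyTableError")
})

test_that("per-ASV correlations match cor.test", {
  set.seed(31)
  n <- 20
  res <- rnorm(n)
  clr <- cbind(same = res, anti = -res,
               noise1 = rnorm(n), noise2 = rnorm(n))
  rownames(clr) <- names(res) <- paste0("s", 1:n)
  co <- correlateAsvs(clr, res)
  expect_equal(co$r[co$asv_id == "same"], 1, tolerance = 1e-12)
  expect_lt(co$p[co$asv_id == "same"], 1e-12)
  expect_equal(co$r[co$asv_id == "anti"], -1, tolerance = 1e-12)
  ## p-values agree with the oracle cor.test
  for (k in c("noise1", "noise2")) {
    ct <- cor.test(clr[, k], res)
    expect_equal(co$r[co$asv_id == k], unname(ct$estimate),
                 tolerance = 1e-12)
    expect_equal(co$p[co$asv_id == k], ct$p.value, tolerance = 1e-12)
  }
})

test_that("constant clr columns are flagged neutral, not fatal", {
  set.seed(32)
  clr <- cbind(flat = rep(1, 12), ok = rnorm(12))
  expect_warning(co <- correlateAsvs(clr, rnorm(12)), "constant")
  expect_true(is.na(co$r[co$asv_id == "flat"]))
  expect_equal(co$sign[co$asv_id == "flat"], "neutral")
  sets <- selectSignificant(co)
  expect_false("flat" %in% c(sets$positive, sets$negative))
})

test_that("null clr tables select about 5% of ASVs", {
  set.seed(33)
  n <- 51
  clr <- matrix(rnorm(n * 2000), n, 2000,
                dimnames = list(paste0("s", 1:n), paste0("A", 1:2000)))
  co <- correlateAsvs(clr, rnorm(n))
  frac <- mean(co$p < 0.05)
  expect_gte(frac, 0.035)
  expect_lte(frac, 0.065)
})

test_that("signed selection recovers planted ASVs and ignores order", {
  ds <- cachedDataset()
  tr <- groundTruth(ds)
  imp <- imputeZeros(filterFeatures(ds@features))
  clr <- clrTransform(imp)
  res <- tr$microbial_component + 0 # perfect detrending stand-in
  co <- correlateAsvs(clr, res[rownames(clr)])
  sets <- selectSignificant(co)
  expect_gte(mean(tr$positive_set %in% sets$positive), 0.8)
  expect_gte(mean(tr$negative_set %in% sets$negative), 0.8)
  ## every selected planted ASV carries its planted sign
  expect_length(intersect(sets$positive, tr$negative_set), 0)
  expect_length(intersect(sets$negative, tr$positive_set), 0)
  ## ordering invariance
  perm <- sample(nrow(co))
  setsPerm <- selectSignificant(co[perm, ])
  expect_setequal(setsPerm$positive, sets$positive)
  expect_setequal(setsPerm$negative, sets$negative)
  ## all p >= alpha -> empty sets
  co0 <- co; co0$p <- 0.5
  empty <- selectSignificant(co0)
  expect_length(empty$positive, 0)
})

test_that("SBI matches the hand-evaluated two-set balance", {
  imp <- rbind(s1 = c(a = 0.04, b = 0.01, c = 0.95),
               s2 = c(a = 0.10, b = 0.10, c = 0.80))
  r <- computeSBI(imp, positive = "a", negative = "b")
  expect_equal(unname(sbiValues(r)["s1"]), sqrt(1 / 2) * log(4),
               tolerance = 1e-9)
  expect_equal(unname(sbiValues(r)["s1"]), 0.980258, tolerance = 1e-6)
  expect_equal(unname(sbiValues(r)["s2"]), 0)
  ## unnormalized variant drops the orthonormal coefficient
  r2 <- computeSBI(imp, "a", "b", normalized = FALSE)
  expect_equal(unname(sbiValues(r2)["s1"]), log(4), tolerance = 1e-9)
  ## errors
  expect_error(computeSBI(imp, character(), "b"),
               class = "sbiUndefinedError")
  expect_error(computeSBI(imp, "zz", "b"), class = "unknownFeatureError")
})

test_that("SBI increases with the positive set and is depth invariant", {
  ds <- cachedDataset()
  ft <- filterFeatures(ds@features)
  imp <- imputeZeros(ft)
  tr <- groundTruth(ds)
  pos <- intersect(tr$positive_set, colnames(imp))
  neg <- intersect(tr$negative_set, colnames(imp))
  base <- sbiValues(computeSBI(imp, pos, neg))
  ## doubling positive-set counts in one sample raises its SBI only
  m <- t(counts(ft))
  m2 <- m
  m2[3, pos] <- m2[3, pos] * 2
  bumped <- sbiValues(computeSBI(imputeZeros(m2), pos, neg))
  expect_gt(bumped[3], base[3])
  ## per-sample depth rescaling leaves the SBI unchanged (proportions)
  m3 <- m * 3
  expect_equal(sbiValues(computeSBI(imputeZeros(m3), pos, neg)), base,
               tolerance = 1e-9)
})

test_that("phylum tallies count and conserve selected ASVs", {
  tax <- data.frame(asv_id = c("a1", "a2", "a3", "b1"),
                    phylum = c("P", "P", "P", "Q"))
  t1 <- tallyByPhylum(c("a1", "a2", "a3"), "b1", tax)
  expect_equal(t1$n_positive[t1$phylum == "P"], 3)
  expect_equal(t1$n_negative[t1$phylum == "Q"], 1)
  expect_equal(sum(t1$n_positive), 3)
  expect_equal(sum(t1$n_negative), 1)
  ## unmapped ids fall into Unassigned; empty sets give an empty tally
  t2 <- tallyByPhylum("zz", character(), tax)
  expect_equal(t2$phylum, "Unassigned")
  expect_equal(nrow(tallyByPhylum(character(), character(), tax)), 0)
})
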