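test_that("closure rescales positive parts and rejects bad input", {
  expect_equal(closeComposition(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  expect_equal(closeComposition(c(0.2, 0.3, 0.5)), c(0.2, 0.3, 0.5))
  expect_named(closeComposition(c(a = 1, b = 3)), c("a", "b"))
  expect_error(closeComposition(c(3, 0, 1)),
               class = "zeroOrNegativePartError")
  expect_error(closeComposition(c(1, -2, 1)),
               class = "zeroOrNegativePartError")
  expect_error(closeComposition(5), class = "degenerateCompositionError")
})

test_that("clr matches direct log/geometric-mean evaluation", {
  expect_equal(clrTransform(rep(1 / 3, 3)), rep(0, 3))
  ## independent evaluation: log(x) - mean(log(x)) for closed (1, 2, 4)
  x <- c(1, 2, 4) / 7
  expect_equal(clrTransform(x), log(x) - mean(log(x)))
  expect_equal(clrTransform(x),
               c(-0.6931472, 0, 0.6931472), tolerance = 1e-6)
  expect_error(clrTransform(c(1, 0, 2)), class = "zeroOrNegativePartError")
})

test_that("clr rows sum to zero and are scale invariant", {
  comps <- randomCompositions(50, 8, seed = 11)
  cl <- clrTransform(comps)
  expect_true(all(abs(rowSums(cl)) < 1e-9))
  expect_equal(clrTransform(7.3 * comps), cl, tolerance = 1e-10)
})

test_that("single balances match hand-evaluated values", {
  node <- list(num = "Sand", den = "Silt")
  x <- c(Silt = 0.25, Sand = 0.25, Clay = 0.5)
  expect_equal(ilrBalance(x, node), 0)
  x <- c(Silt = 0.25, Sand = 0.50, Clay = 0.25)
  expect_equal(ilrBalance(x, node), sqrt(1 / 2) * log(2),
               tolerance = 1e-9)
  expect_equal(ilrBalance(x, node), 0.490129, tolerance = 1e-6)
  ## two-part denominator subset, r = 2, s = 1
  y <- c(Clay = 0.2, Silt = 0.3, Sand = 0.5)
  node2 <- list(num = c("Silt", "Sand"), den = "Clay")
  expect_equal(ilrBalance(y, node2),
               sqrt(2 / 3) * log(sqrt(0.3 * 0.5) / 0.2), tolerance = 1e-9)
  expect_equal(ilrBalance(y, node2), 0.539605, tolerance = 1e-6)
  ## balance ignores closure over extra parts
  y2 <- closeComposition(c(y, Other = 3))
  expect_equal(ilrBalance(y2, node2), ilrBalance(y, node2),
               tolerance = 1e-10)
})

test_that("balance errors on unknown or overlapping parts", {
  x <- c(a = 0.5, b = 0.5)
  expect_error(ilrBalance(x, list(num = "zz", den = "a")),
               class = "unknownPartError")
  expect_error(ilrBalance(x, list(num = c("a", "b"), den = "a")),
               class = "invalidPartitionError")
})

test_that("partition construction enforces strict bifurcation", {
  p <- soilBalancePartition()
  expect_s4_class(p, "BalancePartition")
  expect_equal(vapply(p@nodes, `[[`, character(1), "label"),
               c("[Clay,Silt,Sand | N,C]", "[Clay | Silt,Sand]",
                 "[Silt | Sand]", "[N | C]"))
  ## a node that splits nothing available is rejected
  expect_error(
    balancePartition(c("a", "b", "c"),
                     list(list(num = "a", den = "b"),
                          list(num = "b", den = "c"))),
    class = "invalidPartitionError")
  expect_error(
    balancePartition(c("a", "b"), list(list(num = "a", den = "z"))),
    class = "unknownPartError")
})

test_that("ilrAll lays out labelled balance columns", {
  comps <- randomCompositions(6, 5, seed = 3)
  colnames(comps) <- c("Sand", "Silt", "Clay", "C", "N")
  b <- ilrAll(comps, soilBalancePartition())
  expect_equal(dim(b), c(6, 4))
  expect_equal(colnames(b),
               c("[Clay,Silt,Sand | N,C]", "[Clay | Silt,Sand]",
                 "[Silt | Sand]", "[N | C]"))
  uniform <- matrix(0.2, 2, 5,
                    dimnames = list(NULL, colnames(comps)))
  expect_equal(unname(ilrAll(uniform, soilBalancePartition())),
               matrix(0, 2, 4))
})

test_that("full ilr basis is an isometry of clr space", {
  comps <- randomCompositions(100, 5, seed = 21)
  ilr <- ilrAll(comps, fullPartition5())
  clr <- clrTransform(comps)
  expect_equal(as.vector(dist(ilr)), as.vector(dist(clr)),
               tolerance = 1e-8)
})

test_that("increasing a numerator part increases the balance", {
  set.seed(4)
  node <- list(num = c("p4", "p5"), den = c("p1", "p2"))
  for (i in 1:20) {
    x <- setNames(exp(rnorm(5)), paste0("p", 1:5))
    bumped <- x
    bumped["p4"] <- bumped["p4"] * 1.3
    expect_gt(ilrBalance(bumped, node), ilrBalance(x, node))
  }
})

test_that("zero imputation bounds, re-closure and ratio preservation", {
  m <- rbind(s1 = c(10, 5, 0, 5),
             s2 = c(3, 1, 1, 1),
             s3 = c(0, 2, 2, 6))
  colnames(m) <- paste0("a", 1:4)
  imp <- imputeZeros(m)
  expect_true(all(imp > 0))
  expect_equal(rowSums(imp), setNames(rep(1, 3), rownames(m)))
  ## replaced value strictly below the row's smallest non-zero proportion
  expect_lt(imp["s1", "a3"], 5 / 20)
  expect_lt(imp["s3", "a1"], 2 / 10)
  ## non-zero ratios preserved within each row
  expect_equal(imp["s1", "a1"] / imp["s1", "a2"], 2, tolerance = 1e-9)
  expect_equal(imp["s3", "a4"] / imp["s3", "a2"], 3, tolerance = 1e-9)
  ## no zeros -> plain closure
  nozero <- m[2, , drop = FALSE]
  expect_equal(imputeZeros(nozero), nozero / sum(nozero))
  ## common multiplicative row factor on non-zero parts
  delta <- 0.65 * (5 / 20)
  expect_equal(unname(imp["s1", c("a1", "a2", "a4")]),
               c(10, 5, 5) / 20 * (1 - delta), tolerance = 1e-12)
})

test_that("zero imputation rejects empty rows and columns", {
  m <- rbind(c(0, 0), c(1, 2))
  colnames(m) <- c("a", "b"); rownames(m) <- c("s1", "s2")
  expect_error(imputeZeros(m), class = "emptySampleError")
  m2 <- rbind(s1 = c(1, 0), s2 = c(2, 0))
  colnames(m2) <- c("a", "b")
  expect_error(imputeZeros(m2), class = "emptyFeatureError")
})
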