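test_that("constrained axes equal a PCA of the fitted values (oracle)", {
  set.seed(51)
  n <- 51
  x <- standardizePredictors(matrix(rnorm(n * 5), n, 5,
                                    dimnames = list(NULL, paste0("x", 1:5))))
  y <- matrix(rnorm(n * 50), n, 50,
              dimnames = list(paste0("s", 1:n), paste0("a", 1:50)))
  y <- y + x[, 1] %o% rnorm(50) # some structure
  r <- fitRda(y, x)
  ## brute-force oracle: explicit hat-matrix projection + prcomp
  yc <- scale(y, center = TRUE, scale = FALSE)
  xc <- scale(x, center = TRUE, scale = FALSE)
  hat <- xc %*% solve(crossprod(xc)) %*% t(xc)
  pc <- prcomp(hat %*% yc, center = FALSE)
  k <- length(r@eigConstrained)
  expect_equal(r@eigConstrained, (pc$sdev^2)[1:k], tolerance = 1e-8)
  for (ax in 1:2) {
    v <- pc$rotation[, ax]
    if (v[which.max(abs(v))] < 0) v <- -v # same sign convention
    expect_equal(unname(r@speciesScores[, ax]), unname(v),
                 tolerance = 1e-8)
  }
  ## residual axes analogously
  pcr <- prcomp((diag(n) - hat) %*% yc, center = FALSE)
  expect_equal(r@eigUnconstrained,
               (pcr$sdev^2)[seq_along(r@eigUnconstrained)],
               tolerance = 1e-8)
})

test_that("eigenvalues agree with the vegan cross-check", {
  set.seed(52)
  n <- 40
  x <- standardizePredictors(matrix(rnorm(n * 3), n, 3,
                                    dimnames = list(NULL, c("a", "b", "c"))))
  y <- matrix(rnorm(n * 12), n, 12) + x[, 2] %o% rnorm(12, sd = 2)
  r <- fitRda(y, x)
  vg <- vegan::rda(y ~ ., data = as.data.frame(x))
  expect_equal(r@eigConstrained,
               unname(vg$CCA$eig[seq_along(r@eigConstrained)]),
               tolerance = 1e-6)
  expect_equal(r@eigUnconstrained,
               unname(vg$CA$eig[seq_along(r@eigUnconstrained)]),
               tolerance = 1e-6)
  expect_equal(r@proportionConstrained,
               unname(vg$CCA$tot.chi / vg$tot.chi), tolerance = 1e-8)
})

test_that("variance decomposes and degenerate designs error", {
  set.seed(53)
  x <- standardizePredictors(matrix(rnorm(30 * 3), 30, 3,
                                    dimnames = list(NULL, paste0("x", 1:3))))
  y <- matrix(rnorm(30 * 8), 30, 8)
  r <- fitRda(y, x)
  yc <- scale(y, center = TRUE, scale = FALSE)
  expect_equal(sum(r@eigConstrained) + sum(r@eigUnconstrained),
               sum(yc^2) / (nrow(y) - 1), tolerance = 1e-8)
  expect_error(fitRda(y, cbind(x, dup = x[, 1])),
               class = "singularDesignError")
})

test_that("fully explained and null responses bracket the proportion", {
  set.seed(54)
  n <- 51
  x <- standardizePredictors(matrix(rnorm(n * 8), n, 8,
                                    dimnames = list(NULL, paste0("x", 1:8))))
  yLin <- x %*% matrix(rnorm(8 * 20), 8, 20)
  expect_equal(fitRda(yLin, x)@proportionConstrained, 1, tolerance = 1e-8)
  yNull <- matrix(rnorm(n * 200), n, 200)
  expect_lt(fitRda(yNull, x)@proportionConstrained, 0.3)
})

test_that("results are invariant to sample order up to axis sign", {
  set.seed(55)
  n <- 30
  x <- standardizePredictors(matrix(rnorm(n * 3), n, 3,
                                    dimnames = list(NULL, c("a", "b", "c"))))
  y <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(paste0("s", 1:n), paste0("v", 1:10)))
  perm <- sample(n)
  r1 <- fitRda(y, x)
  r2 <- fitRda(y[perm, ], x[perm, ])
  expect_equal(r2@eigConstrained, r1@eigConstrained, tolerance = 1e-8)
  expect_equal(abs(r2@siteScores[rownames(r1@siteScores), ]),
               abs(r1@siteScores), tolerance = 1e-6)
})

test_that("trend surface reproduces constructed index geometry", {
  set.seed(56)
  n <- 51
  x <- standardizePredictors(matrix(rnorm(n * 4), n, 4,
                                    dimnames = list(NULL, paste0("x", 1:4))))
  y <- matrix(rnorm(n * 30), n, 30,
              dimnames = list(paste0("s", 1:n), paste0("a", 1:30)))
  y <- y + x[, 1] %o% rnorm(30, sd = 2)
  r <- fitRda(y, x)
  ## constant index -> flat surface
  flat <- projectIndex(r, rep(2.5, n))
  expect_equal(range(flat$grid$value), c(2.5, 2.5), tolerance = 1e-8)
  ## index equal to axis-1 score -> gradient along axis 1
  s1 <- projectIndex(r, r@siteScores[, 1])
  cf <- coef(s1$model)
  grad <- atan2(abs(cf["a2"]), abs(cf["a1"])) * 180 / pi
  expect_lt(grad, 5)
  expect_gt(cor(s1$fittedAtSites, r@siteScores[, 1]), 0.9)
  ## too few samples
  expect_error(projectIndex(fitRda(y[1:8, ], x[1:8, 1:2]), rep(1, 8)),
               class = "insufficientDataError")
})
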