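test_that("median-of-ratios matches closed forms and the brute-force
           formula, and agrees with the DESeq2 implementation", {
  # two identical columns
  m <- cbind(a = c(10, 50, 100), b = c(10, 50, 100))
  expect_equal(unname(medianOfRatios(m)), c(1, 1))

  # exact doubling: (1/sqrt(2), sqrt(2)) after geometric-mean rescaling
  m <- cbind(a = c(10, 50, 100), b = 2 * c(10, 50, 100))
  expect_equal(unname(medianOfRatios(m)), c(1 / sqrt(2), sqrt(2)))

  # random matrix vs brute-force oracle to 1e-12
  set.seed(51)
  m <- matrix(rnbinom(400, mu = 100, size = 5), ncol = 4)
  expect_equal(medianOfRatios(m), oracle_size_factors(m),
               tolerance = 1e-12)

  # independent cross-check against DESeq2's estimator (which takes the
  # median in log space, so agreement is near- but not bit-exact when the
  # usable feature count is even)
  skip_if_not_installed("DESeq2")
  sf_d <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(medianOfRatios(m)),
               unname(sf_d / exp(mean(log(sf_d)))), tolerance = 1e-3)

  # no all-positive feature: error, unless pseudo-reference requested
  m0 <- cbind(c(0, 5), c(5, 0))
  expect_error(medianOfRatios(m0), "pseudoReference")
  expect_length(medianOfRatios(m0, pseudoReference = TRUE), 2L)
})

test_that("BH adjustment matches the step-up definition, closed forms and
           stats::p.adjust", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(52)
  for (i in 1:20) {
    p <- runif(sample(1:200, 1))
    expect_equal(bhAdjust(p), p.adjust(p, "BH"), tolerance = 1e-14)
  }
  # NA handling: excluded from m, preserved in place
  p <- c(0.01, NA, 0.5)
  expect_equal(bhAdjust(p), c(0.02, NA, 0.5))
  expect_true(all(bhAdjust(p) >= p, na.rm = TRUE))
})

test_that("dispersion estimation recovers known alpha regimes", {
  set.seed(53)
  cells <- factor(rep(1:2, each = 3))

  # Poisson data: median final dispersion ~ 0
  m <- matrix(rpois(2000 * 6, 100), ncol = 6)
  d <- fitDispersions(m, rep(1, 6), cells)
  expect_lte(median(d$dispersion), 0.01)

  # NB alpha = 0.1: median final within [0.05, 0.2]
  m <- matrix(rnbinom(2000 * 6, mu = 100, size = 10), ncol = 6)
  d <- fitDispersions(m, rep(1, 6), cells)
  expect_gte(median(d$dispersion), 0.05)
  expect_lte(median(d$dispersion), 0.2)

  # constant feature: zero method-of-moments estimate
  m <- rbind(matrix(rnbinom(100 * 6, mu = 50, size = 10), ncol = 6),
             matrix(60, 1, 6))
  d <- fitDispersions(m, rep(1, 6), cells)
  expect_equal(d$dispMoM[101], 0)
})

test_that("the NB Wald fit matches reference GLM fits", {
  set.seed(54)
  m <- matrix(rnbinom(50 * 6, mu = 200, size = 10), ncol = 6)
  cd <- data.frame(condition = rep(c("a", "b"), each = 3),
                   replicate = as.character(rep(1:3, 2)))
  sf <- rep(1, 6)

  # fixed-dispersion NB IRLS equals MASS::glm with negative.binomial family
  skip_if_not_installed("MASS")
  r <- nbWaldTest(m, cd, ~ condition, "conditionb", sizeFactors = sf,
                  dispersions = 0.1)
  for (i in sample(50, 8)) {
    g <- suppressWarnings(
      glm(m[i, ] ~ cd$condition, family = MASS::negative.binomial(10)))
    expect_equal(r$log2FC[i], unname(coef(g)[2]) / log(2),
                 tolerance = 1e-6)
    expect_equal(r$lfcSE[i],
                 unname(sqrt(diag(vcov(g)))[2]) / log(2) /
                   sqrt(summary(g)$dispersion),
                 tolerance = 1e-4)
  }

  # alpha -> 0 with large counts converges to the Poisson GLM answer
  r0 <- nbWaldTest(m, cd, ~ condition, "conditionb", sizeFactors = sf,
                   dispersions = 1e-12)
  for (i in sample(50, 8)) {
    g <- glm(m[i, ] ~ cd$condition, family = poisson())
    expect_equal(r0$log2FC[i], unname(coef(g)[2]) / log(2),
                 tolerance = 1e-3)
  }
})

test_that("null and planted two-group cases behave as expected", {
  # identical counts in both groups: exact zero effect, p ~ 1
  m <- matrix(rep(c(100, 120, 90), 2), nrow = 1)
  cd <- data.frame(condition = rep(c("a", "b"), each = 3))
  r <- nbWaldTest(m, cd, ~ condition, "conditionb",
                  sizeFactors = rep(1, 6), dispersions = 0.05)
  expect_lt(abs(r$log2FC[1]), 1e-8)
  expect_gte(r$pvalue[1], 0.99)

  # parameter recovery: true log2FC = 2 at mu 500, alpha 0.05, 3v3
  set.seed(55)
  n <- 200
  m <- cbind(matrix(rnbinom(n * 3, mu = 500, size = 20), ncol = 3),
             matrix(rnbinom(n * 3, mu = 2000, size = 20), ncol = 3))
  r <- nbWaldTest(m, cd, ~ condition, "conditionb",
                  sizeFactors = rep(1, 6), dispersions = 0.05)
  expect_equal(mean(r$log2FC), 2, tolerance = 0.1)

  # all-zero features get NA statistics
  m0 <- rbind(m[1, ], 0)
  r0 <- nbWaldTest(m0, cd, ~ condition, "conditionb",
                   sizeFactors = rep(1, 6), dispersions = 0.05)
  expect_true(is.na(r0$pvalue[2]))
})

test_that("hit calling applies both thresholds with strict inequalities", {
  r <- DataFrame(log2FC = c(-2, 1, 3, 1.5),
                 padj = c(0.009, 0.009, 0.02, 0.009))
  h <- callHits(r, alpha = 0.01, lfcThreshold = 1.5)
  expect_equal(h$significant, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(h$hit, c(TRUE, FALSE, FALSE, FALSE))  # |1.5| is not > 1.5
  expect_equal(h$direction, c("down", NA, NA, NA))
})

test_that("baseline estimation recovers planted channel biases and
           normalization removes them", {
  # symmetric control screen: beta0 centered at zero
  truth <- simulateScreen(simulateLibrary(
    simConfig(n_constructs = 60, n_nontargeting = 5, depth = 3e5,
              baseline_bias_sd = 0.35, seed = 56)),
    conditions = c("pre", "post"), nReplicates = 3)
  tc <- truthCounts(truth)
  res <- runCounts(tc, attr(tc, "manifest"), truthLookup(truth),
                   minMean = 1)
  bp <- barcodePairMatrix(res$bcm)
  bl <- estimateBaseline(bp)
  # estimates track the planted per-pair biases
  common <- intersect(rownames(bl), names(truth@baseline))
  expect_gt(cor(bl[common, "beta0"], truth@baseline[common]), 0.85)
  expect_lte(abs(mean(bl$beta0, na.rm = TRUE)), 0.05)

  # an 8-fold planted pair bias is recovered as beta0 ~ 3
  big <- names(which.max(truth@baseline))
  truth2 <- truth
  truth2@baseline[big] <- 3
  truth2 <- simulateScreen(truth2, conditions = c("pre", "post"),
                           nReplicates = 3)
  tc2 <- truthCounts(truth2)
  res2 <- runCounts(tc2, attr(tc2, "manifest"), truthLookup(truth2),
                    minMean = 1)
  bl2 <- estimateBaseline(barcodePairMatrix(res2$bcm))
  expect_equal(bl2[big, "beta0"], 3, tolerance = 0.5)

  # supplying the baseline as an offset nulls the channel ratio
  r_with <- screenContrast(barcodePairMatrix(res2$bcm), "channel_ratio",
                           baseline = bl2)
  r_without <- screenContrast(barcodePairMatrix(res2$bcm), "channel_ratio")
  expect_lte(mean(abs(r_with$log2FC), na.rm = TRUE), 0.1)
  expect_gt(mean(abs(r_without$log2FC), na.rm = TRUE),
            mean(abs(r_with$log2FC), na.rm = TRUE))

  # empty control screen errors
  empty <- barcodePairMatrix(res$bcm[0, ])
  expect_error(estimateBaseline(empty), "empty")
})
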