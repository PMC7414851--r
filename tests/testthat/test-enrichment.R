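test_that("TPM normalization scales to one million and is equivariant", {
  expect_equal(tpmNormalize(c(1, 1, 2)), c(250000, 250000, 500000))
  set.seed(1)
  x <- rpois(500, 40)
  expect_equal(sum(tpmNormalize(x)), 1e6, tolerance = 1e-6)
  perm <- sample(length(x))
  expect_equal(tpmNormalize(x)[perm], tpmNormalize(x[perm]))
  expect_error(tpmNormalize(rep(0, 5)), "empty")
  expect_error(tpmNormalize(c(1, -1)), "nonnegative")
})

test_that("log2 enrichment follows the pseudocounted ratio", {
  expect_equal(computeEnrichment(c(5, 9), c(5, 9)), c(0, 0))
  expect_equal(computeEnrichment(c(8, 2), c(4, 1), pseudocount = 0), c(1, 1))
  expect_equal(computeEnrichment(100, 0, pseudocount = 1), log2(101),
               tolerance = 1e-12)                      # ~6.658
  expect_error(computeEnrichment(1:3, 1:2), "different grids")
  expect_error(computeEnrichment(c(1, 0), c(1, 1), pseudocount = 0),
               "strictly positive")
})

test_that("enriched-window selection uses a strict positive threshold", {
  expect_equal(selectEnrichedWindows(c(-1, 0, 0.5)), 3L)
  expect_equal(selectEnrichedWindows(c(-2, -0.1)), integer(0))
  expect_equal(selectEnrichedWindows(c(0.2, 0.9)), c(1L, 2L))
})

test_that("matched controls are seeded draws without replacement", {
  all <- sampleMatchedControls(50, 50, seed = 1)
  expect_equal(all, 1:50)
  a <- sampleMatchedControls(500, 10, seed = 9)
  b <- sampleMatchedControls(500, 10, seed = 9)
  expect_equal(a, b)
  expect_length(unique(a), 10)
  expect_error(sampleMatchedControls(5, 6, seed = 1), "exceeds")
})

test_that("quantile labels split windows into near-equal ascending bins", {
  expect_equal(assignQuantiles(1:25, n = 25), 1:25)
  lab <- assignQuantiles(1:100, n = 25)
  expect_equal(as.integer(table(lab)), rep(4L, 25))
  expect_equal(lab[7], 2L)
  # remainder goes to the lowest quantiles
  lab2 <- assignQuantiles(1:27, n = 25)
  expect_equal(as.integer(table(lab2)[1:2]), c(2L, 2L))
  # ties broken by genomic order; sizes still differ by <= 1
  vals <- c(rep(5, 10), sample(1:100, 90))
  lab3 <- assignQuantiles(vals, n = 25)
  expect_lte(diff(range(table(lab3))), 1)
  tied <- which(vals == 5)
  expect_false(is.unsorted(lab3[tied]))   # tie order = genomic order
  # NA values are excluded with an NA label
  lab4 <- assignQuantiles(c(NA, 1:30), n = 5)
  expect_true(is.na(lab4[1]))
  expect_error(assignQuantiles(1:10, n = 25), "fewer")
})

test_that("quantile coverage profiles partition windows and track trends", {
  gen <- defaultGenome()
  rt <- gen$windows$rt
  lab <- assignQuantiles(rt, 25)
  tpm <- tpmNormalize(rep(1, length(rt)))
  prof <- quantileCoverageProfile(tpm, lab)
  expect_equal(sum(lengths(quantileMembers(prof))), sum(!is.na(lab)))
  expect_equal(sort(unlist(quantileMembers(prof))), which(!is.na(lab)))
  expect_equal(var(profileSummary(prof)$mean), 0)       # constant coverage
  expect_equal(as.numeric(trendStatistic(prof)), 0)
  expect_true(attr(trendStatistic(prof), "degenerate"))

  # coverage strictly increasing with RT rank -> strictly increasing means
  inc <- rank(rt)
  prof2 <- quantileCoverageProfile(inc, lab)
  expect_true(all(diff(profileSummary(prof2)$mean) > 0))
  expect_equal(as.numeric(trendStatistic(prof2)), 1)
})

test_that("trend statistic is the Spearman rho of quantile means", {
  mk <- function(means) {
    n <- length(means)
    new("QuantileProfile", scheme = "RT", nQuantiles = as.integer(n),
        summary = data.frame(quantile = seq_len(n), n = 1, mean = means,
                             median = means, q1 = means, q3 = means,
                             whisker_lo = means, whisker_hi = means),
        membership = as.list(seq_len(n)), values = as.list(means))
  }
  expect_equal(as.numeric(trendStatistic(mk(c(1, 2, 5, 9)))), 1)
  expect_equal(as.numeric(trendStatistic(mk(c(9, 5, 2, 1)))), -1)
  expect_equal(as.numeric(trendStatistic(mk(c(1, 3, 2)))), 0.5)
})

test_that("distribution summaries use interpolated quartiles and Tukey whiskers", {
  s <- distributionSummary(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3); expect_equal(s$q1, 2); expect_equal(s$q3, 4)
  expect_equal(s$whisker_lo, 1); expect_equal(s$whisker_hi, 5)
  s2 <- distributionSummary(c(1:10, 100))
  expect_equal(s2$outliers, 100)
  expect_lte(s2$whisker_hi, 10)
  expect_true(s2$q1 <= s2$median && s2$median <= s2$q3)
})

test_that("Mann-Whitney exact branch matches enumeration and wilcox.test", {
  r <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p.value, 0.1)           # 2/20 orderings as extreme
  expect_equal(r$method, "exact")
  set.seed(11)
  for (i in 1:20) {
    n <- sample(2:8, 1); m <- sample(2:8, 1)
    x <- rnorm(n); y <- rnorm(m)
    expect_equal(mannWhitneyU(x, y)$p.value,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney degenerate and tied samples give p = 1 behavior", {
  expect_equal(mannWhitneyU(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  expect_equal(mannWhitneyU(rep(2, 5), rep(2, 7))$p.value, 1)
})

test_that("violin summaries compare selected and control RT distributions", {
  gen <- defaultGenome()
  rt <- gen$windows$rt
  idx <- seq_along(rt)
  same <- violinRtSummary(idx, idx, rt)
  expect_equal(same$selected$median, same$controls$median)
  expect_equal(same$test$p.value, 1)

  early <- which(rt > median(rt)); late <- which(rt <= median(rt))
  v <- violinRtSummary(early, late, rt)
  expect_gt(v$selected$median, v$controls$median)
  expect_lt(v$test$p.value, 1e-3)
})
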