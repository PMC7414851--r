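test_that("KR balancing reaches equal row sums and the closed form", {
  # constant matrix: x_i = 1/2, balanced entries 1/2
  kb <- krBalance(ContactMatrix(matrix(2, 2, 2)))
  expect_equal(kb$x, c(0.5, 0.5))
  expect_equal(kb$balanced, matrix(0.5, 2, 2))

  # already balanced (doubly stochastic-like): x constant
  A <- matrix(c(0.6, 0.4, 0.4, 0.6), 2)
  kb2 <- krBalance(ContactMatrix(A, minNonzeroFrac = 0))
  expect_equal(kb2$x[1], kb2$x[2], tolerance = 1e-10)

  # random symmetric positive 50x50: max relative row-sum deviation < 1e-8
  set.seed(1)
  M <- matrix(runif(2500, 0.05, 1), 50); M <- M + t(M)
  kb3 <- krBalance(ContactMatrix(M, minNonzeroFrac = 0))
  rs <- rowSums(kb3$balanced)
  expect_true(kb3$converged)
  expect_lt(max(abs(rs - mean(rs))) / mean(rs), 1e-8)
})

test_that("sparse bins are masked before balancing", {
  set.seed(2)
  M <- matrix(rpois(400, 20), 20); M <- M + t(M)
  M[5, ] <- 0; M[, 5] <- 0
  cm <- ContactMatrix(M)
  expect_false(binMask(cm)[5])
  kb <- krBalance(cm)
  expect_true(is.na(kb$x[5]))
  expect_true(all(is.na(kb$balanced[5, ])))
  rs <- rowSums(kb$balanced[binMask(cm), binMask(cm)])
  expect_lt(max(abs(rs - mean(rs))) / mean(rs), 1e-8)
})

test_that("observed/expected removes distance decay and matches the oracle", {
  # constant per diagonal -> all ones
  n <- 12
  B <- outer(seq_len(n), seq_len(n), function(i, j) 1 / (abs(i - j) + 1))
  oe <- observedOverExpected(B, mask = rep(TRUE, n))
  expect_equal(oe, matrix(1, n, n))
  # an entry at twice its diagonal mean -> 2.0 (check via direct doubling)
  B2 <- B; B2[1, 4] <- B2[4, 1] <- 2 * B[1, 4]
  oe2 <- observedOverExpected(B2, mask = rep(TRUE, n))
  d3 <- which(abs(row(B2) - col(B2)) == 3)
  expect_equal(oe2[1, 4], B2[1, 4] / mean(B2[d3]))

  set.seed(3)
  C <- matrix(runif(400), 20); C <- (C + t(C)) / 2
  expect_equal(observedOverExpected(C, mask = rep(TRUE, 20)), oeOracle(C),
               tolerance = 1e-12)
})

test_that("Pearson matrix has unit diagonal and block-sign structure", {
  # checkered two-block O/E
  lab <- rep(c(1, -1), each = 10)
  OE <- 1 + 0.5 * outer(lab, lab)
  OE <- OE + diag(1e-9, 20)
  pm <- pearsonMatrix(OE, mask = rep(TRUE, 20))
  P <- pm$P
  expect_equal(diag(P), rep(1, 20))
  expect_equal(P, t(P))
  same <- outer(lab, lab) > 0
  off <- !diag(TRUE, 20)
  expect_true(all(P[same & off] > 0.9))
  expect_true(all(P[!same] < -0.9))
  # identical O/E rows correlate exactly 1
  expect_equal(P[1, 2], 1)
})

test_that("compartment eigenvector recovers simulated A/B labels", {
  gen <- defaultGenome()
  labels <- gen$truth$compartment
  cm <- simulateContactMatrix(labels, sameCompartmentBoost = 1, seed = 1)
  cp <- compartmentPipeline(cm, reference = gen$windows$rt)
  ev <- cp$eigenvector
  ok <- !is.na(ev)
  agreement <- mean((ev[ok] > 0) == (labels[ok] == "A"))
  expect_gte(agreement, 0.95)
  expect_gt(attr(ev, "eigenvalueShare"), 0.5)
  expect_gt(cor(ev[ok], gen$windows$rt[ok]), 0)  # oriented: positive = early
})

test_that("the compartment pipeline is invariant to global scaling", {
  gen <- defaultGenome()
  cm <- simulateContactMatrix(gen$truth$compartment, seed = 1)
  rt <- gen$windows$rt
  ev1 <- compartmentPipeline(cm, reference = rt)$eigenvector
  scaled <- ContactMatrix(contactCounts(cm) * 7.3)
  ev2 <- compartmentPipeline(scaled, reference = rt)$eigenvector
  expect_equal(as.numeric(ev1), as.numeric(ev2), tolerance = 1e-9)
})

test_that("eigenvector orientation follows the RT reference", {
  set.seed(4)
  ref <- rnorm(50)
  ev <- ref + rnorm(50, 0, 0.3)
  expect_equal(as.numeric(orientEigenvector(ev, ref)), ev)      # unchanged
  flipped <- orientEigenvector(-ev, ref)
  expect_equal(as.numeric(flipped), ev)                          # negated back
  orth <- rnorm(50)
  orth <- orth - ref * sum(orth * ref) / sum(ref^2)   # exactly uncorrelated
  orth <- orth - mean(orth) + mean(ref) * 0           # keep centered form
  expect_warning(orientEigenvector(orth - mean(orth), ref - mean(ref)),
                 "ambiguous")
})

test_that("flat correlation structure is flagged as degenerate", {
  P <- diag(20)
  expect_warning(ev <- compartmentEigenvector(P, mask = rep(TRUE, 20)),
                 "degenerate")
  expect_lt(attr(ev, "eigenvalueShare"), 0.5)
  expect_true(attr(ev, "degenerate"))
})

test_that("contact matrices round-trip through dense and sparse text", {
  dir <- withr::local_tempdir()
  set.seed(5)
  M <- matrix(rpois(100, 15), 10); M <- M + t(M)
  cm <- ContactMatrix(M)
  p1 <- writeContactMatrix(cm, file.path(dir, "dense.txt"))
  back <- readContactMatrix(p1, "dense")
  expect_equal(contactCounts(back), contactCounts(cm))

  ij <- which(upper.tri(M, diag = TRUE) & M > 0, arr.ind = TRUE)
  write.table(data.frame(i = ij[, 1] - 1L, j = ij[, 2] - 1L,
                         count = M[ij]),
              file.path(dir, "sparse.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE)
  back2 <- readContactMatrix(file.path(dir, "sparse.tsv"), "sparse",
                             nBins = 10)
  expect_equal(contactCounts(back2), unname(contactCounts(cm)))
})
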