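test_that("generators are pure functions of their config and seed", {
  g1 <- simulateGenome(simGenomeConfig(seed = 5))
  g2 <- simulateGenome(simGenomeConfig(seed = 5))
  expect_identical(g1$windows, g2$windows)
  g3 <- simulateGenome(simGenomeConfig(seed = 6))
  expect_false(identical(g1$windows$rt, g3$windows$rt))

  rt <- g1$windows$rt
  expect_identical(simulateChipCounts(rt, 1e5, 1, seed = 2),
                   simulateChipCounts(rt, 1e5, 1, seed = 2))
  cmA <- simulateContactMatrix(g1$truth$compartment, seed = 3)
  cmB <- simulateContactMatrix(g1$truth$compartment, seed = 3)
  expect_identical(contactCounts(cmA), contactCounts(cmB))
})

test_that("noise-free RT equals the compartment means exactly", {
  cfg <- simGenomeConfig(chromSizes = c(chr1 = 2e6), rtNoiseSd = 0,
                         fracA = 0.5, seed = 2)
  gen <- simulateGenome(cfg)
  a <- gen$windows$compartment == "A"
  expect_true(all(gen$windows$rt[a] == cfg$rtMu))
  expect_true(all(gen$windows$rt[!a] == -cfg$rtMu))
})

test_that("default genome has RT-compartment correlation above 0.8", {
  gen <- defaultGenome()
  ind <- ifelse(gen$windows$compartment == "A", 1, -1)
  expect_gt(cor(gen$windows$rt, ind), 0.8)
  # histone marks favor their compartment
  a <- gen$windows$compartment == "A"
  expect_gt(mean(gen$windows$H3K4me3[a]), mean(gen$windows$H3K4me3[!a]))
  expect_gt(mean(gen$windows$H3K9me3[!a]), mean(gen$windows$H3K9me3[a]))
})

test_that("ChIP counts are multinomial with an RT-loglinear bias", {
  gen <- defaultGenome()
  rt <- gen$windows$rt
  for (s in 1:3)
    expect_equal(sum(simulateChipCounts(rt, 25000, 0.7, seed = s)), 25000)
  pos <- simulateChipCounts(rt, 1e6, +1, seed = 1)
  expect_gt(cor(pos, rt, method = "spearman"), 0)
  neg <- simulateChipCounts(rt, 1e6, -1, seed = 1)
  expect_lt(cor(neg, rt, method = "spearman"), 0)
  expect_error(simulateChipCounts(c(1, NA), 100, 1, 1), "finite")
})

test_that("contact matrices are symmetric with distance decay and boost", {
  labels <- rep(c("A", "B"), each = 100)
  cm <- simulateContactMatrix(labels, sameCompartmentBoost = 1, seed = 1)
  M <- contactCounts(cm)
  expect_identical(M, t(M))
  expect_true(all(M >= 0))

  # boost = 1: same-label mean exceeds cross-label mean at every distance <= 50
  d <- abs(row(M) - col(M))
  same <- outer(labels, labels, "==")
  for (k in 1:50) {
    expect_gt(mean(M[d == k & same]), mean(M[d == k & !same]))
  }
  expect_error(simulateContactMatrix(labels, decayExponent = 0), "> 0")
  expect_error(simulateContactMatrix(c("A", "B")), "4 bins")
})

test_that("without boost, same- and cross-label contacts are equivalent", {
  labels <- rep(c("A", "B"), each = 100)
  cm0 <- simulateContactMatrix(labels, sameCompartmentBoost = 0, seed = 1)
  M <- contactCounts(cm0)
  d <- abs(row(M) - col(M))
  same <- outer(labels, labels, "==")
  # pool distances with both pair types present, compare matched means
  sel <- d > 0 & d <= 99
  ratio <- mean(M[sel & same] / (d[sel & same] + 1)^-1) /
           mean(M[sel & !same] / (d[sel & !same] + 1)^-1)
  expect_gt(ratio, 0.9); expect_lt(ratio, 1.1)
})

test_that("PLA fields carry exact ground truth", {
  f0 <- simulatePlaImages(simPlaConfig(nNuclei = 5, lambda = c(none = 0),
                                       imageShape = c(270, 270), seed = 2))$none
  expect_equal(f0$truth$counts, rep(0L, 5))
  expect_equal(max(f0$pla), max(abs(f0$pla)))     # noise only
  expect_lt(max(f0$pla), 0.5)
  expect_equal(length(unique(f0$truth$labels[f0$truth$labels > 0])), 5)
  # masks disjoint by construction: labeled pixel count equals disk areas
  expect_equal(sum(f0$truth$labels > 0),
               sum(table(f0$truth$labels[f0$truth$labels > 0])))

  big <- simulatePlaImages(simPlaConfig(nNuclei = 200, lambda = c(x = 4),
                                        seed = 1))$x
  m <- mean(big$truth$counts)
  expect_gt(m, 3.6); expect_lt(m, 4.4)            # Poisson standard error
  expect_error(simulatePlaImages(simPlaConfig(nNuclei = 50,
                                              imageShape = c(100, 100))),
               "infeasible")
})

test_that("rigid transforms compose, invert and preserve content", {
  f <- smallPlaField(seed = 4)
  img <- f$dapi
  expect_identical(shiftRotateStack(img, 0, 0, 0), img)
  # integer translation is exact; inverse restores the interior
  fwd <- shiftRotateStack(img, 3, 5, 0)
  back <- shiftRotateStack(fwd, -3, -5, 0)
  inner <- 30:240
  expect_lt(max(abs((back - img)[inner, inner])), 1e-12)
  # two 10-degree rotations agree with one 20-degree rotation
  r2 <- shiftRotateStack(shiftRotateStack(img, 0, 0, 10), 0, 0, 10)
  r1 <- shiftRotateStack(img, 0, 0, 20)
  expect_lt(mean(abs(r2 - r1)), 0.02)             # interpolation tolerance
  expect_error(shiftRotateStack(img, 0, 0, 50), "45")
  expect_warning(shiftRotateStack(img, 200, 0, 0), "out of frame")
  # stacks transform plane-wise
  st <- array(img, c(dim(img), 2))
  ts <- shiftRotateStack(st, 2, 1, 0)
  expect_equal(ts[, , 1], ts[, , 2])
})

test_that("TIFF image stacks round-trip within quantization error", {
  dir <- withr::local_tempdir()
  f <- smallPlaField(seed = 5)
  p <- writeImageStack(list(dapi = f$dapi, pla = f$pla),
                       file.path(dir, "field.tif"))
  back <- readImageStack(p)
  expect_length(back, 2)
  expect_equal(dim(back$ch1), dim(f$dapi))
  expect_lt(max(abs(back$ch1 - pmin(pmax(f$dapi, 0), 1))), 1e-4)  # 16-bit
})
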