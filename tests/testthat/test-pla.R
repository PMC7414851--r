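test_that("nucleus segmentation finds well-separated disks exactly", {
  f <- smallPlaField(seed = 3)
  seg <- segmentNuclei(f$dapi)
  expect_equal(nrow(seg$table), nrow(f$truth$centers))
  ord <- matchNuclei(f$truth, seg$table)
  d <- sqrt((seg$table$y[ord] - f$truth$centers[, 1])^2 +
            (seg$table$x[ord] - f$truth$centers[, 2])^2)
  expect_lt(max(d), 1)                      # centroids within 1 px
  # blank noise-only image yields no nuclei
  set.seed(1)
  blank <- matrix(rnorm(200 * 200, 0, 0.05), 200)
  expect_equal(nrow(segmentNuclei(blank)$table), 0)
  # a disk below the area filter is rejected
  small <- RepliProfiler:::.renderDisks(c(100, 100),
                                        cbind(y = 50, x = 50), r = 4)
  expect_equal(nrow(segmentNuclei(small, minArea = 100)$table), 0)
  expect_equal(nrow(segmentNuclei(small, minArea = 10)$table), 1)
})

test_that("focus detection counts separated spots and size-filters blobs", {
  spots <- data.frame(y = c(30, 30, 80, 120, 160),
                      x = c(40, 150, 90, 30, 170))
  img <- RepliProfiler:::.renderSpots(c(200, 200),
                                      cbind(spots, nucleus = 1), sigma = 1.5)
  set.seed(2)
  img <- img + matrix(rnorm(4e4, 0, 0.05), 200)
  det <- detectFoci(img)
  expect_equal(nrow(det$table), 5)
  ord <- apply(outer(det$table$y, spots$y, "-")^2 +
               outer(det$table$x, spots$x, "-")^2, 2, which.min)
  expect_lt(max(abs(det$table$y[ord] - spots$y)), 1)

  # a bright blob larger than maxArea is not a focus
  blob <- RepliProfiler:::.renderDisks(c(200, 200),
                                       cbind(y = 100, x = 100), r = 8)
  expect_equal(nrow(detectFoci(blob, maxArea = 50)$table), 0)
  # blank image: nothing detected
  set.seed(3)
  blank <- matrix(rnorm(4e4, 0, 0.05), 200)
  expect_equal(nrow(detectFoci(blank)$table), 0)
})

test_that("foci are assigned to the nucleus containing their centroid", {
  lab <- matrix(0L, 50, 50)
  lab[5:15, 5:15] <- 1L
  lab[30:45, 30:45] <- 2L
  foci <- data.frame(focus_id = 1:3, y = c(10, 40, 25), x = c(10, 35, 25),
                     area = 10)
  asg <- assignFoci(foci, lab, 2)
  expect_equal(asg$foci$parent, c(1L, 2L, NA))   # outside-all excluded
  expect_equal(asg$counts, c(1L, 1L))
  expect_equal(sum(asg$counts), sum(!is.na(asg$foci$parent)))
})

test_that("per-nucleus counts equal ground truth on the default fixture", {
  f <- smallPlaField(seed = 6, nNuclei = 12, shape = c(290, 290))
  res <- countFociPerNucleus(f$dapi, f$pla, "fixture")
  expect_equal(length(fociCounts(res)), 12)
  ord <- matchNuclei(f$truth, res@nuclei)
  expect_equal(as.integer(fociCounts(res)[ord]), f$truth$counts)
})

test_that("condition comparison reports fold ratio and significance labels", {
  cp <- compareConditions(rep(5, 30), rep(1, 30))
  expect_equal(cp$ratio, 5)
  expect_lt(cp$p.value, 1e-3)
  expect_equal(cp$label, "significant")
  same <- compareConditions(rep(3, 20), rep(3, 20))
  expect_equal(same$ratio, 1)
  expect_equal(same$p.value, 1)
  expect_equal(same$label, "NS")
  expect_error(compareConditions(1, 1:5), "at least 2")
})

test_that("registration recovers the inverse of known rigid drifts", {
  f <- smallPlaField(seed = 4)
  img <- f$dapi
  idt <- registerRounds(img, img)
  expect_lt(abs(idt$dy), 0.1); expect_lt(abs(idt$dx), 0.1)
  expect_lt(abs(idt$angle), 0.1)
  expect_true(idt$reliable)

  grid <- list(c(3, 5, 0), c(0, 0, 10), c(-4, 2, 0), c(2, -3, 6))
  for (tr in grid) {
    mov <- shiftRotateStack(img, tr[1], tr[2], tr[3])
    est <- registerRounds(img, mov)
    # expected inverse: angle -theta, translation -R(-theta) %*% t
    th <- -tr[3] * pi / 180
    expT <- -c(cos(th) * tr[1] - sin(th) * tr[2],
               sin(th) * tr[1] + cos(th) * tr[2])
    expect_lt(abs(est$angle - (-tr[3])), 0.5)
    expect_lt(abs(est$dy - expT[1]), 0.5)
    expect_lt(abs(est$dx - expT[2]), 0.5)
  }
})

test_that("unrelated fields are flagged unreliable", {
  a <- smallPlaField(seed = 7)$dapi
  set.seed(8)
  noise <- matrix(rnorm(length(a), 0, 0.05), nrow(a))
  expect_warning(est <- registerRounds(a, noise), "unreliable")
  expect_false(est$reliable)
})

test_that("overlap fraction is 1 for identical foci and 0 when far apart", {
  f <- smallPlaField(seed = 3)
  seg <- segmentNuclei(f$dapi)
  det <- detectFoci(f$pla)
  asg <- assignFoci(det$table, seg$labels, nrow(seg$table))
  foci <- asg$foci[!is.na(asg$foci$parent), ]
  ov <- overlapFraction(foci, foci, radius = 2, nucleusLabels = seg$labels,
                        nPermutations = 50, seed = 1)
  expect_equal(ov$fraction, 1)
  far <- foci; far$y <- far$y + 1000
  ov2 <- overlapFraction(foci, far, radius = 2, nPermutations = 0)
  expect_equal(ov2$fraction, 0)
  empty <- foci[0, ]
  ov3 <- overlapFraction(empty, foci, radius = 2, nPermutations = 0)
  expect_equal(ov3$fraction, 0); expect_equal(ov3$p.value, 1)
})

test_that("independent placements sit inside their own permutation null", {
  f1 <- smallPlaField(seed = 9, nNuclei = 9, lambda = c(a = 5))
  seg <- segmentNuclei(f1$dapi)
  det1 <- assignFoci(detectFoci(f1$pla)$table, seg$labels, nrow(seg$table))
  a <- det1$foci[!is.na(det1$foci$parent), ]
  # round 2: same nuclei, independent uniform positions inside each parent
  pixByNucleus <- split(which(seg$labels > 0), seg$labels[seg$labels > 0])
  b <- a
  set.seed(21)
  for (j in seq_len(nrow(b))) {
    px <- sample(pixByNucleus[[as.character(b$parent[j])]], 1)
    b$y[j] <- (px - 1) %% nrow(seg$labels) + 1
    b$x[j] <- (px - 1) %/% nrow(seg$labels) + 1
  }
  ov <- overlapFraction(a, b, radius = 2, nucleusLabels = seg$labels,
                        nPermutations = 200, seed = 2)
  expect_gte(ov$p.value, 0.025)   # not spuriously colocalized
})
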