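#' Configuration for the synthetic genome generator
#'
#' Defaults describe the study conditions the analyses assume: a 10-Mb
#' chromosome tiled into 50-kb windows; A/B compartments in alternating
#' blocks with a 500-kb mean run length and half the genome in A; RT =
#' log2(Early/Late) centered at +1.5 in A and -1.5 in B with 0.5 units of
#' Gaussian noise (a typical dynamic range for mammalian RT tracks);
#' histone marks with a 4-fold contrast between favored and disfavored
#' compartments (H3K4me3 up in A/early, H3K9me3 up in B/late).
#'
#' @param chromSizes Named numeric vector of chromosome lengths (bp).
#' @param windowWidth Window width in bp.
#' @param compartmentMeanBlock Expected A/B run length in bp.
#' @param fracA Expected fraction of the genome in the A compartment.
#' @param rtMu RT magnitude: A windows center at `+rtMu`, B at `-rtMu`.
#' @param rtNoiseSd Gaussian noise SD on RT, in RT units.
#' @param markContrast Fold weight of a histone mark in its favored
#'   compartment.
#' @param markTotalTags Tags per simulated histone-mark library.
#' @param seed Global seed; all sub-generators derive child seeds from it.
#' @return A config list of class `simGenomeConfig`.
#' @export
simGenomeConfig <- function(chromSizes = c(chr1 = 1e7), windowWidth = 50000,
                            compartmentMeanBlock = 5e5, fracA = 0.5,
                            rtMu = 1.5, rtNoiseSd = 0.5, markContrast = 4,
                            markTotalTags = 2e5, seed = 1) {
  stopifnot(windowWidth > 0, fracA > 0, fracA < 1, rtNoiseSd >= 0,
            markContrast > 0, compartmentMeanBlock >= windowWidth)
  if (any(chromSizes <= windowWidth))
    stop("every chromosome must be longer than one window")
  structure(as.list(environment()), class = "simGenomeConfig")
}

#' Simulate a genome with compartments, RT and histone-mark tracks
#'
#' Draws alternating A/B compartment blocks with geometric run lengths (in
#' window units; memoryless, giving the blocky profile compartment
#' eigenvectors show), mean `2 * fracA * meanBlock` windows for A runs and
#' `2 * (1 - fracA) * meanBlock` for B so the A fraction hits `fracA` in
#' expectation. RT is `+rtMu` (A) or `-rtMu` (B) plus Gaussian noise —
#' positive = early, negative = late. Histone-mark tags are drawn
#' multinomially with weight `markContrast` in the favored compartment
#' (H3K4me3: A; H3K9me3: B) and reported as TPM.
#'
#' @param cfg A [simGenomeConfig()].
#' @return A list: `grid` (the window [GenomicRanges::GRanges]), `windows`
#'   (data frame with `window_id`, `chrom`, `start`, `end`, `compartment`,
#'   `rt`, `H3K4me3`, `H3K9me3`), `truth` (list with the compartment
#'   labels and noise-free RT), `cfg`.
#' @export
simulateGenome <- function(cfg = simGenomeConfig()) {
  stopifnot(inherits(cfg, "simGenomeConfig"))
  grid <- suppressMessages(makeWindows(cfg$chromSizes, cfg$windowWidth))
  chrom <- as.character(GenomicRanges::seqnames(grid))
  nWin <- length(grid)
  meanBlockWin <- cfg$compartmentMeanBlock / cfg$windowWidth
  meanA <- max(1, 2 * cfg$fracA * meanBlockWin)
  meanB <- max(1, 2 * (1 - cfg$fracA) * meanBlockWin)

  comp <- withSeed(childSeed(cfg$seed, "compartments"), {
    out <- character(nWin)
    for (chr in unique(chrom)) {
      idx <- which(chrom == chr)
      lab <- character(0)
      cur <- if (stats::runif(1) < cfg$fracA) "A" else "B"
      while (length(lab) < length(idx)) {
        mean <- if (cur == "A") meanA else meanB
        len <- stats::rgeom(1, prob = 1 / mean) + 1L
        lab <- c(lab, rep(cur, len))
        cur <- if (cur == "A") "B" else "A"
      }
      out[idx] <- lab[seq_along(idx)]
    }
    out
  })

  rtTrue <- ifelse(comp == "A", cfg$rtMu, -cfg$rtMu)
  rt <- withSeed(childSeed(cfg$seed, "rt"),
                 rtTrue + stats::rnorm(nWin, 0, cfg$rtNoiseSd))

  markTpm <- function(favored, tag) {
    w <- ifelse(comp == favored, cfg$markContrast, 1)
    counts <- withSeed(childSeed(cfg$seed, tag),
                       stats::rmultinom(1, cfg$markTotalTags, w / sum(w))[, 1])
    tpmNormalize(counts)
  }

  windows <- data.frame(
    window_id = S4Vectors::mcols(grid)$window_id,
    chrom = chrom,
    start = GenomicRanges::start(grid) - 1L,
    end = GenomicRanges::end(grid),
    compartment = comp,
    rt = rt,
    H3K4me3 = markTpm("A", "H3K4me3"),
    H3K9me3 = markTpm("B", "H3K9me3"))

  list(grid = grid, windows = windows,
       truth = list(compartment = comp, rt_true = rtTrue), cfg = cfg)
}

#' Simulate ChIP tag counts biased by replication timing
#'
#' Tags are distributed over windows as
#' `Multinomial(totalTags, p_i %prop% exp(biasBeta * rt_i))`: a positive
#' coefficient skews tags toward early-replicating windows (DONSON-like),
#' a negative one toward late (FANCM-like), zero gives an unbiased Input.
#'
#' @param rt Per-window RT values (finite).
#' @param totalTags Library size.
#' @param biasBeta Log-linear coefficient of tag weight on RT.
#' @param seed Integer seed.
#' @return Integer per-window counts summing to `totalTags`.
#' @export
simulateChipCounts <- function(rt, totalTags = 1e6, biasBeta = 0, seed = 1) {
  if (any(!is.finite(rt))) stop("rt must be finite for all windows")
  stopifnot(totalTags > 0)
  w <- exp(biasBeta * rt)
  withSeed(seed, stats::rmultinom(1, totalTags, w / sum(w))[, 1])
}

#' Simulate a compartment-checkered Hi-C contact matrix
#'
#' Expected intensity decays with genomic distance as
#' `(|i - j| + 1)^(-decayExponent)` and is multiplied by
#' `1 + sameCompartmentBoost` when bins i and j share a compartment label,
#' giving the plaid pattern compartment analysis detects. Counts are
#' Poisson-sampled on the upper triangle and mirrored, so the matrix is
#' exactly symmetric.
#'
#' @param labels Per-bin compartment labels ("A"/"B").
#' @param decayExponent Power-law distance-decay exponent (> 0).
#' @param sameCompartmentBoost Relative intensity boost for same-label
#'   pairs (0 = no compartment signal).
#' @param totalContacts Expected total count over the full matrix.
#' @param seed Integer seed.
#' @param chrom,binWidth Passed to [ContactMatrix()].
#' @return A [ContactMatrix]; the generating compartment labels travel
#'   with it as `attr(contactCounts(x), "truth")`.
#' @export
simulateContactMatrix <- function(labels, decayExponent = 1,
                                  sameCompartmentBoost = 1,
                                  totalContacts = 2e6, seed = 1,
                                  chrom = "chr1", binWidth = 50000) {
  n <- length(labels)
  if (n < 4L) stop("need at least 4 bins")
  if (decayExponent <= 0) stop("decayExponent must be > 0")
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  same <- outer(labels, labels, "==")
  E <- (d + 1)^(-decayExponent) * (1 + sameCompartmentBoost * same)
  E <- E / sum(E) * totalContacts
  up <- upper.tri(E, diag = TRUE)
  M <- matrix(0, n, n)
  M[up] <- withSeed(seed, stats::rpois(sum(up), E[up]))
  M <- M + t(M) - diag(diag(M))
  cm <- ContactMatrix(M, chrom = chrom, binWidth = binWidth)
  attr(cm@counts, "truth") <- labels
  cm
}

#' Configuration for the synthetic PLA image generator
#'
#' Defaults emulate a PLA experiment at the scale scored per condition:
#' 60 nuclei per condition, mean 4 foci per nucleus in the favored
#' condition versus 1 in the other (the fold difference the assay is
#' designed to resolve), 20-px nucleus radius, diffraction-limited foci
#' rendered as isotropic Gaussians of 1.5 px SD, and 5% Gaussian read
#' noise (peak SNR 20).
#'
#' @param nNuclei Nuclei per condition.
#' @param lambda Named vector: mean foci per nucleus per condition.
#' @param nucleusRadiusPx Nucleus radius in pixels.
#' @param focusSigmaPx Focus Gaussian SD in pixels.
#' @param imageShape `c(ny, nx)`; `NULL` = smallest square grid that fits
#'   the nuclei without overlap.
#' @param noiseSd Gaussian read-noise SD (intensity units; foci peak at 1).
#' @param minFocusSepPx Minimum separation enforced between foci within a
#'   nucleus, so that ground-truth counts are recoverable exactly.
#' @param seed Global seed.
#' @return A config list of class `simPlaConfig`.
#' @export
simPlaConfig <- function(nNuclei = 60, lambda = c(early = 4, late = 1),
                         nucleusRadiusPx = 20, focusSigmaPx = 1.5,
                         imageShape = NULL, noiseSd = 0.05,
                         minFocusSepPx = 8, seed = 1) {
  stopifnot(nNuclei > 0, all(lambda >= 0), nucleusRadiusPx > 2,
            focusSigmaPx > 0, noiseSd >= 0)
  if (is.null(names(lambda)) || any(!nzchar(names(lambda))))
    stop("lambda must be named by condition")
  structure(as.list(environment()), class = "simPlaConfig")
}

#' Simulate PLA image fields with known ground truth
#'
#' Per condition, renders one field: nuclei as filled bright disks on the
#' DAPI channel (placed on a jittered grid, so masks never overlap), and
#' per-nucleus Poisson(`lambda`) foci as Gaussian spots at uniform
#' positions inside the nucleus (kept `3 * focusSigmaPx + 1` px from the
#' rim and at least `minFocusSepPx` apart) on the PLA channel. Gaussian
#' read noise is added to both channels.
#'
#' @param cfg A [simPlaConfig()].
#' @return A named list (one element per condition), each a list with
#'   `dapi` and `pla` image matrices and `truth`: nucleus `centers`,
#'   `radius`, integer `counts`, `foci` (data frame `y`, `x`, `nucleus`),
#'   and `labels` (the ground-truth nucleus label matrix).
#' @export
simulatePlaImages <- function(cfg = simPlaConfig()) {
  stopifnot(inherits(cfg, "simPlaConfig"))
  r <- cfg$nucleusRadiusPx
  cell <- ceiling(2 * r + 12)            # grid pitch guaranteeing disjoint disks
  perRow <- ceiling(sqrt(cfg$nNuclei))
  shape <- cfg$imageShape
  if (is.null(shape)) shape <- rep(perRow * cell + cell, 2L)
  nRows <- floor((shape[1] - cell) / cell)
  nCols <- floor((shape[2] - cell) / cell)
  if (nRows * nCols < cfg$nNuclei)
    stop("infeasible packing: ", cfg$nNuclei, " nuclei of radius ", r,
         " do not fit in a ", shape[1], "x", shape[2], " image")

  out <- list()
  for (cond in names(cfg$lambda)) {
    sd0 <- childSeed(cfg$seed, paste0("pla_", cond))
    field <- withSeed(sd0, {
      cells <- sample(nRows * nCols, cfg$nNuclei)
      jit <- (cell - 2 * r - 2) / 2
      centers <- cbind(
        y = ((cells - 1) %/% nCols) * cell + cell / 2 + cell / 2 +
          stats::runif(cfg$nNuclei, -jit, jit),
        x = ((cells - 1) %% nCols) * cell + cell / 2 + cell / 2 +
          stats::runif(cfg$nNuclei, -jit, jit))
      counts <- stats::rpois(cfg$nNuclei, cfg$lambda[[cond]])
      margin <- 3 * cfg$focusSigmaPx + 1
      foci <- list()
      for (i in seq_len(cfg$nNuclei)) {
        pts <- matrix(numeric(0), 0, 2)
        tries <- 0
        while (nrow(pts) < counts[i] && tries < 2000) {
          tries <- tries + 1
          a <- stats::runif(1, 0, 2 * pi)
          rad <- (r - margin) * sqrt(stats::runif(1))
          p <- centers[i, ] + rad * c(sin(a), cos(a))
          if (nrow(pts) == 0 ||
              min(sqrt(rowSums((pts - matrix(p, nrow(pts), 2,
                                             byrow = TRUE))^2))) >=
                cfg$minFocusSepPx)
            pts <- rbind(pts, p)
        }
        counts[i] <- nrow(pts)             # honest bookkeeping if capped
        if (counts[i] > 0)
          foci[[length(foci) + 1]] <-
            data.frame(y = pts[, 1], x = pts[, 2], nucleus = i)
      }
      fociDf <- if (length(foci)) do.call(rbind, foci) else
        data.frame(y = numeric(0), x = numeric(0), nucleus = integer(0))
      dapi <- .renderDisks(shape, centers, r, intensity = 0.9)
      labels <- .diskLabels(shape, centers, r)
      pla <- .renderSpots(shape, fociDf, cfg$focusSigmaPx, amplitude = 1)
      if (cfg$noiseSd > 0) {
        dapi <- dapi + matrix(stats::rnorm(prod(shape), 0, cfg$noiseSd),
                              shape[1], shape[2])
        pla <- pla + matrix(stats::rnorm(prod(shape), 0, cfg$noiseSd),
                            shape[1], shape[2])
      }
      list(dapi = dapi, pla = pla,
           truth = list(centers = centers, radius = r,
                        counts = as.integer(counts), foci = fociDf,
                        labels = labels))
    })
    out[[cond]] <- field
  }
  out
}

.renderDisks <- function(shape, centers, r, intensity = 0.9) {
  img <- matrix(0, shape[1], shape[2])
  for (i in seq_len(nrow(centers))) {
    ys <- max(1, floor(centers[i, 1] - r)):min(shape[1], ceiling(centers[i, 1] + r))
    xs <- max(1, floor(centers[i, 2] - r)):min(shape[2], ceiling(centers[i, 2] + r))
    dy <- ys - centers[i, 1]; dx <- xs - centers[i, 2]
    inside <- outer(dy^2, dx^2, "+") <= r^2
    img[ys, xs][inside] <- intensity
  }
  img
}

.diskLabels <- function(shape, centers, r) {
  lab <- matrix(0L, shape[1], shape[2])
  for (i in seq_len(nrow(centers))) {
    ys <- max(1, floor(centers[i, 1] - r)):min(shape[1], ceiling(centers[i, 1] + r))
    xs <- max(1, floor(centers[i, 2] - r)):min(shape[2], ceiling(centers[i, 2] + r))
    dy <- ys - centers[i, 1]; dx <- xs - centers[i, 2]
    inside <- outer(dy^2, dx^2, "+") <= r^2
    block <- lab[ys, xs]
    block[inside] <- i
    lab[ys, xs] <- block
  }
  lab
}

.renderSpots <- function(shape, foci, sigma, amplitude = 1) {
  img <- matrix(0, shape[1], shape[2])
  if (nrow(foci) == 0) return(img)
  half <- ceiling(4 * sigma)
  for (i in seq_len(nrow(foci))) {
    cy <- foci$y[i]; cx <- foci$x[i]
    ys <- max(1, floor(cy - half)):min(shape[1], ceiling(cy + half))
    xs <- max(1, floor(cx - half)):min(shape[2], ceiling(cx + half))
    g <- amplitude * outer(exp(-(ys - cy)^2 / (2 * sigma^2)),
                           exp(-(xs - cx)^2 / (2 * sigma^2)))
    img[ys, xs] <- img[ys, xs] + g
  }
  img
}

#' Apply a rigid transform (rotation about center, then translation)
#'
#' Rotates the image by `angleDeg` about its center, then shifts it by
#' (`dy`, `dx`) pixels, resampling with bilinear interpolation. For a 3-D
#' stack the same transform is applied to every plane. If bright content
#' would leave the frame a warning is issued.
#'
#' @param img Matrix or 3-D array (y, x, plane).
#' @param dy,dx Translation in pixels (rows, columns).
#' @param angleDeg Rotation in degrees, counter-clockwise; `|angle| < 45`.
#' @return Transformed image of the same shape.
#' @export
shiftRotateStack <- function(img, dy = 0, dx = 0, angleDeg = 0) {
  if (abs(angleDeg) >= 45) stop("|angle| must be < 45 degrees (drift bound)")
  if (length(dim(img)) == 3L) {
    out <- img
    for (k in seq_len(dim(img)[3]))
      out[, , k] <- shiftRotateStack(img[, , k], dy, dx, angleDeg)
    return(out)
  }
  if (dy == 0 && dx == 0 && angleDeg == 0) return(img)
  ny <- nrow(img); nx <- ncol(img)
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  th <- angleDeg * pi / 180
  # inverse map: source = R(-theta) %*% (dest - center - t) + center
  destY <- matrix(seq_len(ny), ny, nx) - cy - dy
  destX <- matrix(seq_len(nx), ny, nx, byrow = TRUE) - cx - dx
  srcY <- cos(th) * destY + sin(th) * destX + cy
  srcX <- -sin(th) * destY + cos(th) * destX + cx
  out <- .bilinear(img, srcY, srcX)
  # content check: a rigid transform conserves bright mass unless pixels
  # leave the frame (interpolation losses are a few percent at most)
  lim <- 0.25 * max(img)
  if (lim > 0 && sum(img[img > lim]) > 1.1 * sum(out[out > lim]) + 1e-9)
    warning("shiftRotateStack: bright content moved out of frame")
  out
}

# bilinear sampling; coordinates outside the frame return 0
.bilinear <- function(img, Y, X) {
  ny <- nrow(img); nx <- ncol(img)
  y0 <- floor(Y); x0 <- floor(X)
  fy <- Y - y0; fx <- X - x0
  pad <- matrix(0, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- img
  gv <- function(yy, xx) {
    yy <- pmin(pmax(yy, 0), ny + 1) + 1
    xx <- pmin(pmax(xx, 0), nx + 1) + 1
    matrix(pad[cbind(as.vector(yy), as.vector(xx))], nrow(Y), ncol(Y))
  }
  inb <- (Y >= 1) & (Y <= ny) & (X >= 1) & (X <= nx)
  v <- (1 - fy) * (1 - fx) * gv(y0, x0) + (1 - fy) * fx * gv(y0, x0 + 1L) +
    fy * (1 - fx) * gv(y0 + 1L, x0) + fy * fx * gv(y0 + 1L, x0 + 1L)
  v[!inb] <- 0
  v
}

#' Write / read a multi-channel image as TIFF
#'
#' Channels are stored as frames of a single multi-frame TIFF via
#' [EBImage::writeImage()]. Intensities are clipped to `[0, 1]` on write
#' (the TIFF range); negative noise excursions are lost, which does not
#' affect thresholded quantification.
#'
#' @param channels Named list of image matrices (same shape).
#' @param path Output `.tif` path.
#' @return `writeImageStack()`: `path` invisibly; `readImageStack()`: a
#'   list of matrices named `ch1..chK` (names are not stored in TIFF).
#' @export
writeImageStack <- function(channels, path) {
  stopifnot(length(channels) >= 1)
  arr <- simplify2array(channels)
  arr <- pmin(pmax(arr, 0), 1)
  EBImage::writeImage(EBImage::Image(arr), path, type = "tiff",
                      bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeImageStack
#' @export
readImageStack <- function(path) {
  img <- EBImage::readImage(path)
  arr <- EBImage::imageData(img)
  if (length(dim(arr)) == 2L) return(list(ch1 = as.matrix(arr)))
  # EBImage stores (x, y, frame); transpose back to (row = y, col = x)?
  chans <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
  names(chans) <- paste0("ch", seq_along(chans))
  chans
}
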