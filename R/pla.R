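#' Segment nuclei from a DAPI image
#'
#' Gaussian smoothing, a global Otsu threshold (with an absolute intensity
#' floor so pure-noise images yield no objects), hole filling, connected
#' component labeling and an area filter.
#'
#' @param img Single-channel 2-D image matrix.
#' @param smoothSigma Gaussian smoothing SD in px.
#' @param minArea,maxArea Retained nucleus area range in px^2.
#' @param minThreshold Absolute intensity floor for the threshold; Otsu is
#'   used when it lies above this floor.
#' @return A list: `table` (data frame `nucleus_id`, `y`, `x`, `area`) and
#'   `labels` (integer label matrix, 0 = background, relabeled densely
#'   after the area filter).
#' @export
segmentNuclei <- function(img, smoothSigma = 2, minArea = 100,
                          maxArea = Inf, minThreshold = 0.2) {
  stopifnot(is.matrix(img))
  if (length(img) == 0L)
    return(list(table = .emptyNucleusTable(), labels = img))
  sm <- EBImage::gblur(pmin(pmax(img, 0), 1), sigma = smoothSigma)
  thr <- max(EBImage::otsu(EBImage::Image(sm), range = c(0, 1)),
             minThreshold)
  mask <- sm > thr
  lab <- EBImage::bwlabel(EBImage::fillHull(EBImage::Image(mask)))
  lab <- as.matrix(EBImage::imageData(lab))
  .labelTable(lab, img, minArea, maxArea, weighted = FALSE, idName = "nucleus_id")
}

.emptyNucleusTable <- function()
  data.frame(nucleus_id = integer(0), y = numeric(0), x = numeric(0),
             area = numeric(0))

# centroid/area table from a label matrix, with dense relabeling after an
# area filter; centroids optionally intensity-weighted
.labelTable <- function(lab, img, minArea, maxArea, weighted, idName) {
  nLab <- max(lab)
  if (nLab == 0L) {
    tab <- data.frame(id = integer(0), y = numeric(0), x = numeric(0),
                      area = numeric(0))
    names(tab)[1] <- idName
    return(list(table = tab, labels = matrix(0L, nrow(lab), ncol(lab))))
  }
  idx <- which(lab > 0)
  l <- lab[idx]
  ys <- (idx - 1) %% nrow(lab) + 1
  xs <- (idx - 1) %/% nrow(lab) + 1
  w <- if (weighted) pmax(img[idx], 0) else rep(1, length(idx))
  area <- tabulate(l, nLab)
  sw <- rowsum(w, l)[, 1]
  cy <- rowsum(w * ys, l)[, 1] / sw
  cx <- rowsum(w * xs, l)[, 1] / sw
  keep <- which(area >= minArea & area <= maxArea)
  relab <- integer(nLab)
  relab[keep] <- seq_along(keep)
  newLab <- matrix(0L, nrow(lab), ncol(lab))
  newLab[idx] <- relab[l]
  tab <- data.frame(id = seq_along(keep), y = cy[keep], x = cx[keep],
                    area = area[keep])
  names(tab)[1] <- idName
  list(table = tab, labels = newLab)
}

#' Detect PLA foci in a single-channel image
#'
#' Band-pass filtering by a white top-hat with a disc structuring element,
#' a robust threshold (median + `k` * MAD of the filtered image, with an
#' absolute floor), connected-component labeling, and a size filter that
#' discards components larger than `maxArea` — large bright blobs are not
#' foci. Centroids are intensity-weighted.
#'
#' @param img Single-channel 2-D image matrix.
#' @param maxArea Maximum focus area in px^2 (default 50).
#' @param minArea Minimum focus area in px^2 (default 3; rejects
#'   single-pixel noise excursions).
#' @param topHatRadius Disc radius of the top-hat structuring element.
#' @param k Robust threshold multiplier.
#' @param minThreshold Absolute threshold floor.
#' @return A list: `table` (data frame `focus_id`, `y`, `x`, `area`) and
#'   `labels` (integer label matrix after filtering).
#' @export
detectFoci <- function(img, maxArea = 50, minArea = 3, topHatRadius = 5,
                       k = 6, minThreshold = 0.3) {
  stopifnot(is.matrix(img))
  brush <- EBImage::makeBrush(2L * as.integer(topHatRadius) + 1L,
                              shape = "disc")
  th <- EBImage::whiteTopHat(EBImage::Image(pmax(img, 0)), brush)
  th <- as.matrix(EBImage::imageData(th))
  cut <- max(stats::median(th) + k * stats::mad(th), minThreshold)
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(th > cut)))
  res <- .labelTable(lab, img, minArea, maxArea, weighted = TRUE,
                     idName = "focus_id")
  res
}

#' Assign foci to parent nuclei and count per nucleus
#'
#' A focus's parent is the nucleus whose mask contains its centroid
#' (rounded to the nearest pixel). Foci outside every nucleus are excluded
#' from the counts; each focus has at most one parent, so no focus is ever
#' double-counted.
#'
#' @param foci Focus table from [detectFoci()] (`focus_id`, `y`, `x`, ...).
#' @param nucleusLabels Integer nucleus label matrix from
#'   [segmentNuclei()].
#' @param nNuclei Number of nuclei (defaults to `max(nucleusLabels)`).
#' @return A list: `foci` (the table with a `parent` column, `NA` =
#'   outside all nuclei) and `counts` (integer vector, one per nucleus).
#' @export
assignFoci <- function(foci, nucleusLabels, nNuclei = max(nucleusLabels)) {
  nNuclei <- max(0L, as.integer(nNuclei))
  if (nrow(foci) == 0L)
    return(list(foci = cbind(foci, parent = integer(0)),
                counts = integer(nNuclei)))
  yy <- pmin(pmax(round(foci$y), 1), nrow(nucleusLabels))
  xx <- pmin(pmax(round(foci$x), 1), ncol(nucleusLabels))
  parent <- nucleusLabels[cbind(yy, xx)]
  parent[parent == 0L] <- NA_integer_
  counts <- tabulate(parent[!is.na(parent)], nbins = nNuclei)
  foci$parent <- parent
  list(foci = foci, counts = as.integer(counts))
}

#' Count PLA foci per nucleus for one condition
#'
#' Runs the full per-image quantification: nucleus segmentation on the
#' DAPI channel, size-filtered focus detection on the PLA channel, and
#' parent-child assignment.
#'
#' @param dapi,pla Single-channel image matrices from the same field.
#' @param condition Condition label recorded in the result.
#' @param nucleusParams,focusParams Named lists of overrides passed to
#'   [segmentNuclei()] / [detectFoci()].
#' @return A [PlaResult].
#' @export
countFociPerNucleus <- function(dapi, pla, condition = "condition",
                                nucleusParams = list(),
                                focusParams = list()) {
  seg <- do.call(segmentNuclei, c(list(img = dapi), nucleusParams))
  det <- do.call(detectFoci, c(list(img = pla), focusParams))
  asg <- assignFoci(det$table, seg$labels, nrow(seg$table))
  new("PlaResult", condition = condition, counts = as.numeric(asg$counts),
      nuclei = seg$table, foci = asg$foci)
}

#' Compare focus counts between two conditions
#'
#' Fold ratio of mean foci per nucleus and a two-sided Mann-Whitney
#' rank-sum test. Labels follow the reporting convention: `"significant"`
#' for p < 0.001, `"NS"` for p > 0.05, otherwise the raw p-value is the
#' label. The raw p-value is always reported alongside.
#'
#' @param a,b [PlaResult] objects (or bare count vectors), each with at
#'   least 2 nuclei.
#' @return A list: `ratio` (mean(a)/mean(b)), `U`, `p.value`, `label`,
#'   `n` (nuclei per condition).
#' @export
compareConditions <- function(a, b) {
  ca <- if (methods::is(a, "PlaResult")) fociCounts(a) else as.numeric(a)
  cb <- if (methods::is(b, "PlaResult")) fociCounts(b) else as.numeric(b)
  if (length(ca) < 2L || length(cb) < 2L)
    stop("each condition needs at least 2 nuclei")
  mw <- mannWhitneyU(ca, cb)
  label <- if (mw$p.value < 0.001) "significant"
           else if (mw$p.value > 0.05) "NS"
           else format(mw$p.value, digits = 3)
  list(ratio = mean(ca) / mean(cb), U = mw$U, p.value = mw$p.value,
       label = label, n = c(length(ca), length(cb)))
}

# normalized cross-correlation over circular shifts via FFT; returns the
# subpixel peak location (dy, dx mapping b onto a) and the peak value
.xcorrPeak <- function(a, b) {
  a0 <- a - mean(a); b0 <- b - mean(b)
  num <- Re(stats::fft(stats::fft(a0) * Conj(stats::fft(b0)),
                       inverse = TRUE)) / length(a0)
  den <- sqrt(sum(a0^2) * sum(b0^2))
  cc <- num / den
  pk <- which.max(cc)
  ny <- nrow(cc); nx <- ncol(cc)
  py <- (pk - 1) %% ny + 1
  px <- (pk - 1) %/% ny + 1
  # parabolic subpixel refinement along each axis (circular neighbors)
  sub <- function(vm, v0, vp) {
    den <- vm - 2 * v0 + vp
    if (den == 0) 0 else 0.5 * (vm - vp) / den
  }
  wy <- c((py - 2) %% ny + 1, py, py %% ny + 1)
  wx <- c((px - 2) %% nx + 1, px, px %% nx + 1)
  dy <- (py - 1) + sub(cc[wy[1], px], cc[py, px], cc[wy[3], px])
  dx <- (px - 1) + sub(cc[py, wx[1]], cc[py, px], cc[py, wx[3]])
  if (dy > ny / 2) dy <- dy - ny
  if (dx > nx / 2) dx <- dx - nx
  list(dy = dy, dx = dx, corr = cc[py, px])
}

#' Estimate the rigid drift between two sequential rounds
#'
#' Returns the transform (`dy`, `dx`, `angle`) that maps round 2 onto
#' round 1, i.e. `shiftRotateStack(round2, dy, dx, angle)` best matches
#' `round1`. Translation is found at the peak of the FFT
#' cross-correlation (with parabolic subpixel refinement); rotation by
#' maximizing the correlation over a coarse angular grid followed by
#' golden-section refinement. 3-D stacks are maximum-projected first.
#'
#' @param round1,round2 Image matrices (or 3-D stacks) of the same field.
#' @param maxAngleDeg Half-width of the angular search grid (degrees).
#' @param coarseStepDeg Coarse grid step (degrees).
#' @param minCorr Correlation floor below which the estimate is flagged
#'   unreliable.
#' @return A list: `dy`, `dx`, `angle` (degrees), `correlation`,
#'   `reliable`.
#' @export
registerRounds <- function(round1, round2, maxAngleDeg = 15,
                           coarseStepDeg = 1, minCorr = 0.2) {
  proj <- function(x) if (length(dim(x)) == 3L) apply(x, c(1, 2), max) else x
  a <- proj(round1); b <- proj(round2)
  stopifnot(all(dim(a) == dim(b)))
  score <- function(theta) {
    # candidate rotations are scoring probes, not applied transforms, so
    # the out-of-frame content warning does not apply here
    br <- if (theta == 0) b else
      suppressWarnings(shiftRotateStack(b, 0, 0, theta))
    .xcorrPeak(a, br)
  }
  angles <- seq(-maxAngleDeg, maxAngleDeg, by = coarseStepDeg)
  corrs <- vapply(angles, function(t) score(t)$corr, numeric(1))
  best <- angles[which.max(corrs)]
  opt <- stats::optimize(function(t) -score(t)$corr,
                         interval = c(best - coarseStepDeg,
                                      best + coarseStepDeg), tol = 0.01)
  angle <- opt$minimum
  pk <- score(angle)
  if (pk$corr < max(corrs)) {        # refinement never worsens the fit
    angle <- best
    pk <- score(angle)
  }
  reliable <- pk$corr >= minCorr
  if (!reliable)
    warning("registerRounds: correlation peak below floor; unreliable")
  list(dy = pk$dy, dx = pk$dx, angle = angle, correlation = pk$corr,
       reliable = reliable)
}

#' Fraction of round-1 foci matched by round-2 foci after registration
#'
#' Greedy nearest-neighbor matching: the closest unmatched pair within
#' `radius` px is matched repeatedly until none remains. The fraction is
#' `matched / min(n1, n2)`. The permutation null re-places the round-2
#' foci uniformly within their parent nucleus masks `nPermutations` times;
#' the p-value is the fraction of permutations with at least the observed
#' number of matches (small p = more colocalization than chance).
#'
#' @param foci1,foci2 Data frames with `y`, `x` and (for the null)
#'   `parent` columns, both registered into the round-1 frame.
#' @param radius Matching radius in px.
#' @param nucleusLabels Integer nucleus label matrix (required when
#'   `nPermutations > 0`).
#' @param nPermutations Number of null permutations (0 = skip the test).
#' @param seed Integer seed for the permutations.
#' @return A list: `fraction`, `matched`, `p.value` (`NA` when the null is
#'   skipped).
#' @export
overlapFraction <- function(foci1, foci2, radius = 2, nucleusLabels = NULL,
                            nPermutations = 200, seed = 1) {
  n1 <- nrow(foci1); n2 <- nrow(foci2)
  if (n1 == 0L || n2 == 0L)
    return(list(fraction = 0, matched = 0L, p.value = 1))
  observed <- .greedyMatches(foci1, foci2, radius)
  fraction <- observed / min(n1, n2)
  p <- NA_real_
  if (nPermutations > 0) {
    if (is.null(nucleusLabels) || is.null(foci2$parent))
      stop("the permutation null needs nucleusLabels and foci2$parent")
    pixByNucleus <- split(which(nucleusLabels > 0),
                          nucleusLabels[nucleusLabels > 0])
    ny <- nrow(nucleusLabels)
    ge <- withSeed(seed, {
      hits <- 0L
      for (p_i in seq_len(nPermutations)) {
        perm <- foci2
        for (j in seq_len(n2)) {
          par <- as.character(perm$parent[j])
          if (is.na(perm$parent[j]) || is.null(pixByNucleus[[par]])) next
          px <- sample(pixByNucleus[[par]], 1)
          perm$y[j] <- (px - 1) %% ny + 1
          perm$x[j] <- (px - 1) %/% ny + 1
        }
        if (.greedyMatches(foci1, perm, radius) >= observed)
          hits <- hits + 1L
      }
      hits
    })
    p <- ge / nPermutations
  }
  list(fraction = fraction, matched = observed, p.value = p)
}

.greedyMatches <- function(foci1, foci2, radius) {
  d <- sqrt(outer(foci1$y, foci2$y, "-")^2 + outer(foci1$x, foci2$x, "-")^2)
  matched <- 0L
  while (length(d) && min(d) <= radius) {
    pk <- arrayInd(which.min(d), dim(d))
    matched <- matched + 1L
    d <- d[-pk[1], -pk[2], drop = FALSE]
  }
  matched
}
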