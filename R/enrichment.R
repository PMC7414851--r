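#' Convert per-window tag counts to TPM (tags per million)
#'
#' `tpm_i = counts_i / sum(counts) * 1e6`. No length term is applied:
#' windows are equal-width by construction, so the count scaling alone
#' reproduces tags-per-million semantics and the total is exactly 1e6.
#'
#' @param counts Nonnegative per-window tag counts.
#' @return Numeric TPM vector summing to 1e6.
#' @examples
#' tpmNormalize(c(1, 1, 2))
#' @export
tpmNormalize <- function(counts) {
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and nonnegative")
  tot <- sum(counts)
  if (tot <= 0) stop("empty sample: total count is zero")
  counts / tot * 1e6
}

#' Per-window log2(ChIP/Input) enrichment
#'
#' `e_i = log2((chip_i + c) / (input_i + c))` on TPM-normalized tracks.
#' The default pseudocount of 1 TPM guards windows with zero coverage in
#' either track; `pseudocount = 0` is allowed only when both tracks are
#' strictly positive.
#'
#' @param chipTpm,inputTpm Aligned per-window TPM vectors (same grid).
#' @param pseudocount Pseudocount in TPM units (default 1).
#' @return Numeric per-window log2 enrichment.
#' @export
computeEnrichment <- function(chipTpm, inputTpm, pseudocount = 1) {
  if (length(chipTpm) != length(inputTpm))
    stop("chip and input are on different grids (lengths differ)")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (pseudocount == 0 && (any(chipTpm <= 0) || any(inputTpm <= 0)))
    stop("pseudocount 0 requires strictly positive tracks")
  log2((chipTpm + pseudocount) / (inputTpm + pseudocount))
}

#' Select enriched windows
#'
#' Windows with strictly positive log2(ChIP/Input); windows at exactly 0
#' are excluded.
#'
#' @param enrichment Per-window log2 enrichment.
#' @return Integer indices (1-based positions in the grid) of enriched
#'   windows.
#' @export
selectEnrichedWindows <- function(enrichment) {
  which(!is.na(enrichment) & enrichment > 0)
}

#' Draw matched random control windows
#'
#' Samples `k` distinct windows uniformly without replacement from the
#' retained grid, matching an enriched-window set in number and (by
#' construction of the grid) in size. Enriched windows are not excluded
#' from the pool by default; pass their indices via `exclude` to drop them.
#'
#' @param nWindows Number of retained windows in the grid.
#' @param k Number of controls to draw.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param exclude Optional indices to leave out of the sampling pool.
#' @return Sorted integer indices of the control windows.
#' @export
sampleMatchedControls <- function(nWindows, k, seed, exclude = integer(0)) {
  pool <- setdiff(seq_len(nWindows), exclude)
  if (k > length(pool))
    stop("k exceeds the number of available windows")
  sort(withSeed(seed, sample(pool, k, replace = FALSE)))
}

#' Assign equal-count quantile labels
#'
#' Windows are sorted by value ascending (ties broken by original/genomic
#' order so the labeling is deterministic) and split into `n` contiguous
#' bins whose sizes differ by at most one; when the count is not divisible
#' by `n` the extra windows go to the lowest quantiles. Label 1 holds the
#' smallest values — the latest-replicating (RT scheme) or most-B
#' (eigenvector scheme) windows — ascending toward early/A. `NA` values
#' receive an `NA` label and are excluded from the split.
#'
#' @param values Per-window scores (`NA` = missing, excluded).
#' @param n Number of quantiles (default 25, the profile resolution).
#' @return Integer labels `1..n` (`NA` where the score is missing).
#' @examples
#' assignQuantiles(c(1:100), n = 25)[7]  # quantile 2
#' @export
assignQuantiles <- function(values, n = 25) {
  ok <- which(!is.na(values))
  if (length(ok) < n)
    stop("fewer non-missing values (", length(ok), ") than quantiles (", n, ")")
  ord <- ok[order(values[ok], ok)]   # ascending, ties by genomic order
  N <- length(ord)
  q <- N %/% n
  r <- N %% n
  sizes <- rep(q, n)
  if (r > 0) sizes[seq_len(r)] <- q + 1L  # remainder to the lowest quantiles
  labels <- rep(NA_integer_, length(values))
  labels[ord] <- rep.int(seq_len(n), sizes)
  labels
}

#' Five-number-plus-mean distribution summary
#'
#' Quartiles by linear interpolation (type-7), whiskers at the most extreme
#' data points within 1.5 x IQR of the quartile hinges (standard box-plot
#' convention), outliers listed beyond that.
#'
#' @param x Numeric values.
#' @return A list: `n`, `mean`, `median`, `q1`, `q3`, `whisker_lo`,
#'   `whisker_hi`, `outliers`.
#' @export
distributionSummary <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("no values to summarize")
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- qs[3] - qs[1]
  loFence <- qs[1] - 1.5 * iqr
  hiFence <- qs[3] + 1.5 * iqr
  inside <- x >= loFence & x <= hiFence
  list(n = length(x), mean = mean(x), median = qs[2], q1 = qs[1], q3 = qs[3],
       whisker_lo = min(x[inside]), whisker_hi = max(x[inside]),
       outliers = sort(x[!inside]))
}

#' Per-quantile coverage profile
#'
#' Summarizes the coverage (TPM) distribution of the windows in each
#' quantile: mean (the dot in the profile plots), median, quartiles and
#' whiskers.
#'
#' @param tpm Per-window coverage, aligned with `labels`.
#' @param labels Quantile labels from [assignQuantiles()].
#' @param scheme Ranking scheme the labels came from (`"RT"` or
#'   `"eigenvector"`); recorded in the result.
#' @return A [QuantileProfile].
#' @export
quantileCoverageProfile <- function(tpm, labels, scheme = "RT") {
  stopifnot(length(tpm) == length(labels))
  n <- max(labels, na.rm = TRUE)
  membership <- lapply(seq_len(n), function(q) which(!is.na(labels) & labels == q))
  values <- lapply(membership, function(ids) tpm[ids])
  rows <- lapply(seq_len(n), function(q) {
    s <- distributionSummary(values[[q]])
    data.frame(quantile = q, n = s$n, mean = s$mean, median = s$median,
               q1 = s$q1, q3 = s$q3,
               whisker_lo = s$whisker_lo, whisker_hi = s$whisker_hi)
  })
  new("QuantileProfile", scheme = scheme, nQuantiles = as.integer(n),
      summary = do.call(rbind, rows), membership = membership,
      values = values)
}

#' Mann-Whitney U rank-sum test
#'
#' U is the number of (x, y) pairs with x > y (ties count 1/2). For small
#' samples (`min(n, m) <= exactMax`) without ties the two-sided p-value is
#' computed by exact enumeration of the U null distribution; otherwise the
#' tie-corrected normal approximation with continuity correction is used.
#'
#' @param x,y Numeric samples.
#' @param exactMax Largest `min(n, m)` for which the exact branch is used
#'   (default 8).
#' @return A list: `U`, `p.value`, `method` (`"exact"` or `"normal"`).
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mannWhitneyU <- function(x, y, exactMax = 8) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n <- length(x); m <- length(y)
  if (n == 0L || m == 0L) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- table(c(x, y))
  hasTies <- any(ties > 1)
  if (!hasTies && min(n, m) <= exactMax) {
    counts <- .uNullCounts(n, m)          # counts of U = 0..n*m
    tot <- sum(counts)
    u <- round(U)
    pLow <- sum(counts[seq_len(u + 1)]) / tot
    pHigh <- sum(counts[(u + 1):(n * m + 1)]) / tot
    p <- min(1, 2 * min(pLow, pHigh))
    return(list(U = U, p.value = p, method = "exact"))
  }
  N <- n + m
  mu <- n * m / 2
  tieTerm <- sum(ties^3 - ties)
  sigma2 <- n * m / 12 * ((N + 1) - tieTerm / (N * (N - 1)))
  if (sigma2 <= 0)                         # all values identical
    return(list(U = U, p.value = 1, method = "normal"))
  d <- U - mu
  d <- d - sign(d) * 0.5                   # continuity correction
  z <- d / sqrt(sigma2)
  list(U = U, p.value = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

# Null distribution of U for sample sizes (n, m) without ties: counts of
# the C(n+m, n) arrangements attaining each U in 0..n*m, via the standard
# recursion on the largest observation:
#   c(u; n, m) = c(u - m; n - 1, m) + c(u; n, m - 1).
.uNullCounts <- function(n, m) {
  U <- n * m
  f <- matrix(0, n + 1, U + 1)  # counts for sizes (i, j - 1), row i + 1
  f[, 1] <- 1                   # j = 0: U is always 0
  for (j in seq_len(m)) {
    g <- matrix(0, n + 1, U + 1)
    g[1, 1] <- 1
    for (i in seq_len(n)) {
      shifted <- c(rep(0, j), g[i, seq_len(U + 1 - j)])
      g[i + 1, ] <- f[i + 1, ] + shifted
    }
    f <- g
  }
  f[n + 1, ]
}

#' Violin/box RT summary of enriched windows versus controls
#'
#' Summarizes the RT score distribution of a selected window set and its
#' matched random controls, and compares them with a two-sided
#' Mann-Whitney rank-sum test.
#'
#' @param selected,controls Window indices (1-based grid positions).
#' @param rt Per-window RT scores (`NA` allowed; such windows are dropped
#'   from the summaries with a message).
#' @return A list: `selected` and `controls` ([distributionSummary()]
#'   lists), `test` (the [mannWhitneyU()] result).
#' @export
violinRtSummary <- function(selected, controls, rt) {
  if (length(selected) == 0L || length(controls) == 0L)
    stop("both window sets must be non-empty")
  xs <- rt[selected]; xc <- rt[controls]
  nDrop <- sum(is.na(xs)) + sum(is.na(xc))
  if (nDrop > 0)
    message(sprintf("violinRtSummary: %d window(s) without RT excluded", nDrop))
  xs <- xs[!is.na(xs)]; xc <- xc[!is.na(xc)]
  list(selected = distributionSummary(xs),
       controls = distributionSummary(xc),
       test = mannWhitneyU(xs, xc))
}

#' Coverage trend across quantiles
#'
#' Spearman rank correlation between the quantile index (1 = late/B, n =
#' early/A) and the per-quantile mean coverage. +1 means coverage rises
#' monotonically toward early-replicating / A-compartment windows, -1 the
#' reverse.
#'
#' @param profile A [QuantileProfile].
#' @return Spearman rho in `[-1, 1]`; constant means give 0 with attribute
#'   `"degenerate" = TRUE`.
#' @export
trendStatistic <- function(profile) {
  s <- profileSummary(profile)
  if (nrow(s) < 3L) stop("need at least 3 quantiles")
  means <- s$mean
  if (stats::sd(means) == 0)
    return(structure(0, degenerate = TRUE))
  stats::cor(seq_along(means), means, method = "spearman")
}
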