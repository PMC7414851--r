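#' @include AllGenerics.R
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges rowData
#'   rowData<- assay assay<- assayNames
NULL

#' ContactMatrix: binned symmetric Hi-C counts for one chromosome
#'
#' Holds a dense symmetric matrix of intra-chromosomal contact counts at a
#' fixed bin width, plus a logical mask of bins retained for balancing and
#' eigenvector analysis. Sparse bins (those with fewer than
#' `minNonzeroFrac` nonzero entries, including all-zero rows) are masked at
#' construction because matrix balancing is unstable on them.
#'
#' @slot chrom Chromosome name.
#' @slot binWidth Bin width in bp.
#' @slot counts Dense symmetric nonnegative count matrix.
#' @slot mask Logical vector, `TRUE` for retained bins.
#'
#' @param counts Symmetric nonnegative square matrix of contact counts.
#' @param chrom Chromosome name (default `"chr1"`).
#' @param binWidth Bin width in bp (default 50000, the analysis resolution).
#' @param minNonzeroFrac Minimum fraction of nonzero entries for a bin to be
#'   retained (default 0.25).
#' @param x A `ContactMatrix`.
#' @return `ContactMatrix()` returns a validated object; `contactCounts()`
#'   the count matrix; `binMask()` the retained-bin mask; `binWidth()` the
#'   bin width in bp.
#'
#' @examples
#' m <- matrix(c(4, 2, 2, 4), 2)
#' cm <- ContactMatrix(m, binWidth = 50000)
#' binMask(cm)
#' @aliases contactCounts binMask binWidth
#' @export ContactMatrix
#' @exportClass ContactMatrix
setClass("ContactMatrix",
  slots = c(chrom = "character", binWidth = "numeric",
            counts = "matrix", mask = "logical"))

setValidity("ContactMatrix", function(object) {
  m <- object@counts
  if (!is.numeric(m)) return("counts must be numeric")
  if (nrow(m) != ncol(m)) return("counts must be square")
  if (length(object@mask) != nrow(m)) return("mask length != number of bins")
  if (any(m < 0)) return("counts must be nonnegative")
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
    return("counts must be symmetric")
  if (length(object@binWidth) != 1L || object@binWidth <= 0)
    return("binWidth must be a single positive number")
  TRUE
})

ContactMatrix <- function(counts, chrom = "chr1", binWidth = 50000,
                          minNonzeroFrac = 0.25) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  nz <- rowSums(counts > 0)
  mask <- nz > 0 & (nz / n) >= minNonzeroFrac
  new("ContactMatrix", chrom = chrom, binWidth = binWidth,
      counts = counts, mask = mask)
}

#' @rdname ContactMatrix-class
setMethod("contactCounts", "ContactMatrix", function(x) x@counts)
#' @rdname ContactMatrix-class
setMethod("binMask", "ContactMatrix", function(x) x@mask)
#' @rdname ContactMatrix-class
setMethod("binWidth", "ContactMatrix", function(x) x@binWidth)

setMethod("show", "ContactMatrix", function(object) {
  n <- nrow(object@counts)
  cat(sprintf("ContactMatrix: %s, %d bins x %d bp (%d retained, %d masked)\n",
              object@chrom, n, as.integer(object@binWidth),
              sum(object@mask), sum(!object@mask)))
  cat(sprintf("  total contacts: %.4g\n", sum(object@counts)))
})

#' QuantileProfile: per-quantile coverage distribution summaries
#'
#' Windows are ranked by a score (RT or compartment eigenvector) and split
#' into `nQuantiles` equal-count bins; quantile 1 holds the smallest scores
#' (latest replication / most-B) and ascends toward early/A. For each
#' quantile the coverage (TPM) distribution is summarized by mean, median,
#' quartiles and Tukey whiskers.
#'
#' @slot scheme Ranking scheme, `"RT"` or `"eigenvector"`.
#' @slot nQuantiles Number of quantiles.
#' @slot summary One row per quantile: `quantile`, `n`, `mean`, `median`,
#'   `q1`, `q3`, `whisker_lo`, `whisker_hi`.
#' @slot membership List of window ids per quantile.
#' @slot values List of coverage values per quantile.
#'
#' @param x A `QuantileProfile`.
#' @return `profileSummary()` the per-quantile summary data frame;
#'   `quantileMembers()` the window-id list; `quantileValues()` the
#'   coverage-value list.
#' @aliases profileSummary quantileMembers quantileValues
#' @exportClass QuantileProfile
setClass("QuantileProfile",
  slots = c(scheme = "character", nQuantiles = "integer",
            summary = "data.frame", membership = "list", values = "list"))

setValidity("QuantileProfile", function(object) {
  n <- object@nQuantiles
  if (nrow(object@summary) != n) return("summary must have nQuantiles rows")
  if (length(object@membership) != n || length(object@values) != n)
    return("membership/values must have nQuantiles elements")
  sizes <- lengths(object@membership)
  if (diff(range(sizes)) > 1L) return("quantile sizes must differ by <= 1")
  TRUE
})

#' @rdname QuantileProfile-class
setMethod("profileSummary", "QuantileProfile", function(x) x@summary)
#' @rdname QuantileProfile-class
setMethod("quantileMembers", "QuantileProfile", function(x) x@membership)
#' @rdname QuantileProfile-class
setMethod("quantileValues", "QuantileProfile", function(x) x@values)

setMethod("show", "QuantileProfile", function(object) {
  cat(sprintf("QuantileProfile: %s, n = %d quantiles, %d windows\n",
              object@scheme, object@nQuantiles,
              sum(lengths(object@membership))))
  cat("  quantile means (1 = late/B ... n = early/A):\n")
  print(signif(object@summary$mean, 4))
})

#' PlaResult: per-nucleus PLA focus counts for one condition
#'
#' The unit of PLA quantification: for every segmented nucleus in a
#' condition, the number of proximity-ligation foci whose centroid falls
#' inside the nucleus mask.
#'
#' @slot condition Condition label.
#' @slot counts Integer focus count per nucleus.
#' @slot nuclei Per-nucleus table (`nucleus_id`, centroid, area).
#' @slot foci Per-focus table (`focus_id`, centroid, area, `parent`).
#'
#' @param x A `PlaResult`.
#' @return `fociCounts()` the per-nucleus count vector; `conditionName()`
#'   the condition label.
#' @aliases fociCounts conditionName
#' @exportClass PlaResult
setClass("PlaResult",
  slots = c(condition = "character", counts = "numeric",
            nuclei = "data.frame", foci = "data.frame"))

setValidity("PlaResult", function(object) {
  if (any(object@counts < 0)) return("counts must be nonnegative")
  if (nrow(object@nuclei) != length(object@counts))
    return("one count per nucleus required")
  TRUE
})

#' @rdname PlaResult-class
setMethod("fociCounts", "PlaResult", function(x) x@counts)
#' @rdname PlaResult-class
setMethod("conditionName", "PlaResult", function(x) x@condition)

setMethod("show", "PlaResult", function(object) {
  cat(sprintf("PlaResult: condition '%s', %d nuclei\n",
              object@condition, length(object@counts)))
  cat(sprintf("  foci/nucleus: mean %.2f, median %.1f, range [%d, %d]\n",
              mean(object@counts), stats::median(object@counts),
              as.integer(min(object@counts)), as.integer(max(object@counts))))
})

#' WindowExperiment: per-window scores and sample assays on a window grid
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] whose rows are the
#' equal-width genomic windows of a [makeWindows()] grid (with dense
#' `window_id` starting at 0) and whose assays hold per-sample tag counts,
#' TPM and log2(ChIP/Input) enrichment. Per-window scores (RT, compartment
#' eigenvector, quantile labels) live in `rowData`; missing scores are `NA`,
#' never silently zero.
#'
#' @param grid A window grid from [makeWindows()].
#' @param counts Optional windows x samples count matrix.
#' @param rt,eigenvector Optional per-window score vectors (`NA` = missing).
#' @return A `WindowExperiment`.
#' @examples
#' grid <- makeWindows(c(chr1 = 200000), width = 50000)
#' we <- WindowExperiment(grid, counts = cbind(chip = c(5, 0, 2, 1)),
#'                        rt = c(1.2, 0.5, -0.3, -1.1))
#' @export WindowExperiment
#' @exportClass WindowExperiment
setClass("WindowExperiment",
         contains = "RangedSummarizedExperiment")

setValidity("WindowExperiment", function(object) {
  gr <- SummarizedExperiment::rowRanges(object)
  if (length(gr) == 0L) return("empty window grid")
  w <- GenomicRanges::width(gr)
  if (length(unique(w)) != 1L) return("all windows must have equal width")
  wid <- S4Vectors::mcols(gr)$window_id
  if (is.null(wid) || !identical(as.integer(wid), seq_len(length(gr)) - 1L))
    return("window_id must be dense 0..N-1 in file order")
  TRUE
})

WindowExperiment <- function(grid, counts = NULL, rt = NULL,
                             eigenvector = NULL) {
  n <- length(grid)
  if (is.null(counts)) {
    counts <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    counts <- as.matrix(counts)
    stopifnot(nrow(counts) == n)
  }
  rd <- S4Vectors::DataFrame(
    rt = if (is.null(rt)) rep(NA_real_, n) else rt,
    eigenvector = if (is.null(eigenvector)) rep(NA_real_, n) else eigenvector)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowRanges = grid)
  SummarizedExperiment::rowData(se) <- cbind(
    SummarizedExperiment::rowData(se), rd)
  new("WindowExperiment", se)
}

setMethod("show", "WindowExperiment", function(object) {
  gr <- SummarizedExperiment::rowRanges(object)
  cat(sprintf("WindowExperiment: %d windows x %d bp, %d sample(s)\n",
              length(gr), GenomicRanges::width(gr)[1], ncol(object)))
  cat(sprintf("  chromosomes: %s\n",
              paste(GenomeInfoDb::seqlevels(gr), collapse = ", ")))
  rd <- SummarizedExperiment::rowData(object)
  cat(sprintf("  rt: %d windows scored; eigenvector: %d windows scored\n",
              sum(!is.na(rd$rt)), sum(!is.na(rd$eigenvector))))
  if (ncol(object) > 0)
    cat(sprintf("  samples: %s\n", paste(colnames(object), collapse = ", ")))
  cat(sprintf("  assays: %s\n",
              paste(SummarizedExperiment::assayNames(object), collapse = ", ")))
})
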