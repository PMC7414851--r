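#' @importFrom GenomicRanges GRanges width start end seqnames findOverlaps
#'   pintersect
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits DataFrame
#' @importFrom GenomeInfoDb seqlengths seqlevels Seqinfo seqnames
NULL

#' Read a chrom.sizes file
#'
#' Two-column TSV (chromosome name, length in bp), the UCSC convention.
#'
#' @param path File path.
#' @return Named numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  if (nrow(df) == 0L) stop("empty chrom.sizes file: ", path)
  stats::setNames(df$length, df$chrom)
}

#' Write a chrom.sizes file
#' @param chromSizes Named numeric vector of chromosome lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeChromSizes <- function(chromSizes, path) {
  utils::write.table(
    data.frame(chrom = names(chromSizes), length = as.integer(chromSizes)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Tile the genome into equal-width windows
#'
#' Divides each chromosome into contiguous windows of `width` bp starting
#' at position 0. The terminal partial window (the `length %% width`
#' remainder) is dropped by default so that every retained window has
#' exactly the same width, which the TPM and quantile analyses assume;
#' set `keepPartial = TRUE` to retain it.
#'
#' @param chromSizes Named numeric vector of chromosome lengths in bp, or a
#'   path to a chrom.sizes file.
#' @param width Window width in bp; the default 50000 (50 kb) is the
#'   analysis resolution used throughout.
#' @param keepPartial Keep the terminal sub-width window per chromosome?
#' @return A [GenomicRanges::GRanges] with one range per window, a dense
#'   0-based `window_id` metadata column, and `seqlengths` set. The number
#'   of bp dropped per chromosome is attached as attribute `"dropped_bp"`
#'   (in `metadata`-free attribute form) and reported via `message()`.
#' @examples
#' makeWindows(c(chr1 = 120000), width = 50000)  # 2 windows, 20 kb dropped
#' @export
makeWindows <- function(chromSizes, width = 50000, keepPartial = FALSE) {
  if (is.character(chromSizes) && length(chromSizes) == 1L)
    chromSizes <- readChromSizes(chromSizes)
  if (length(chromSizes) == 0L) stop("empty chrom sizes")
  if (is.null(names(chromSizes)) || any(!nzchar(names(chromSizes))))
    stop("chromSizes must be named by chromosome")
  if (width <= 0) stop("width must be > 0")
  if (any(chromSizes <= 0)) stop("chromosome lengths must be > 0")

  pieces <- lapply(names(chromSizes), function(chr) {
    len <- chromSizes[[chr]]
    nFull <- floor(len / width)
    starts0 <- seq_len(nFull) * width - width    # 0-based starts
    ends0 <- starts0 + width
    if (keepPartial && len %% width > 0) {
      starts0 <- c(starts0, nFull * width)
      ends0 <- c(ends0, len)
    }
    if (length(starts0) == 0L) return(NULL)
    GRanges(chr, IRanges(start = starts0 + 1, end = ends0))
  })
  gr <- suppressWarnings(do.call(c, pieces[!vapply(pieces, is.null, TRUE)]))
  if (is.null(gr) || length(gr) == 0L)
    stop("no windows: all chromosomes shorter than 'width'")
  GenomeInfoDb::seqlevels(gr) <- names(chromSizes)
  GenomeInfoDb::seqlengths(gr) <- chromSizes
  mcols(gr)$window_id <- seq_along(gr) - 1L
  droppedBp <- sum(chromSizes) - sum(width(gr))
  attr(gr, "dropped_bp") <- droppedBp
  if (droppedBp > 0 && !keepPartial)
    message(sprintf("makeWindows: dropped %d bp of terminal partial windows",
                    as.integer(droppedBp)))
  gr
}

.checkWithinBounds <- function(track, grid, what) {
  sl <- seqlengths(grid)
  chr <- as.character(seqnames(track))
  known <- chr %in% names(sl)
  if (any(known)) {
    over <- end(track)[known] > sl[chr[known]]
    if (any(over))
      stop(what, ": ", sum(over),
           " interval(s) extend beyond the chromosome end")
  }
  invisible(TRUE)
}

#' Bin a score track onto a window grid by coverage-weighted mean
#'
#' Each window's value is the mean of the overlapping interval values
#' weighted by the number of bases each interval contributes to the
#' window (equivalent to the base-resolution mean when intervals tile
#' without overlap). Windows with no overlapping interval are `NA`.
#'
#' @param track A `GRanges` with a numeric `score` column (e.g. read from
#'   bedGraph via [readBedGraph()]).
#' @param grid Window grid from [makeWindows()].
#' @return Numeric vector, one value per window (`NA` = no coverage).
#' @export
binTrackMean <- function(track, grid) {
  stopifnot(methods::is(track, "GRanges"), methods::is(grid, "GRanges"))
  if (is.null(track$score)) stop("track must carry a 'score' column")
  .checkWithinBounds(track, grid, "binTrackMean")
  hits <- findOverlaps(track, grid, ignore.strand = TRUE)
  if (length(hits) == 0L) return(rep(NA_real_, length(grid)))
  ov <- pintersect(track[queryHits(hits)], grid[subjectHits(hits)])
  w <- width(ov)
  v <- track$score[queryHits(hits)]
  j <- subjectHits(hits)
  num <- rowsum(w * v, j)
  den <- rowsum(w, j)
  out <- rep(NA_real_, length(grid))
  out[as.integer(rownames(num))] <- num / den
  out
}

#' Count tags per window by fragment midpoint
#'
#' Each tag (read/fragment interval) is assigned to the single window
#' containing its midpoint, so every tag is counted exactly once and
#' `assigned + discarded` always equals the number of input tags. Tags
#' whose midpoint falls in a dropped terminal remainder (or otherwise off
#' the grid) are discarded and counted.
#'
#' @param tags A `GRanges` of tag intervals, or a path to a BED file.
#' @param grid Window grid from [makeWindows()].
#' @return Integer vector of per-window counts with attributes
#'   `"assigned"` and `"discarded"`.
#' @export
binTagCounts <- function(tags, grid) {
  if (is.character(tags) && length(tags) == 1L) tags <- readBed(tags)
  stopifnot(methods::is(tags, "GRanges"), methods::is(grid, "GRanges"))
  .checkWithinBounds(tags, grid, "binTagCounts")
  # midpoint of the 0-based half-open fragment, as a 1-based position
  mid0 <- floor((start(tags) - 1 + end(tags)) / 2)
  midGr <- GRanges(seqnames(tags), IRanges(mid0 + 1, width = 1))
  hits <- findOverlaps(midGr, grid, ignore.strand = TRUE)
  counts <- tabulate(subjectHits(hits), nbins = length(grid))
  assigned <- length(hits)
  structure(as.integer(counts),
            assigned = assigned, discarded = length(tags) - assigned)
}

#' Read/write interval formats
#'
#' Thin wrappers over [rtracklayer::import()]/[rtracklayer::export()] that
#' fix the dialect used throughout the package: BED and bedGraph files are
#' 0-based half-open on disk and converted to the 1-based closed `GRanges`
#' convention in memory.
#'
#' @param path File path.
#' @return A `GRanges`; for bedGraph, with a numeric `score` column.
#' @export
readBedGraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  mcols(gr) <- DataFrame(score = as.numeric(gr$score))
  gr
}

#' @rdname readBedGraph
#' @export
readBed <- function(path) rtracklayer::import(path, format = "bed")

#' @rdname readBedGraph
#' @param gr A `GRanges`; for bedGraph export it must carry `score`.
#' @export
writeBedGraph <- function(gr, path) {
  stopifnot(!is.null(gr$score))
  keep <- !is.na(gr$score)
  rtracklayer::export(gr[keep], path, format = "bedGraph")
  invisible(path)
}

#' @rdname readBedGraph
#' @export
writeBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write / read a WindowExperiment as TSV with a JSON sidecar
#'
#' The TSV holds one row per window (chrom, 0-based start/end, window_id,
#' all rowData score columns, then one column per assay and sample named
#' `<assay>.<sample>`); column metadata travel in `<path>.json`. A
#' write-then-read round trip reproduces the table exactly.
#'
#' @param we A [WindowExperiment].
#' @param path Output TSV path.
#' @return `writeWindowTable()`: `path` invisibly; `readWindowTable()`:
#'   a `data.frame`.
#' @export
writeWindowTable <- function(we, path) {
  gr <- SummarizedExperiment::rowRanges(we)
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   window_id = mcols(gr)$window_id,
                   check.names = FALSE)
  rd <- SummarizedExperiment::rowData(we)
  rd <- rd[, setdiff(colnames(rd), "window_id"), drop = FALSE]
  for (nm in colnames(rd)) df[[nm]] <- rd[[nm]]
  meta <- list(columns = colnames(df), assays = list())
  for (an in SummarizedExperiment::assayNames(we)) {
    a <- SummarizedExperiment::assay(we, an)
    for (sn in colnames(a)) {
      cn <- paste(an, sn, sep = ".")
      df[[cn]] <- a[, sn]
      meta$assays[[cn]] <- list(assay = an, sample = sn)
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeWindowTable
#' @export
readWindowTable <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
}
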