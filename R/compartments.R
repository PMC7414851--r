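#' Knight-Ruiz balancing of a symmetric contact matrix
#'
#' Finds a positive scaling vector `x` such that the balanced matrix
#' `B = diag(x) %*% M %*% diag(x)` has equal row sums (equal to 1), using
#' the Knight-Ruiz inner-outer Newton iteration with a conjugate-gradient
#' inner solve. Masked (sparse or all-zero) bins are excluded before
#' balancing and carry `NA` in the result. If the iteration fails to
#' converge within `maxIter` outer steps the function falls back to
#' square-root coverage normalization (`x = 1/sqrt(rowSums)`) with a
#' warning.
#'
#' @param cm A [ContactMatrix] (or a plain symmetric matrix, in which case
#'   all-zero rows are masked).
#' @param tol Convergence tolerance on the residual `max |x * (Mx) - 1|`.
#' @param maxIter Maximum outer iterations.
#' @return A list: `x` (scaling vector, `NA` on masked bins), `balanced`
#'   (full-size matrix, `NA` rows/cols on masked bins), `converged`,
#'   `mask`.
#' @examples
#' krBalance(ContactMatrix(matrix(c(2, 2, 2, 2), 2)))$balanced
#' @export
krBalance <- function(cm, tol = 1e-12, maxIter = 100) {
  if (methods::is(cm, "ContactMatrix")) {
    M <- contactCounts(cm); mask <- binMask(cm)
  } else {
    M <- as.matrix(cm); mask <- rowSums(M) > 0
  }
  nFull <- nrow(M)
  A <- M[mask, mask, drop = FALSE]
  n <- nrow(A)
  if (n < 2L) stop("fewer than 2 retained bins")

  x <- .krCore(A, tol = tol, maxIter = maxIter)
  converged <- !is.null(x)
  if (!converged) {
    warning("KR balancing did not converge; ",
            "falling back to sqrt coverage normalization")
    x <- 1 / sqrt(rowSums(A))
  }
  B <- A * tcrossprod(x)
  xFull <- rep(NA_real_, nFull); xFull[mask] <- x
  BFull <- matrix(NA_real_, nFull, nFull)
  BFull[mask, mask] <- B
  list(x = xFull, balanced = BFull, converged = converged, mask = mask)
}

# Knight & Ruiz (2013)-style balancing: outer Newton steps on
# f(x) = x * (A x) - e, inner CG on the Jacobian, with the step clamped to
# the box [delta, Delta] for stability. Returns NULL on non-convergence.
.krCore <- function(A, tol = 1e-12, maxIter = 100,
                    delta = 0.1, Delta = 3) {
  n <- nrow(A)
  e <- rep(1, n)
  x <- e
  g <- 0.9; etamax <- 0.1
  eta <- etamax
  stopTol <- tol * 0.5
  rt <- tol^2
  v <- x * drop(A %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1; rold <- rout
  it <- 0
  while (rout > rt) {
    it <- it + 1
    if (it > maxIter) return(NULL)
    k <- 0; y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- rho_km1
    Z <- p <- w <- NULL
    while (rho_km1 > innertol) {
      k <- k + 1
      if (k == 1) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      if (k > 200) break
      w <- x * drop(A %*% (x * p)) + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        ind <- ap < 0
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- ynew > Delta
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
    }
    x <- x * y
    v <- x * drop(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    # Ratio-based forcing-term update for the inexact Newton step
    rat <- rout / rold; rold <- rout
    resNorm <- sqrt(rout)
    eta_o <- eta
    eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), stopTol / resNorm)
  }
  if (max(abs(x * drop(A %*% x) - 1)) > sqrt(tol) * 10) return(NULL)
  x
}

#' Observed/expected normalization of a balanced matrix
#'
#' Divides each entry by the mean balanced signal over all retained pairs
#' at the same genomic distance `|i - j|` on the chromosome, removing the
#' distance decay so that compartment structure dominates the correlation
#' analysis. Distances with no retained pair are `NA`.
#'
#' @param B Balanced matrix (full size, `NA` on masked bins), e.g.
#'   `krBalance(cm)$balanced`.
#' @param mask Logical retained-bin mask; defaults to rows that are not
#'   all-`NA`.
#' @return O/E matrix, `NA` on masked rows/columns.
#' @export
observedOverExpected <- function(B, mask = NULL) {
  n <- nrow(B)
  if (is.null(mask)) mask <- !apply(B, 1, function(r) all(is.na(r)))
  idx <- which(mask)
  if (length(idx) < 2L) stop("fewer than 2 retained bins")
  sub <- B[idx, idx, drop = FALSE]
  d <- abs(outer(idx, idx, "-"))
  expected <- tapply(as.vector(sub), as.vector(d), mean, na.rm = TRUE)
  E <- matrix(expected[as.character(d)], nrow(sub), ncol(sub))
  OE <- sub / E
  out <- matrix(NA_real_, n, n)
  out[idx, idx] <- OE
  out
}

#' Pearson correlation matrix of O/E rows
#'
#' `P[i, j]` is the Pearson correlation of O/E rows i and j over retained
#' columns. Bins whose O/E row has zero variance are masked with a
#' warning; the diagonal is exactly 1.
#'
#' @param OE O/E matrix from [observedOverExpected()].
#' @param mask Logical retained-bin mask (default: non-all-`NA` rows).
#' @return A list: `P` (full-size correlation matrix, `NA` on masked
#'   bins), `mask` (possibly further reduced).
#' @export
pearsonMatrix <- function(OE, mask = NULL) {
  n <- nrow(OE)
  if (is.null(mask)) mask <- !apply(OE, 1, function(r) all(is.na(r)))
  idx <- which(mask)
  if (length(idx) < 3L) stop("need >= 3 retained bins")
  sub <- OE[idx, idx, drop = FALSE]
  vr <- apply(sub, 1, stats::var, na.rm = TRUE)
  zv <- !is.na(vr) & vr == 0
  if (any(zv)) {
    warning(sum(zv), " zero-variance bin(s) masked in pearsonMatrix")
    keep <- !zv
    idx <- idx[keep]
    sub <- sub[keep, keep, drop = FALSE]
    mask[setdiff(which(mask), idx)] <- FALSE
  }
  Psub <- suppressWarnings(stats::cor(t(sub), use = "pairwise.complete.obs"))
  diag(Psub) <- 1
  P <- matrix(NA_real_, n, n)
  P[idx, idx] <- Psub
  list(P = P, mask = mask)
}

#' First principal component of the Pearson matrix
#'
#' The unoriented compartment eigenvector: the eigenvector (unit norm) of
#' the column-centered covariance of P with the largest eigenvalue,
#' computed per chromosome. The sign before orientation is fixed
#' deterministically by making the largest-magnitude loading positive.
#' When the top two eigenvalues are within `degenerateTol` (relative) a
#' warning flags the degenerate spectrum; the fixed ordering of `eigen()`
#' keeps the choice deterministic.
#'
#' @param P Pearson matrix from [pearsonMatrix()].
#' @param mask Logical retained-bin mask (default: non-all-`NA` rows).
#' @param degenerateTol Relative gap below which the spectrum is flagged.
#' @return Numeric eigenvector, `NA` on masked bins, with attributes
#'   `"eigenvalueShare"` (top eigenvalue / total) and `"degenerate"`.
#' @export
compartmentEigenvector <- function(P, mask = NULL, degenerateTol = 1e-6) {
  n <- nrow(P)
  if (is.null(mask)) mask <- !apply(P, 1, function(r) all(is.na(r)))
  idx <- which(mask)
  sub <- P[idx, idx, drop = FALSE]
  if (any(is.na(sub))) sub[is.na(sub)] <- 0
  C <- stats::cov(sub)            # covariance of columns of P
  es <- eigen(C, symmetric = TRUE)
  vals <- pmax(es$values, 0)
  share <- if (sum(vals) > 0) vals[1] / sum(vals) else 0
  degenerate <- length(vals) > 1 &&
    (vals[1] - vals[2]) <= degenerateTol * max(vals[1], .Machine$double.eps)
  if (degenerate)
    warning("degenerate spectrum: top two eigenvalues nearly equal; ",
            "using fixed eigen() ordering")
  v <- es$vectors[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v   # deterministic pre-orientation
  out <- rep(NA_real_, n)
  out[idx] <- v
  structure(out, eigenvalueShare = share, degenerate = degenerate)
}

#' Orient a compartment eigenvector against a reference track
#'
#' Flips the eigenvector sign iff its Pearson correlation with the
#' reference (typically RT, since the A compartment replicates early) is
#' negative, so that positive values mean A. When `|corr| < 0.05` the
#' orientation is ambiguous: the vector is returned unchanged with
#' attribute `"orientation" = "ambiguous"` and a warning.
#'
#' @param ev Eigenvector (NA on masked bins).
#' @param reference Per-bin reference values, e.g. window-mean RT.
#' @return The oriented eigenvector with attributes `"orientation"` and
#'   `"referenceCorrelation"`.
#' @export
orientEigenvector <- function(ev, reference) {
  stopifnot(length(ev) == length(reference))
  ok <- !is.na(ev) & !is.na(reference)
  if (sum(ok) < 10L) stop("reference defined on fewer than 10 retained bins")
  r <- stats::cor(ev[ok], reference[ok])
  orientation <- "reference"
  out <- ev
  if (abs(r) < 0.05) {
    warning("ambiguous orientation: |corr(ev, reference)| < 0.05; unchanged")
    orientation <- "ambiguous"
  } else if (r < 0) {
    out <- -ev
    r <- -r
  }
  attributes(out) <- attributes(ev)
  structure(out, orientation = orientation, referenceCorrelation = r)
}

#' Full compartment pipeline for one chromosome
#'
#' Chains [krBalance()], [observedOverExpected()], [pearsonMatrix()],
#' [compartmentEigenvector()] and, when a reference is given,
#' [orientEigenvector()].
#'
#' @param cm A [ContactMatrix].
#' @param reference Optional per-bin orientation reference (e.g. RT).
#' @param tol KR convergence tolerance.
#' @return A list: `eigenvector` (oriented if a reference was given),
#'   `balanced`, `oe`, `pearson`, `mask`, `eigenvalueShare`.
#' @export
compartmentPipeline <- function(cm, reference = NULL, tol = 1e-12) {
  kb <- krBalance(cm, tol = tol)
  oe <- observedOverExpected(kb$balanced, kb$mask)
  pm <- pearsonMatrix(oe, kb$mask)
  ev <- compartmentEigenvector(pm$P, pm$mask)
  if (!is.null(reference)) ev <- orientEigenvector(ev, reference)
  list(eigenvector = ev, balanced = kb$balanced, oe = oe, pearson = pm$P,
       mask = pm$mask,
       eigenvalueShare = attr(ev, "eigenvalueShare"))
}

#' Read / write contact matrices as plain text
#'
#' Dense format: whitespace-delimited numeric matrix, one row per bin.
#' Sparse format: 3-column TSV `bin_i  bin_j  count` with 0-based bin
#' indices; symmetry is completed on read.
#'
#' @param path File path.
#' @param format `"dense"` or `"sparse"`.
#' @param nBins Number of bins (required for sparse input).
#' @param chrom,binWidth Passed to [ContactMatrix()].
#' @return A [ContactMatrix].
#' @export
readContactMatrix <- function(path, format = c("dense", "sparse"),
                              nBins = NULL, chrom = "chr1",
                              binWidth = 50000) {
  format <- match.arg(format)
  if (format == "dense") {
    M <- as.matrix(utils::read.table(path, header = FALSE))
    dimnames(M) <- NULL
  } else {
    df <- utils::read.table(path, header = FALSE,
                            col.names = c("i", "j", "count"))
    if (is.null(nBins)) nBins <- max(df$i, df$j) + 1L
    M <- matrix(0, nBins, nBins)
    M[cbind(df$i + 1L, df$j + 1L)] <- df$count
    M[cbind(df$j + 1L, df$i + 1L)] <- df$count
  }
  ContactMatrix(M, chrom = chrom, binWidth = binWidth)
}

#' @rdname readContactMatrix
#' @param cm A [ContactMatrix] to write (dense whitespace text).
#' @export
writeContactMatrix <- function(cm, path) {
  utils::write.table(contactCounts(cm), path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an eigenvector as bedGraph on a window grid
#'
#' @param ev Per-bin eigenvector values (NA bins skipped).
#' @param grid Window grid from [makeWindows()] aligned with the bins.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeEigenvectorTrack <- function(ev, grid, path) {
  stopifnot(length(ev) == length(grid))
  gr <- grid
  S4Vectors::mcols(gr)$score <- as.numeric(ev)
  writeBedGraph(gr, path)
}
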