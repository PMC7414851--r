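# Shared fixtures, all generated in code.

# default synthetic genome used across tests (10 Mb, 50-kb windows, seed 1)
defaultGenome <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulateGenome(simGenomeConfig(seed = 1))
    cache
  }
})

# a small PLA field: few nuclei in a compact frame, quick to segment
smallPlaField <- function(seed = 3, nNuclei = 9, lambda = c(one = 4),
                          shape = c(270, 270)) {
  cfg <- simPlaConfig(nNuclei = nNuclei, lambda = lambda,
                      imageShape = shape, seed = seed)
  simulatePlaImages(cfg)[[1]]
}

# match segmented nuclei back to ground-truth nuclei by nearest centroid
matchNuclei <- function(truth, table) {
  stopifnot(nrow(table) == nrow(truth$centers))
  vapply(seq_len(nrow(truth$centers)), function(i) {
    d <- (table$y - truth$centers[i, 1])^2 + (table$x - truth$centers[i, 2])^2
    which.min(d)
  }, integer(1))
}

# base-resolution oracle for window means: assign each base the value of
# its covering interval, then average covered bases per window
baseMeanOracle <- function(starts0, ends0, values, width, chromLen) {
  base <- rep(NA_real_, chromLen)
  for (i in seq_along(values)) base[(starts0[i] + 1):ends0[i]] <- values[i]
  nWin <- floor(chromLen / width)
  vapply(seq_len(nWin), function(w) {
    seg <- base[((w - 1) * width + 1):(w * width)]
    if (all(is.na(seg))) NA_real_ else mean(seg, na.rm = TRUE)
  }, numeric(1))
}

# brute-force per-diagonal O/E oracle
oeOracle <- function(B) {
  n <- nrow(B)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- abs(i - j)
    vals <- c()
    for (a in seq_len(n)) for (b in seq_len(n))
      if (abs(a - b) == d) vals <- c(vals, B[a, b])
    out[i, j] <- B[i, j] / mean(vals)
  }
  out
}

# exhaustive Mann-Whitney U null distribution by enumerating all
# C(n+m, n) rank assignments (independent of the package's recursion)
uEnumOracle <- function(n, m) {
  N <- n + m
  combos <- utils::combn(N, n)
  u <- apply(combos, 2, function(ix) sum(ix) - n * (n + 1) / 2)
  tabulate(u + 1, nbins = n * m + 1)
}
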