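#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the Mersenne-Twister stream seeded at `seed`, then
#' restores the caller's RNG state, so seeded generators never perturb
#' (and are never perturbed by) surrounding code.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a parent seed and a tag
#'
#' Sub-generators draw their own deterministic seed from the config's
#' global seed plus a stage tag, so adding a generator to a pipeline never
#' perturbs the streams of existing ones. The result is always a valid
#' 32-bit R integer seed.
#'
#' @param seed Parent integer seed.
#' @param tag Character stage label.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
childSeed <- function(seed, tag) {
  stopifnot(is.character(tag), length(tag) == 1L)
  m <- 2147483647  # 2^31 - 1, prime
  h <- (as.numeric(seed) %% m)
  for (code in utf8ToInt(tag)) h <- (h * 131 + code) %% m
  as.integer(h)
}

# shared numeric formatter for deterministic text outputs
.fmtNum <- function(x) formatC(x, digits = 12, format = "g")
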