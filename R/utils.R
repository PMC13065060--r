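#' @useDynLib spffunet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif fft sd
#' @importFrom utils modifyList
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# The seed is scrambled first: adjacent Mersenne-Twister seeds produce
# overlapping sample() streams in base R (seeds 0 and 1 draw identical
# 8-of-12 subsets), which would correlate consecutive scan/train seeds.
with_seed_ <- function(seed, expr) {
  seed <- as.integer((as.numeric(seed) * 2654435761) %% 2147483647)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
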