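#' @importFrom data.table data.table := setkey setkeyv as.data.table fread fwrite
#' @importFrom stats fft ks.test mad median quantile rexp rgamma rnorm rpois runif
#'   cor cor.test kmeans rbinom sd
#' @importFrom utils head tail
#' @useDynLib cohesim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Deterministic child seed for an independent RNG stream. Keeps results
# reproducible per output (Hi-C, 4C, expression) from one root seed.
child_seed <- function(seed, stream, extra = 0L) {
  s <- (as.numeric(seed) * 7919 + as.numeric(stream) * 104729 +
          as.numeric(extra) %% 1e6 * 131) %% 2147483647
  as.integer(s) + 1L
}

# Evaluate `code` under a temporary RNG seed, restoring caller state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# bp position -> 1-based bin index
pos_to_bin <- function(pos, bin_size) pmin(floor(pos / bin_size), .Machine$integer.max) + 1L
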