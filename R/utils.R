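#' @keywords internal
"_PACKAGE"

## Run code under a fixed RNG state without disturbing the caller's stream.
## All exported stochastic functions take an explicit `seed`; NULL means
## "use the current RNG state".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## Named sub-seeds derived from one root seed, so independent stages
## (background sampling, permutations, generator) get distinct streams.
## Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  offs <- c(background = 101L, permutation = 211L, similarity = 307L,
            solver = 401L, generator = 503L, species = 601L, block = 701L)
  off <- if (stream %in% names(offs)) offs[[stream]] else
    sum(utf8ToInt(stream)) %% 1000L
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
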