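#' @keywords internal
"_PACKAGE"

## Deterministic RNG scoping. All stochastic operations in the package run
## inside with_seed() so that (a) results are reproducible from an integer
## seed across platforms and R versions, and (b) the caller's .Random.seed
## is never disturbed. RNG algorithms are pinned explicitly because R's
## defaults for sample() changed at 3.6.0.

with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  old_kind <- RNGkind()
  on.exit({
    do.call(RNGkind, as.list(old_kind))
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }, add = TRUE)
  RNGkind(kind = "Mersenne-Twister", normal.kind = "Inversion",
          sample.kind = "Rejection")
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

## Stable 31-bit string hash (polynomial rolling hash; all intermediate
## values stay below 2^53 so double arithmetic is exact).
string_hash <- function(x) {
  m <- 2147483647  # 2^31 - 1
  h <- 0
  for (c in utf8ToInt(x)) h <- (h * 131 + c) %% m
  h
}

#' Derive a named RNG stream seed
#'
#' Each projection (and each position sampler) draws from its own stream so
#' that adding or deleting one projection never perturbs the realized
#' connectivity of the others. The stream seed is a deterministic function
#' of the master seed and the stream name.
#'
#' @param master_seed integer master seed.
#' @param name character stream label (e.g. a projection name).
#' @return an integer seed in [0, 2^31).
#' @export
derive_seed <- function(master_seed, name) {
  m <- 2147483647
  h <- string_hash(name)
  s <- (as.numeric(master_seed) %% m) * 48271 %% m
  as.integer((s + h * 69621) %% m)
}
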