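## Value distributions for synapse parameters (weights, delays) and for
## position templates. Gaussian, uniform and constant are built in; further
## kinds can be registered at run time by name.

.dist_registry <- new.env(parent = emptyenv())

#' Register a value-distribution kind
#'
#' The distribution registry is extensible: a new kind is defined by a
#' sampler `function(n, params)` returning `n` numeric draws from the
#' current RNG stream, and an optional validator for its parameter list.
#'
#' @param kind character name of the distribution kind.
#' @param sampler function of `(n, params)` returning `n` numeric draws.
#' @param validator optional function of `(params)` that errors on invalid
#'   parameters.
#' @export
register_distribution <- function(kind, sampler, validator = NULL) {
  stopifnot(is.character(kind), nzchar(kind), is.function(sampler))
  assign(kind, list(sampler = sampler, validator = validator),
         envir = .dist_registry)
  invisible(kind)
}

register_builtin_distributions <- function() {
  register_distribution(
    "constant",
    sampler = function(n, p) rep(p$value, n),
    validator = function(p) {
      stopifnot(is.numeric(p$value), length(p$value) == 1L, is.finite(p$value))
    })
  register_distribution(
    "gaussian",
    sampler = function(n, p) stats::rnorm(n, mean = p$mean, sd = p$stdev),
    validator = function(p) {
      stopifnot(is.numeric(p$mean), is.numeric(p$stdev), p$stdev >= 0)
    })
  register_distribution(
    "uniform",
    sampler = function(n, p) stats::runif(n, min = p$min, max = p$max),
    validator = function(p) {
      stopifnot(is.numeric(p$min), is.numeric(p$max), p$min <= p$max)
    })
}

#' Value distributions
#'
#' Constructors for the distribution objects used for synapse weights,
#' delays and position templates. `dist_constant(v)` repeats a fixed value,
#' `dist_gaussian(mean, stdev)` draws normal deviates and
#' `dist_uniform(min, max)` draws uniformly. Units are contextual: weights
#' are in simulator-defined model units, delays in milliseconds, positions
#' in micrometres.
#'
#' @param value,mean,stdev,min,max numeric distribution parameters.
#' @param kind registered kind name (for `distribution()`).
#' @param params named list of parameters (for `distribution()`).
#' @return an object of class `csa_distribution`.
#' @export
distribution <- function(kind, params) {
  if (!exists(kind, envir = .dist_registry)) {
    stop("unregistered distribution kind: '", kind, "'", call. = FALSE)
  }
  entry <- get(kind, envir = .dist_registry)
  if (!is.null(entry$validator)) entry$validator(params)
  structure(list(kind = kind, params = params), class = "csa_distribution")
}

#' @rdname distribution
#' @export
dist_constant <- function(value) distribution("constant", list(value = value))

#' @rdname distribution
#' @export
dist_gaussian <- function(mean, stdev) {
  distribution("gaussian", list(mean = mean, stdev = stdev))
}

#' @rdname distribution
#' @export
dist_uniform <- function(min, max) {
  distribution("uniform", list(min = min, max = max))
}

#' Sample from a value distribution
#'
#' Draws `count` values. With `seed` given the draws are deterministic and
#' the caller's RNG state is untouched; with `seed = NULL` the draws come
#' from the current RNG stream (used internally so each projection consumes
#' its own stream in enumeration order).
#'
#' @param d a `csa_distribution`.
#' @param count number of draws (>= 0).
#' @param seed optional integer seed.
#' @return numeric vector of length `count`.
#' @export
sample_distribution <- function(d, count, seed = NULL) {
  stopifnot(inherits(d, "csa_distribution"), count >= 0)
  if (!exists(d$kind, envir = .dist_registry)) {
    stop("unregistered distribution kind: '", d$kind, "'", call. = FALSE)
  }
  sampler <- get(d$kind, envir = .dist_registry)$sampler
  if (count == 0) return(numeric(0))
  if (is.null(seed)) sampler(count, d$params)
  else with_seed(seed, sampler(count, d$params))
}

#' @export
format.csa_distribution <- function(x, ...) {
  ps <- paste(names(x$params), vapply(x$params, format, ""), sep = "=",
              collapse = ", ")
  sprintf("%s(%s)", x$kind, ps)
}

#' @export
print.csa_distribution <- function(x, ...) {
  cat("<distribution ", format(x), ">\n", sep = "")
  invisible(x)
}
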