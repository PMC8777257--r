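## Connectivity patterns and their expansion into masks (sets of index
## pairs), the computational core of the package. Each declarative pattern
## maps to an enumerable connection-set-algebra style mask:
##
##   all_to_all               full Cartesian product
##   one_to_one               the finite diagonal
##   fixed_probability        independent Bernoulli(p) per ordered pair
##   per_cell_connection      fixed fan-in: n distinct sources per target
##   gaussian_connectivity_2d Bernoulli with p = exp(-d^2 / (2 sigma^2))
##   atlas                    connectome matrices (expanded in the generator)
##
## Masks use 0-based indices (i, j), 0 <= i < N_s, 0 <= j < N_t, and are
## enumerated target-major (all pairs for target 0 first). Random kinds
## consume one primitive uniform draw per candidate pair (or one sampling
## call per target for fan-in) in exactly that order, so realizations are
## reproducible and testable against brute-force membership oracles.

pattern_kinds <- c("all_to_all", "one_to_one", "fixed_probability",
                   "per_cell", "gaussian_2d", "atlas")

new_pattern <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "csa_pattern")
}

#' Connectivity patterns
#'
#' Constructors for the declarative connectivity patterns a projection can
#' carry. Parameters are validated at construction time.
#'
#' * `conn_all_to_all()`: every (source, target) pair.
#' * `conn_one_to_one()`: pair `i -> i` for `i < min(N_s, N_t)`.
#' * `conn_fixed_probability(p)`: each ordered pair independently with
#'   probability `p` (pairwise Bernoulli).
#' * `conn_per_cell(n)`: fixed fan-in; every target receives exactly `n`
#'   sources, drawn without replacement unless `multapses = TRUE`.
#' * `conn_gaussian_2d(sigma)`: distance-dependent Bernoulli with
#'   acceptance probability `exp(-d^2 / (2 sigma^2))`, `d` the 2D Euclidean
#'   distance in micrometres between the neurons' positions.
#' * `conn_atlas(file, conduction_speed)`: region-to-region connectivity
#'   read from a connectome-atlas archive (weights + tract lengths);
#'   expanded by [expand_atlas_projection()].
#'
#' @param p connection probability in `[0, 1]`.
#' @param n positive integer fan-in (or fan-out).
#' @param direction `"pre_to_post"` (fan-in, default) or `"post_to_pre"`
#'   (fan-out extension).
#' @param multapses logical; allow duplicate pairs per target.
#' @param sigma positive Gaussian kernel width in micrometres.
#' @param allow_autapses logical; keep the diagonal when source == target.
#' @param file path to the atlas zip archive.
#' @param conduction_speed conduction speed in mm/ms used to turn tract
#'   lengths into delays.
#' @return an object of class `csa_pattern`.
#' @export
conn_all_to_all <- function(allow_autapses = TRUE) {
  new_pattern("all_to_all", allow_autapses = isTRUE(allow_autapses))
}

#' @rdname conn_all_to_all
#' @export
conn_one_to_one <- function() new_pattern("one_to_one")

#' @rdname conn_all_to_all
#' @export
conn_fixed_probability <- function(p, allow_autapses = TRUE) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  new_pattern("fixed_probability", p = p, allow_autapses = isTRUE(allow_autapses))
}

#' @rdname conn_all_to_all
#' @export
conn_per_cell <- function(n, direction = c("pre_to_post", "post_to_pre"),
                          multapses = FALSE, allow_autapses = TRUE) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1, n == round(n))
  direction <- match.arg(direction)
  new_pattern("per_cell", n = as.integer(n), direction = direction,
              multapses = isTRUE(multapses), allow_autapses = isTRUE(allow_autapses))
}

#' @rdname conn_all_to_all
#' @export
conn_gaussian_2d <- function(sigma) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L)
  if (!is.finite(sigma) || sigma <= 0) {
    stop("gaussian_2d requires sigma > 0", call. = FALSE)
  }
  new_pattern("gaussian_2d", sigma = sigma)
}

#' @rdname conn_all_to_all
#' @export
conn_atlas <- function(file, conduction_speed = 1) {
  stopifnot(is.character(file), length(file) == 1L,
            is.numeric(conduction_speed), conduction_speed > 0)
  new_pattern("atlas", file = file, conduction_speed = conduction_speed)
}

#' @export
format.csa_pattern <- function(x, ...) {
  extra <- switch(x$kind,
    fixed_probability = sprintf(" p=%g", x$p),
    per_cell = sprintf(" n=%d %s", x$n, x$direction),
    gaussian_2d = sprintf(" sigma=%g", x$sigma),
    atlas = sprintf(" file=%s", x$file),
    "")
  sprintf("<pattern %s%s>", x$kind, extra)
}

#' @export
print.csa_pattern <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Gaussian spatial connection kernel
#'
#' Probability of connection between two neurons a planar distance `d`
#' apart: `exp(-d^2 / (2 sigma^2))`. Monotone non-increasing in `d`, equal
#' to 1 at `d = 0`.
#'
#' @param d non-negative distance(s) in micrometres.
#' @param sigma positive kernel width in micrometres.
#' @return connection probability/-ies in `(0, 1]`.
#' @export
gaussian_kernel <- function(d, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("gaussian_kernel requires sigma > 0", call. = FALSE)
  }
  stopifnot(is.numeric(d), all(d >= 0))
  exp(-d^2 / (2 * sigma^2))
}

## Pairwise 2D Euclidean distances for one target column j: positions are
## n x 2 (or n x 3; only x,y enter the planar kernel) matrices.
pair_distances <- function(pos_s, pos_t_row) {
  dx <- pos_s[, 1] - pos_t_row[1]
  dy <- pos_s[, 2] - pos_t_row[2]
  sqrt(dx * dx + dy * dy)
}

#' Enumerate the mask of a connectivity pattern
#'
#' Expands a pattern into its explicit, deterministically ordered set of
#' 0-based index pairs. Pairs are enumerated target-major: all sources for
#' target 0, then target 1, and so on. Random patterns are fully
#' reproducible given `seed`.
#'
#' @param pattern a `csa_pattern` (atlas patterns are expanded by
#'   [expand_atlas_projection()], not here).
#' @param n_source,n_target population sizes (>= 1).
#' @param positions optional list with elements `source` and `target`, each
#'   an `n x 2` (or `n x 3`) coordinate matrix in micrometres; required for
#'   `gaussian_2d`.
#' @param seed integer seed for the pattern's RNG stream.
#' @return a data.frame with integer columns `i` (source) and `j` (target).
#' @export
enumerate_mask <- function(pattern, n_source, n_target, positions = NULL,
                           seed = 0L) {
  stopifnot(inherits(pattern, "csa_pattern"),
            n_source >= 1, n_target >= 1)
  n_source <- as.integer(n_source)
  n_target <- as.integer(n_target)
  same_pop <- identical(n_source, n_target)
  drop_diag <- function(df) {
    if (isFALSE(pattern$allow_autapses) && same_pop) {
      df[df$i != df$j, , drop = FALSE]
    } else df
  }
  out <- switch(pattern$kind,
    all_to_all = {
      df <- data.frame(i = rep(0:(n_source - 1L), times = n_target),
                       j = rep(0:(n_target - 1L), each = n_source))
      drop_diag(df)
    },
    one_to_one = {
      k <- min(n_source, n_target)
      data.frame(i = 0:(k - 1L), j = 0:(k - 1L))
    },
    fixed_probability = {
      df <- with_seed(seed, {
        u <- stats::runif(n_source * n_target)
        keep <- u < pattern$p
        data.frame(i = rep(0:(n_source - 1L), times = n_target)[keep],
                   j = rep(0:(n_target - 1L), each = n_source)[keep])
      })
      drop_diag(df)
    },
    per_cell = {
      if (pattern$direction == "post_to_pre") {
        ## fan-out: reuse fan-in machinery with roles swapped
        flipped <- pattern
        flipped$direction <- "pre_to_post"
        m <- enumerate_mask(flipped, n_target, n_source, positions = NULL,
                            seed = seed)
        df <- data.frame(i = m$j, j = m$i)
        df <- df[order(df$j, seq_len(nrow(df))), , drop = FALSE]
        rownames(df) <- NULL
        return(df)
      }
      n <- pattern$n
      pool_size <- if (isFALSE(pattern$allow_autapses) && same_pop) {
        n_source - 1L
      } else n_source
      if (!pattern$multapses && n > pool_size) {
        stop("per_cell fan-in n = ", n, " exceeds available sources (",
             pool_size, ") without multapses", call. = FALSE)
      }
      with_seed(seed, {
        src <- integer(n * n_target)
        for (j in seq_len(n_target)) {
          pool <- 0:(n_source - 1L)
          if (isFALSE(pattern$allow_autapses) && same_pop) {
            pool <- pool[pool != (j - 1L)]
          }
          s <- if (pattern$multapses) {
            pool[sample.int(length(pool), n, replace = TRUE)]
          } else {
            pool[sample.int(length(pool), n)]
          }
          src[((j - 1L) * n + 1L):(j * n)] <- s
        }
        data.frame(i = src, j = rep(0:(n_target - 1L), each = n))
      })
    },
    gaussian_2d = {
      if (is.null(positions) || is.null(positions$source) ||
          is.null(positions$target)) {
        stop("gaussian_2d requires positions for both endpoints",
             call. = FALSE)
      }
      pos_s <- as.matrix(positions$source)
      pos_t <- as.matrix(positions$target)
      stopifnot(nrow(pos_s) == n_source, nrow(pos_t) == n_target)
      df <- with_seed(seed, {
        keep_i <- vector("list", n_target)
        for (j in seq_len(n_target)) {
          d <- pair_distances(pos_s, pos_t[j, ])
          p <- gaussian_kernel(d, pattern$sigma)
          u <- stats::runif(n_source)
          keep_i[[j]] <- which(u < p) - 1L
        }
        data.frame(i = unlist(keep_i),
                   j = rep(0:(n_target - 1L), times = lengths(keep_i)))
      })
      drop_diag(df)
    },
    atlas = stop("atlas patterns are expanded by expand_atlas_projection()",
                 call. = FALSE),
    stop("unknown pattern kind: ", pattern$kind, call. = FALSE)
  )
  rownames(out) <- NULL
  out
}

#' Analytic expected connection count of a pattern
#'
#' Deterministic, RNG-free expectation of the number of realized
#' connections; used for cross-level aggregation of connectivity so that
#' aggregated edge strengths do not depend on a particular realization.
#'
#' @inheritParams enumerate_mask
#' @return a single non-negative number; `NA` for `gaussian_2d` without
#'   positions (flagged not computable).
#' @export
expected_connection_count <- function(pattern, n_source, n_target,
                                      positions = NULL) {
  stopifnot(inherits(pattern, "csa_pattern"), n_source >= 1, n_target >= 1)
  same_pop <- n_source == n_target
  diag_excluded <- isFALSE(pattern$allow_autapses) && same_pop
  switch(pattern$kind,
    all_to_all = n_source * n_target - if (diag_excluded) n_source else 0,
    one_to_one = min(n_source, n_target),
    fixed_probability =
      pattern$p * (n_source * n_target - if (diag_excluded) n_source else 0),
    per_cell = pattern$n * if (pattern$direction == "pre_to_post") n_target
               else n_source,
    gaussian_2d = {
      if (is.null(positions) || is.null(positions$source) ||
          is.null(positions$target)) return(NA_real_)
      pos_s <- as.matrix(positions$source)
      pos_t <- as.matrix(positions$target)
      tot <- 0
      for (j in seq_len(n_target)) {
        p <- gaussian_kernel(pair_distances(pos_s, pos_t[j, ]), pattern$sigma)
        if (diag_excluded) p[j] <- 0
        tot <- tot + sum(p)
      }
      tot
    },
    atlas = stop("expected count of an atlas pattern requires the loaded ",
                 "matrices; see expand_atlas_projection()", call. = FALSE)
  )
}

#' Fixed total connection count from a pairwise connection probability
#'
#' The cortical-microcircuit model derives a fixed total number of
#' connections `K` between a source population of size `N_m` and a target
#' population of size `N_n` from the pairwise connection probability `P`:
#'
#'   `K = ln(1 - P) / ln((N_n * N_m - 1) / (N_n * N_m))`
#'
#' rounded half-up to an integer. For small `P` this approaches
#' `P * N_n * N_m`. The package's generator instead realizes such
#' projections as pairwise Bernoulli draws (so realized counts fluctuate
#' around `P * N_n * N_m`); this function exposes the deterministic count
#' for users who need the fixed-total convention.
#'
#' @param P connection probability, `0 <= P < 1`.
#' @param N_n,N_m population sizes with `N_n * N_m >= 2`.
#' @return list with elements `K` (integer count), `P`, `N_n`, `N_m`.
#' @export
potjans_connection_count <- function(P, N_n, N_m) {
  stopifnot(is.numeric(P), length(P) == 1L, P >= 0,
            N_n >= 1, N_m >= 1, N_n * N_m >= 2)
  if (P >= 1) stop("P = 1 is outside the formula's domain (log of zero)",
                   call. = FALSE)
  K <- if (P == 0) 0L else {
    nm <- as.numeric(N_n) * as.numeric(N_m)
    ## log((nm-1)/nm) computed as log1p(-1/nm) for precision at large nm
    x <- log1p(-P) / log1p(-1 / nm)
    as.integer(floor(x + 0.5))
  }
  list(K = K, P = P, N_n = as.integer(N_n), N_m = as.integer(N_m))
}
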