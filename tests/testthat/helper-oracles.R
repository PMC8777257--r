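# Brute-force mask membership oracles, independent of enumerate_mask():
# each builds an N_s x N_t logical membership matrix by testing pair
# membership directly. Random kinds replay the engine's primitive draw
# sequence (one uniform per candidate pair in target-major order, or one
# sampling call per target) on top of the same seeded stream, but decide
# membership through the matrix rather than through the engine's code
# path.

oracle_membership <- function(pattern, n_s, n_t, positions = NULL,
                              seed = 0L) {
  m <- matrix(FALSE, n_s, n_t)
  same <- n_s == n_t
  no_aut <- !is.null(pattern$allow_autapses) && !pattern$allow_autapses
  switch(pattern$kind,
    all_to_all = {
      m[] <- TRUE
      if (no_aut && same) diag(m) <- FALSE
    },
    one_to_one = {
      for (k in seq_len(min(n_s, n_t))) m[k, k] <- TRUE
    },
    fixed_probability = {
      u <- csanet:::with_seed(seed, stats::runif(n_s * n_t))
      for (j in seq_len(n_t)) {
        for (i in seq_len(n_s)) {
          m[i, j] <- u[(j - 1) * n_s + i] < pattern$p
        }
      }
      if (no_aut && same) diag(m) <- FALSE
    },
    per_cell = {
      stopifnot(pattern$direction == "pre_to_post", !pattern$multapses)
      csanet:::with_seed(seed, {
        for (j in seq_len(n_t)) {
          pool <- seq_len(n_s)
          if (no_aut && same) pool <- pool[pool != j]
          chosen <- pool[sample.int(length(pool), pattern$n)]
          m[chosen, j] <- TRUE
        }
      })
    },
    gaussian_2d = {
      ps <- as.matrix(positions$source)
      pt <- as.matrix(positions$target)
      csanet:::with_seed(seed, {
        for (j in seq_len(n_t)) {
          u <- stats::runif(n_s)
          for (i in seq_len(n_s)) {
            d <- sqrt(sum((ps[i, 1:2] - pt[j, 1:2])^2))
            m[i, j] <- u[i] < exp(-d^2 / (2 * pattern$sigma^2))
          }
        }
      })
      if (no_aut && same) diag(m) <- FALSE
    },
    stop("oracle: unsupported kind ", pattern$kind)
  )
  m
}

# canonical sorted pair set for set-equality comparison
pair_set <- function(df) {
  df <- df[order(df$j, df$i), c("i", "j")]
  rownames(df) <- NULL
  df
}

membership_to_pairs <- function(m) {
  idx <- which(m)
  pair_set(data.frame(i = as.integer((idx - 1) %% nrow(m)),
                      j = as.integer((idx - 1) %/% nrow(m))))
}
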