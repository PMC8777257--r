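## Network instantiation and connection generation. A model is first
## instantiated (global neuron ids, sampled positions), then each
## projection is realized into an explicit connection list (pre_gid,
## post_gid, weight, delay). Each projection draws from its own RNG stream
## derived from (master seed, projection name), so adding or removing a
## projection never perturbs the realized connectivity of the others.

MIN_DELAY_MS <- 1e-3  # delays are clamped to stay positive (ms)

#' Instantiate a network: gid layout and neuron positions
#'
#' Assigns 0-based, contiguous, disjoint global id (gid) ranges to the leaf
#' populations in declaration order, covering `[0, total_neurons)`.
#' Devices (inputs, outputs, translators) occupy single ids in a separate
#' block directly above the neuron range and never consume neuron gids.
#' Position templates are sampled here, deterministically per
#' `(seed, population name)`.
#'
#' @param model a valid `network_model`.
#' @param seed master integer seed.
#' @return a `network_instance` with `gid_ranges` (data.frame `population`,
#'   `first`, `last`, half-open), `device_ids`, `positions` (named list of
#'   matrices) and `seed`.
#' @export
instantiate_network <- function(model, seed = 0L) {
  diags <- validate_model(model)
  if (any(diags$severity == "error")) {
    stop_csanet("csanet_validation_error",
                "cannot instantiate an invalid model:\n",
                paste0("  [", diags$entity, "] ", diags$message,
                       collapse = "\n"))
  }
  leaves <- leaf_populations(model)
  sizes <- vapply(leaves, function(n) model$entities[[n]]$size, 0L)
  last <- cumsum(sizes)
  first <- c(0L, last[-length(last)])
  gid_ranges <- data.frame(population = leaves,
                           first = as.integer(first),
                           last = as.integer(last),
                           row.names = NULL)
  total <- if (length(sizes)) sum(sizes) else 0L
  dn <- device_names(model)
  dev <- c(dn$inputs, dn$outputs, dn$translators)
  device_ids <- if (length(dev)) {
    stats::setNames(total + seq_along(dev) - 1L, dev)
  } else integer(0)

  positions <- list()
  for (nm in leaves) {
    spec <- model$entities[[nm]]$positions
    if (is.null(spec)) next
    positions[[nm]] <- if (spec$mode == "explicit") {
      spec$coordinates
    } else {
      n <- model$entities[[nm]]$size
      draws <- sample_distribution(spec$template, n * spec$dim,
                                   seed = derive_seed(seed, paste0("pos:", nm)))
      matrix(draws, nrow = n, ncol = spec$dim)
    }
  }
  structure(list(model = model, gid_ranges = gid_ranges,
                 device_ids = device_ids, positions = positions,
                 total_neurons = total, seed = seed),
            class = "network_instance")
}

endpoint_gid_info <- function(instance, ref) {
  gr <- instance$gid_ranges
  hit <- which(gr$population == ref)
  if (length(hit) == 1L) {
    list(kind = "population", offset = gr$first[hit],
         n = gr$last[hit] - gr$first[hit])
  } else if (ref %in% names(instance$device_ids)) {
    list(kind = "device", offset = instance$device_ids[[ref]], n = 1L)
  } else {
    stop_csanet("csanet_reference_error",
                "projection endpoint is not a leaf population or device: '",
                ref, "'", element = ref)
  }
}

empty_connections <- function() {
  data.frame(pre_gid = integer(0), post_gid = integer(0),
             weight = numeric(0), delay = numeric(0))
}

#' Realize one projection into an explicit connection list
#'
#' Enumerates the projection's mask, maps the 0-based pair indices into gid
#' space, and draws one weight and one delay per connection (in enumeration
#' order) from the projection's distributions. Everything is drawn from
#' streams derived from `(seed, projection name)`.
#'
#' @param instance a `network_instance`.
#' @param projection a projection list element of the instance's model, or
#'   a projection name.
#' @param seed master seed; defaults to the instance's.
#' @return data.frame with columns `pre_gid`, `post_gid`, `weight`,
#'   `delay` (ms, clamped positive).
#' @export
generate_projection <- function(instance, projection, seed = instance$seed) {
  stopifnot(inherits(instance, "network_instance"))
  projection <- resolve_projection(instance$model, projection)
  if (projection$pattern$kind == "atlas") {
    return(expand_atlas_projection(instance, projection))
  }
  src <- endpoint_gid_info(instance, projection$source)
  tgt <- endpoint_gid_info(instance, projection$target)
  positions <- NULL
  if (projection$pattern$kind == "gaussian_2d") {
    positions <- list(source = instance$positions[[projection$source]],
                      target = instance$positions[[projection$target]])
    if (is.null(positions$source) || is.null(positions$target)) {
      stop_csanet("csanet_validation_error",
                  "gaussian_2d projection '", projection$name,
                  "' requires positions on both endpoint populations",
                  element = projection$name)
    }
  }
  mask <- enumerate_mask(projection$pattern, src$n, tgt$n,
                         positions = positions,
                         seed = derive_seed(seed,
                                            paste0(projection$name, "#mask")))
  k <- nrow(mask)
  if (k == 0) return(empty_connections())
  w <- sample_distribution(projection$weight, k,
                           seed = derive_seed(seed,
                                              paste0(projection$name, "#w")))
  d <- sample_distribution(projection$delay, k,
                           seed = derive_seed(seed,
                                              paste0(projection$name, "#d")))
  data.frame(pre_gid = mask$i + src$offset,
             post_gid = mask$j + tgt$offset,
             weight = w,
             delay = pmax(d, MIN_DELAY_MS))
}

resolve_projection <- function(model, projection) {
  if (is.character(projection)) {
    nms <- vapply(model$projections, `[[`, "", "name")
    hit <- which(nms == projection)
    if (length(hit) != 1L) {
      stop_csanet("csanet_reference_error", "projection not found: '",
                  projection, "'", element = projection)
    }
    model$projections[[hit]]
  } else projection
}

#' Expand an atlas projection into region-to-region connections
#'
#' An atlas projection declared between the first and last indexed region
#' connects the whole family of sibling regions: every population in the
#' endpoint's parent group whose name carries a trailing `_{index}` is a
#' region. One connection is generated per ordered region pair `(r, s)`
#' with `weights[r, s] > 0`; its weight is the matrix entry and its delay
#' is `tract_lengths[r, s] / conduction_speed` (mm over mm/ms gives ms).
#' Proxy regions participate like any other region.
#'
#' @inheritParams generate_projection
#' @return data.frame as from [generate_projection()].
#' @export
expand_atlas_projection <- function(instance, projection) {
  projection <- resolve_projection(instance$model, projection)
  stopifnot(projection$pattern$kind == "atlas")
  model <- instance$model
  atlas <- load_atlas_pattern(projection$pattern)
  regions <- atlas_region_table(model, projection, atlas$n_regions)
  gid_of <- stats::setNames(
    vapply(regions$population,
           function(p) endpoint_gid_info(instance, p)$offset, 0L),
    as.character(regions$index))
  pos <- which(atlas$weights > 0, arr.ind = TRUE)
  known <- as.character(sort(regions$index))
  keep <- (as.character(pos[, 1] - 1L) %in% known) &
          (as.character(pos[, 2] - 1L) %in% known)
  pos <- pos[keep, , drop = FALSE]
  if (nrow(pos) == 0) return(empty_connections())
  ## enumeration order: target-major, matching mask convention
  ord <- order(pos[, 2], pos[, 1])
  pos <- pos[ord, , drop = FALSE]
  w <- atlas$weights[pos]
  d <- atlas$tract_lengths[pos] / atlas$conduction_speed
  data.frame(pre_gid = unname(gid_of[as.character(pos[, 1] - 1L)]),
             post_gid = unname(gid_of[as.character(pos[, 2] - 1L)]),
             weight = w,
             delay = pmax(d, MIN_DELAY_MS))
}

## the family of indexed sibling regions spanned by an atlas projection
atlas_region_table <- function(model, projection, n_regions) {
  for (ref in c(projection$source, projection$target)) {
    if (!has_trailing_index(ref)) {
      stop_csanet("csanet_validation_error",
                  "atlas endpoint '", ref, "' has no trailing _{index}",
                  element = projection$name)
    }
  }
  parent <- model$entities[[projection$source]]$parent
  family <- if (is.na(parent)) root_names(model)
            else model$entities[[parent]]$children
  family <- family[vapply(family, function(f) {
    model$entities[[f]]$type == "population" && has_trailing_index(f)
  }, TRUE)]
  idx <- vapply(family, trailing_index, 0L)
  bad <- idx[idx < 0 | idx >= n_regions]
  if (length(bad)) {
    stop_csanet("csanet_data_error",
                "region indices out of atlas range [0, ", n_regions, "): ",
                paste(bad, collapse = ", "), element = projection$name)
  }
  if (anyDuplicated(idx)) {
    stop_csanet("csanet_data_error", "duplicate region indices",
                element = projection$name)
  }
  data.frame(population = family, index = idx, row.names = NULL)
}

#' Stream a projection's connections in blocks
#'
#' Connection-generation-interface style access: the connections of one
#' projection are handed out in successive blocks of at most `block_size`
#' records whose concatenation equals [generate_projection()] exactly.
#' Returns a stateful iterator closure; `$next_block()` yields the next
#' block or `NULL` when exhausted.
#'
#' @inheritParams generate_projection
#' @param block_size maximum records per block (>= 1).
#' @return list with functions `next_block()` and `reset()`.
#' @export
stream_connections <- function(instance, projection, block_size,
                               seed = instance$seed) {
  stopifnot(block_size >= 1)
  full <- generate_projection(instance, projection, seed = seed)
  pos <- 0L
  list(
    next_block = function() {
      if (pos >= nrow(full)) return(NULL)
      take <- min(block_size, nrow(full) - pos)
      block <- full[(pos + 1L):(pos + take), , drop = FALSE]
      pos <<- pos + take
      rownames(block) <- NULL
      block
    },
    reset = function() {
      pos <<- 0L
      invisible(NULL)
    }
  )
}

#' Generate every projection of an instantiated network
#'
#' @param instance a `network_instance`.
#' @param seed master seed; defaults to the instance's.
#' @return named list of connection data.frames, one per projection.
#' @export
generate_network <- function(instance, seed = instance$seed) {
  conns <- lapply(instance$model$projections, function(pr) {
    generate_projection(instance, pr, seed = seed)
  })
  stats::setNames(conns,
                  vapply(instance$model$projections, `[[`, "", "name"))
}

#' Export connection lists and a manifest
#'
#' Writes one `connections_<projection>.csv` per projection (header
#' `pre_gid,post_gid,weight,delay`) plus a YAML `manifest.yaml` recording
#' populations with their gid ranges, device ids, and the master seed —
#' the neutral integration surface for downstream simulators. Output is
#' deterministic: same instance and seed give byte-identical files.
#'
#' @param instance a `network_instance`.
#' @param connection_lists named list from [generate_network()].
#' @param out_dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
export_connection_list <- function(instance, connection_lists, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (nm in names(connection_lists)) {
    path <- file.path(out_dir, paste0("connections_", sanitize_filename(nm),
                                      ".csv"))
    df <- connection_lists[[nm]]
    lines <- c("pre_gid,post_gid,weight,delay",
               if (nrow(df)) sprintf("%d,%d,%s,%s", df$pre_gid, df$post_gid,
                                     fmt_num(df$weight), fmt_num(df$delay)))
    writeLines(lines, path)
    written <- c(written, path)
  }
  gr <- instance$gid_ranges
  manifest <- list(
    model = instance$model$name,
    seed = as.integer(instance$seed),
    total_neurons = as.integer(instance$total_neurons),
    populations = lapply(seq_len(nrow(gr)), function(k) {
      list(name = gr$population[k], first_gid = gr$first[k],
           last_gid = gr$last[k])
    }),
    devices = lapply(names(instance$device_ids), function(d) {
      list(name = d, id = unname(instance$device_ids[[d]]))
    }),
    projections = as.list(names(connection_lists))
  )
  mpath <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  invisible(c(written, mpath))
}

sanitize_filename <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

#' @export
print.network_instance <- function(x, ...) {
  cat(sprintf("<network_instance '%s': %d neurons in %d populations, %d devices, seed %d>\n",
              x$model$name, x$total_neurons, nrow(x$gid_ranges),
              length(x$device_ids), x$seed))
  invisible(x)
}
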