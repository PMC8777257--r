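## Hierarchical network model container. Populations are the leaves of the
## hierarchy; grouping them gives super-populations. Input, output and
## translator devices live outside the tree. The builder API is functional:
## every operation returns a new model value.
##
## Internal representation: `entities` is a flat named list (one entry per
## population or super-population) with parent/children name links, which
## makes the model-wide name-uniqueness and forest invariants cheap to
## enforce; `projections`, `inputs`, `outputs`, `translators` are ordered
## lists.

#' Create an empty network model
#'
#' @param name model name.
#' @return an object of class `network_model`.
#' @export
network_model <- function(name = "network") {
  structure(list(
    name = name,
    entities = list(),
    projections = list(),
    inputs = list(),
    outputs = list(),
    translators = list()
  ), class = "network_model")
}

## ---- reference helpers -----------------------------------------------------

all_names <- function(model) {
  c(names(model$entities),
    vapply(model$inputs, `[[`, "", "name"),
    vapply(model$outputs, `[[`, "", "name"),
    vapply(model$translators, `[[`, "", "name"))
}

check_new_name <- function(model, name) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("entity name must be a non-empty string", call. = FALSE)
  }
  if (name %in% all_names(model)) {
    stop_csanet("csanet_naming_error", "name already in use: '", name, "'")
  }
}

stop_csanet <- function(class, ..., element = NULL, location = NULL) {
  msg <- paste0(...)
  cond <- structure(
    class = c(class, "csanet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1),
         element = element, location = location))
  stop(cond)
}

resolve_entity <- function(model, ref, what = "entity") {
  if (!ref %in% names(model$entities)) {
    stop_csanet("csanet_reference_error",
                what, " not found: '", ref, "'", element = ref)
  }
  model$entities[[ref]]
}

device_names <- function(model) {
  list(
    inputs = vapply(model$inputs, `[[`, "", "name"),
    outputs = vapply(model$outputs, `[[`, "", "name"),
    translators = vapply(model$translators, `[[`, "", "name"))
}

ref_kind <- function(model, ref) {
  dn <- device_names(model)
  if (ref %in% names(model$entities)) {
    if (model$entities[[ref]]$type == "population") "population" else "group"
  } else if (ref %in% dn$inputs) "input"
  else if (ref %in% dn$outputs) "output"
  else if (ref %in% dn$translators) "translator"
  else NA_character_
}

root_names <- function(model) {
  ns <- names(model$entities)
  ns[vapply(model$entities, function(e) is.na(e$parent), TRUE)]
}

leaf_populations <- function(model) {
  ns <- names(model$entities)
  ns[vapply(model$entities, function(e) e$type == "population", TRUE)]
}

descendant_leaves <- function(model, ref) {
  e <- model$entities[[ref]]
  if (e$type == "population") return(ref)
  unlist(lapply(e$children, descendant_leaves, model = model),
         use.names = FALSE)
}

## ---- builder operations ----------------------------------------------------

attach_entity <- function(model, entity, parent) {
  if (!is.null(parent)) {
    resolve_entity(model, parent, "parent")
    if (model$entities[[parent]]$type != "super_population") {
      stop_csanet("csanet_validation_error",
                  "parent '", parent, "' is a leaf population")
    }
    entity$parent <- parent
    model$entities[[parent]]$children <-
      c(model$entities[[parent]]$children, entity$name)
  } else {
    entity$parent <- NA_character_
  }
  model$entities[[entity$name]] <- entity
  model
}

#' Add super-populations
#'
#' Creates `count` grouping nodes named `{name_root}_{i}` for
#' `i = 0 .. count - 1`, appended under `parent` (or as roots when `parent`
#' is `NULL`). With `count = 1` and `indexed = FALSE` a single group named
#' exactly `name_root` is created.
#'
#' @param model a `network_model`.
#' @param parent parent entity name, or `NULL` for top level.
#' @param name_root name root for the created groups.
#' @param count number of groups to create.
#' @param scale_label optional scale prefix label stored on each group.
#' @param indexed append `_{i}` indices (default `TRUE`).
#' @return the updated model; created names in `attr(, "created")`.
#' @export
add_super_population <- function(model, parent = NULL, name_root, count = 1L,
                                 scale_label = NULL, indexed = TRUE) {
  stopifnot(inherits(model, "network_model"), count >= 1)
  if (!nzchar(name_root)) stop("name_root must be non-empty", call. = FALSE)
  nms <- if (indexed) paste0(name_root, "_", seq_len(count) - 1L)
         else {
           stopifnot(count == 1L)
           name_root
         }
  for (nm in nms) check_new_name(model, nm)
  for (nm in nms) {
    ent <- list(name = nm, type = "super_population", parent = NA_character_,
                children = character(0), scale_label = scale_label)
    model <- attach_entity(model, ent, parent)
  }
  attr(model, "created") <- nms
  model
}

#' Add a leaf neuron population
#'
#' @param model a `network_model`.
#' @param parent parent entity name, or `NULL` for a top-level population.
#' @param name population name (unique model-wide).
#' @param size number of neurons (>= 1).
#' @param cell_model cell model tag (e.g. `"iaf"`, `"nmm kuramoto"`,
#'   `"proxy"`); interpretation is simulator-defined.
#' @param positions optional position specification from
#'   [position_explicit()] or [position_template()].
#' @param scale_label optional scale prefix label.
#' @return the updated model.
#' @export
add_population <- function(model, parent, name, size, cell_model = "iaf",
                           positions = NULL, scale_label = NULL) {
  stopifnot(inherits(model, "network_model"))
  check_new_name(model, name)
  if (!is.numeric(size) || length(size) != 1L || size < 1 ||
      size != round(size)) {
    stop_csanet("csanet_validation_error",
                "population size must be a positive integer, got ",
                format(size), element = name)
  }
  if (!is.character(cell_model) || !nzchar(cell_model)) {
    stop_csanet("csanet_validation_error", "cell_model must be non-empty",
                element = name)
  }
  if (!is.null(positions)) check_positions(positions, size, name)
  ent <- list(name = name, type = "population", parent = NA_character_,
              children = character(0), size = as.integer(size),
              cell_model = cell_model, positions = positions,
              scale_label = scale_label)
  model <- attach_entity(model, ent, parent)
  attr(model, "created") <- name
  model
}

#' Neuron position specifications
#'
#' Positions are either given explicitly, one coordinate row per neuron, or
#' sampled per-axis from a template distribution when the network is
#' instantiated. Coordinates are in micrometres.
#'
#' @param coordinates numeric matrix (n x 2 or n x 3).
#' @param template a `csa_distribution` sampled independently per axis.
#' @param dim 2 or 3 axes for sampled positions.
#' @return a `position_spec`.
#' @export
position_explicit <- function(coordinates) {
  coordinates <- as.matrix(coordinates)
  stopifnot(is.numeric(coordinates), ncol(coordinates) %in% c(2L, 3L))
  structure(list(mode = "explicit", coordinates = coordinates,
                 template = NULL, dim = ncol(coordinates)),
            class = "position_spec")
}

#' @rdname position_explicit
#' @export
position_template <- function(template, dim = 2L) {
  stopifnot(inherits(template, "csa_distribution"), dim %in% c(2L, 3L))
  structure(list(mode = "sampled", coordinates = NULL, template = template,
                 dim = as.integer(dim)),
            class = "position_spec")
}

check_positions <- function(positions, size, name) {
  stopifnot(inherits(positions, "position_spec"))
  if (positions$mode == "explicit" &&
      nrow(positions$coordinates) != size) {
    stop_csanet("csanet_validation_error",
                "explicit position count (", nrow(positions$coordinates),
                ") != population size (", size, ")", element = name)
  }
  invisible(TRUE)
}

#' Add devices external to the hierarchy
#'
#' Input devices (Poisson spike generators) stimulate one or more
#' populations; output devices record from one or more populations;
#' translator devices convert between spikes and rates at the boundary
#' between simulation scales. All three kinds are external to the entity
#' hierarchy and participate in projections like populations do.
#'
#' @param model a `network_model`.
#' @param name device name (unique model-wide).
#' @param rate Poisson rate in Hz (>= 0).
#' @param targets,sources population names the device is attached to
#'   (recorded on the device; the actual connectivity is a projection).
#' @param kind translator kind, `"spike_to_rate"` or `"rate_to_spike"`.
#' @return the updated model.
#' @export
add_input_device <- function(model, name, rate, targets = character(0)) {
  stopifnot(inherits(model, "network_model"), is.numeric(rate), rate >= 0)
  check_new_name(model, name)
  for (t in targets) resolve_entity(model, t, "input target")
  model$inputs[[length(model$inputs) + 1L]] <-
    list(name = name, kind = "poisson", rate = rate, targets = targets)
  model
}

#' @rdname add_input_device
#' @export
add_output_device <- function(model, name, sources = character(0)) {
  stopifnot(inherits(model, "network_model"))
  check_new_name(model, name)
  for (s in sources) {
    e <- resolve_entity(model, s, "output source")
    if (e$type != "population") {
      stop_csanet("csanet_validation_error",
                  "output devices record from leaf populations only: '",
                  s, "' is a group", element = name)
    }
  }
  model$outputs[[length(model$outputs) + 1L]] <-
    list(name = name, sources = sources)
  model
}

#' @rdname add_input_device
#' @export
add_translator <- function(model, name,
                           kind = c("spike_to_rate", "rate_to_spike")) {
  stopifnot(inherits(model, "network_model"))
  kind <- match.arg(kind)
  check_new_name(model, name)
  model$translators[[length(model$translators) + 1L]] <-
    list(name = name, kind = kind)
  model
}

#' Connect two model components with a projection
#'
#' Creates a projection from `source` to `target` carrying a connectivity
#' pattern and weight/delay distributions. Sources may be populations,
#' input devices or (rate-to-spike) translators; targets may be
#' populations, output devices or (spike-to-rate) translators. A
#' self-projection requires `auto = TRUE`.
#'
#' @param model a `network_model`.
#' @param source,target component names.
#' @param pattern a `csa_pattern`; default all-to-all.
#' @param weight,delay `csa_distribution`s (weight in model units, delay in
#'   ms).
#' @param auto set `TRUE` to allow `source == target` (auto-connection).
#' @param name optional projection name; a deterministic
#'   `"{source}__to__{target}"` (suffixed on repeats) is derived otherwise.
#' @return the updated model; the projection name in `attr(, "created")`.
#' @export
connect <- function(model, source, target, pattern = conn_all_to_all(),
                    weight = dist_constant(1), delay = dist_constant(1),
                    auto = FALSE, name = NULL) {
  stopifnot(inherits(model, "network_model"), inherits(pattern, "csa_pattern"),
            inherits(weight, "csa_distribution"),
            inherits(delay, "csa_distribution"))
  for (ref in c(source, target)) {
    if (is.na(ref_kind(model, ref))) {
      stop_csanet("csanet_reference_error",
                  "projection endpoint not found: '", ref, "'", element = ref)
    }
  }
  if (identical(source, target) && !isTRUE(auto)) {
    stop_csanet("csanet_validation_error",
                "self-projection on '", source,
                "' requires auto = TRUE", element = source)
  }
  if (is.null(name)) {
    base <- paste0(source, "__to__", target)
    name <- base
    k <- 1L
    existing <- vapply(model$projections, `[[`, "", "name")
    while (name %in% existing) {
      k <- k + 1L
      name <- paste0(base, "__", k)
    }
  } else if (name %in% vapply(model$projections, `[[`, "", "name")) {
    stop_csanet("csanet_naming_error", "projection name in use: '", name, "'")
  }
  model$projections[[length(model$projections) + 1L]] <-
    list(name = name, source = source, target = target, pattern = pattern,
         weight = weight, delay = delay, auto = isTRUE(auto))
  attr(model, "created") <- name
  model
}

#' Delete an entity (cascading)
#'
#' Removes an entity and all its descendants from the hierarchy.
#' Projections or device attachments that referenced the deleted subtree
#' are left in place and surface as diagnostics from [validate_model()]
#' rather than being silently dropped.
#'
#' @param model a `network_model`.
#' @param name entity to delete.
#' @return the updated model.
#' @export
delete_entity <- function(model, name) {
  e <- resolve_entity(model, name)
  doomed <- c(name, all_descendants(model, name))
  if (!is.na(e$parent)) {
    model$entities[[e$parent]]$children <-
      setdiff(model$entities[[e$parent]]$children, name)
  }
  model$entities[doomed] <- NULL
  model
}

all_descendants <- function(model, ref) {
  e <- model$entities[[ref]]
  if (length(e$children) == 0) return(character(0))
  unlist(lapply(e$children, function(c) c(c, all_descendants(model, c))),
         use.names = FALSE)
}

## ---- summaries -------------------------------------------------------------

#' Summarize an entity: hierarchy depth and total neuron count
#'
#' `depth` is the longest path from the entity down to a leaf population
#' (0 for a leaf); `total_neurons` sums the sizes of all descendant leaves.
#' Totals are additive: a parent's total equals the sum of its children's.
#'
#' @param model a `network_model`.
#' @param entity entity name.
#' @return list with `depth` and `total_neurons`.
#' @export
summarize_entity <- function(model, entity) {
  e <- resolve_entity(model, entity)
  if (e$type == "population") {
    return(list(depth = 0L, total_neurons = e$size))
  }
  if (length(e$children) == 0) {
    return(list(depth = 0L, total_neurons = 0L))
  }
  subs <- lapply(e$children, summarize_entity, model = model)
  list(depth = 1L + max(vapply(subs, `[[`, 0L, "depth")),
       total_neurons = sum(vapply(subs, `[[`, 0L, "total_neurons")))
}

entity_level <- function(model, ref) {
  lvl <- 0L
  p <- model$entities[[ref]]$parent
  while (!is.na(p)) {
    lvl <- lvl + 1L
    p <- model$entities[[p]]$parent
  }
  lvl
}

ancestor_at_level <- function(model, ref, level) {
  while (entity_level(model, ref) > level) {
    ref <- model$entities[[ref]]$parent
  }
  ref
}

#' Aggregate projections to a higher abstraction level
#'
#' Connections created between leaf populations are reflected at coarser
#' hierarchy levels in aggregated form: each leaf-level projection
#' contributes its analytic expected connection count to the single edge
#' between the level-`level` ancestors of its endpoints. Device edges pass
#' through unchanged. Aggregation uses expected counts (not realized
#' samples) so it is deterministic and RNG-free.
#'
#' @param model a `network_model`.
#' @param level hierarchy level (0 = roots) at which to aggregate.
#' @return data.frame with columns `source`, `target`, `strength`.
#' @export
aggregate_projections <- function(model, level = 0L) {
  stopifnot(level >= 0)
  if (length(model$projections) == 0) {
    return(data.frame(source = character(0), target = character(0),
                      strength = numeric(0)))
  }
  rows <- lapply(model$projections, function(pr) {
    strength <- projection_expected_count(model, pr)
    src <- if (pr$source %in% names(model$entities)) {
      ancestor_at_level(model, pr$source, level)
    } else pr$source
    tgt <- if (pr$target %in% names(model$entities)) {
      ancestor_at_level(model, pr$target, level)
    } else pr$target
    data.frame(source = src, target = tgt, strength = strength)
  })
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(strength ~ source + target, data = df, FUN = sum)
  agg <- agg[order(match(paste(agg$source, agg$target),
                         unique(paste(df$source, df$target)))), ]
  rownames(agg) <- NULL
  agg[, c("source", "target", "strength")]
}

endpoint_size <- function(model, ref) {
  kind <- ref_kind(model, ref)
  if (kind %in% c("population", "group")) {
    summarize_entity(model, ref)$total_neurons
  } else 1L  # devices occupy a single slot
}

projection_expected_count <- function(model, pr) {
  n_s <- endpoint_size(model, pr$source)
  n_t <- endpoint_size(model, pr$target)
  if (pr$pattern$kind == "atlas") {
    at <- try(load_atlas_pattern(pr$pattern), silent = TRUE)
    if (inherits(at, "try-error")) return(NA_real_)
    return(sum(at$weights > 0))
  }
  pos <- NULL
  if (pr$pattern$kind == "gaussian_2d") {
    pos <- list(source = explicit_positions_of(model, pr$source),
                target = explicit_positions_of(model, pr$target))
    if (is.null(pos$source) || is.null(pos$target)) pos <- NULL
  }
  expected_connection_count(pr$pattern, n_s, n_t, positions = pos)
}

explicit_positions_of <- function(model, ref) {
  if (!ref %in% names(model$entities)) return(NULL)
  e <- model$entities[[ref]]
  if (e$type != "population" || is.null(e$positions) ||
      e$positions$mode != "explicit") return(NULL)
  e$positions$coordinates
}

## ---- validation ------------------------------------------------------------

has_trailing_index <- function(name) grepl("_[0-9]+$", name)

trailing_index <- function(name) {
  as.integer(sub("^.*_([0-9]+)$", "\\1", name))
}

#' Validate a network model
#'
#' Returns diagnostics (never throws): dangling projection endpoints or
#' device attachments, invalid pattern parameterizations, atlas projections
#' whose endpoint names lack the required trailing `_{index}`, explicit
#' position counts that do not match population sizes.
#'
#' @param model a `network_model`.
#' @return data.frame with columns `severity`, `entity`, `message`; zero
#'   rows when the model is well-formed.
#' @export
validate_model <- function(model) {
  diags <- list()
  note <- function(severity, entity, message) {
    diags[[length(diags) + 1L]] <<-
      data.frame(severity = severity, entity = entity, message = message)
  }
  for (pr in model$projections) {
    for (ref in c(pr$source, pr$target)) {
      if (is.na(ref_kind(model, ref))) {
        note("error", pr$name,
             paste0("projection endpoint not found: '", ref, "'"))
      }
    }
    if (identical(pr$source, pr$target) && !isTRUE(pr$auto)) {
      note("error", pr$name, "self-projection without auto flag")
    }
    if (pr$pattern$kind == "atlas") {
      for (ref in c(pr$source, pr$target)) {
        if (!is.na(ref_kind(model, ref)) && !has_trailing_index(ref)) {
          note("error", pr$name,
               paste0("atlas endpoint '", ref,
                      "' lacks a trailing _{index} in its name"))
        }
      }
    }
  }
  for (d in model$inputs) {
    for (t in d$targets) {
      if (!t %in% names(model$entities)) {
        note("error", d$name, paste0("input target not found: '", t, "'"))
      }
    }
  }
  for (d in model$outputs) {
    for (s in d$sources) {
      if (!s %in% names(model$entities)) {
        note("error", d$name, paste0("output source not found: '", s, "'"))
      }
    }
  }
  for (e in model$entities) {
    if (e$type == "population" && !is.null(e$positions) &&
        e$positions$mode == "explicit" &&
        nrow(e$positions$coordinates) != e$size) {
      note("error", e$name, "explicit position count != population size")
    }
  }
  if (length(diags) == 0) {
    data.frame(severity = character(0), entity = character(0),
               message = character(0))
  } else {
    do.call(rbind, diags)
  }
}

#' @export
print.network_model <- function(x, ...) {
  n_pop <- sum(vapply(x$entities, function(e) e$type == "population", TRUE))
  n_grp <- length(x$entities) - n_pop
  total <- sum(vapply(x$entities,
                      function(e) if (e$type == "population") e$size else 0L,
                      0L))
  cat(sprintf(paste0("<network_model '%s': %d groups, %d populations ",
                     "(%d neurons), %d projections, %d inputs, %d outputs, ",
                     "%d translators>\n"),
              x$name, n_grp, n_pop, total, length(x$projections),
              length(x$inputs), length(x$outputs), length(x$translators)))
  invisible(x)
}
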