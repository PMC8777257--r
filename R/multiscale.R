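## Multiscale co-simulation support: populations are assigned to
## simulation scales by name-prefix rules, the model is split into
## scale-specific sub-models, and a neutral co-simulation interface
## configuration (proxy regions + translator wiring) is emitted. The
## numeric spike<->rate conversion and the orchestration of the simulators
## are the co-simulation framework's job, not this package's.

#' Scale-assignment rule
#'
#' Populations whose names start with `prefix` belong to scale `scale_id`;
#' rules are applied first-match-wins in the given order.
#'
#' @param prefix non-empty name prefix.
#' @param scale_id scale identifier (e.g. `"nest_point_neuron"`,
#'   `"tvb_neural_mass"`).
#' @return a `scale_rule`.
#' @export
scale_rule <- function(prefix, scale_id) {
  stopifnot(is.character(prefix), nzchar(prefix),
            is.character(scale_id), nzchar(scale_id))
  structure(list(prefix = prefix, scale_id = scale_id),
            class = "scale_rule")
}

#' Assign populations to simulation scales by name prefix
#'
#' Every leaf population is assigned to the scale of the first rule whose
#' prefix matches the start of its name. Translator devices belong to the
#' co-simulation interface and receive no scale. A population matching no
#' rule is an error (listing the offending names).
#'
#' @param model a `network_model`.
#' @param rules non-empty list of [scale_rule()]s.
#' @return named character vector: population name -> scale_id.
#' @export
assign_scales <- function(model, rules) {
  stopifnot(length(rules) >= 1)
  rules <- lapply(rules, function(r) {
    if (inherits(r, "scale_rule")) r else scale_rule(r$prefix, r$scale)
  })
  pops <- leaf_populations(model)
  assignment <- vapply(pops, function(p) {
    for (r in rules) {
      if (startsWith(p, r$prefix)) return(r$scale_id)
    }
    NA_character_
  }, "")
  if (anyNA(assignment)) {
    stop_csanet("csanet_validation_error",
                "populations match no scale rule: ",
                paste0("'", pops[is.na(assignment)], "'", collapse = ", "))
  }
  assignment
}

scale_of_ref <- function(model, assignment, ref) {
  kind <- ref_kind(model, ref)
  switch(kind,
    population = assignment[[ref]],
    group = {
      leaves <- descendant_leaves(model, ref)
      s <- unique(assignment[leaves])
      if (length(s) != 1L) {
        stop_csanet("csanet_validation_error", "group '", ref,
                    "' spans scales: ", paste(s, collapse = ", "),
                    element = ref)
      }
      s
    },
    translator = NA_character_,
    input = ,
    output = "device",  # resolved from the attached populations below
    stop_csanet("csanet_reference_error", "unknown reference '", ref, "'",
                element = ref))
}

## scale of an input/output device = unique scale of its attached
## populations (or of its projection peers if unattached)
device_scale <- function(model, assignment, name) {
  dn <- device_names(model)
  attached <- character(0)
  if (name %in% dn$inputs) {
    attached <- model$inputs[[which(dn$inputs == name)]]$targets
  } else if (name %in% dn$outputs) {
    attached <- model$outputs[[which(dn$outputs == name)]]$sources
  }
  peers <- unlist(lapply(model$projections, function(pr) {
    if (pr$source == name) pr$target
    else if (pr$target == name) pr$source
    else NULL
  }))
  cand <- unique(c(attached, peers))
  cand <- cand[cand %in% names(model$entities)]
  leaves <- unique(unlist(lapply(cand, descendant_leaves, model = model)))
  s <- unique(assignment[leaves])
  if (length(s) != 1L) {
    stop_csanet("csanet_validation_error", "device '", name,
                "' attaches to populations on ",
                if (length(s)) "multiple scales" else "no scale",
                element = name)
  }
  s
}

#' Split a model into scale-specific sub-models
#'
#' Each population lands in exactly one sub-model (with its ancestor
#' groups, pruned to that scale). Intra-scale projections are copied
#' verbatim; projections that cross scales must pass through a translator
#' device and are recorded as translator links in the interface spec
#' instead of being copied; a direct cross-scale projection with no
#' translator is an error. Populations with cell model `"proxy"` are
#' recorded as proxy regions with their trailing name index.
#'
#' @param model a valid `network_model`.
#' @param assignment named vector from [assign_scales()] (or a list of
#'   rules, which is passed through [assign_scales()] first).
#' @return list with `sub_models` (named list of `network_model`s, one per
#'   scale in order of first appearance) and `interface` (a
#'   `cosim_interface` with `sub_models`, `proxy_regions`,
#'   `translator_links`).
#' @export
split_model <- function(model, assignment) {
  if (is.list(assignment)) assignment <- assign_scales(model, assignment)
  pops <- leaf_populations(model)
  stopifnot(setequal(names(assignment), pops))
  scales <- unique(unname(assignment[pops]))

  sub_models <- stats::setNames(lapply(scales, function(sc) {
    sub <- network_model(paste0(model$name, "__", sc))
    copy_subtree <- function(sub, name, parent) {
      e <- model$entities[[name]]
      if (e$type == "population") {
        if (assignment[[name]] != sc) return(sub)
        add_population(sub, parent, e$name, e$size,
                       cell_model = e$cell_model, positions = e$positions,
                       scale_label = e$scale_label)
      } else {
        kept_leaves <- descendant_leaves(model, name)
        if (!any(assignment[kept_leaves] == sc)) return(sub)
        sub <- add_super_population(sub, parent, e$name, 1L,
                                    scale_label = e$scale_label,
                                    indexed = FALSE)
        for (child in e$children) sub <- copy_subtree(sub, child, e$name)
        sub
      }
    }
    for (r in root_names(model)) sub <- copy_subtree(sub, r, NULL)
    sub
  }), scales)

  translator_kinds <- stats::setNames(
    vapply(model$translators, `[[`, "", "kind"),
    vapply(model$translators, `[[`, "", "name"))

  links <- list()
  for (pr in model$projections) {
    ends <- c(pr$source, pr$target)
    is_translator <- ends %in% names(translator_kinds)
    if (any(is_translator)) {
      tname <- ends[is_translator][[1]]
      links[[length(links) + 1L]] <- list(
        translator = tname, kind = unname(translator_kinds[[tname]]),
        source = pr$source, target = pr$target,
        projection = pr)
      next
    }
    end_scale <- vapply(ends, function(ref) {
      kind <- ref_kind(model, ref)
      if (kind %in% c("input", "output")) device_scale(model, assignment, ref)
      else scale_of_ref(model, assignment, ref)
    }, "")
    if (end_scale[1] != end_scale[2]) {
      stop_csanet("csanet_validation_error",
                  "projection '", pr$name, "' crosses scales ",
                  end_scale[1], " -> ", end_scale[2],
                  " without a translator device", element = pr$name)
    }
    sc <- end_scale[[1]]
    sub <- sub_models[[sc]]
    sub$projections[[length(sub$projections) + 1L]] <- pr
    sub_models[[sc]] <- sub
  }

  ## devices follow their scale
  for (d in model$inputs) {
    sc <- device_scale(model, assignment, d$name)
    sub <- sub_models[[sc]]
    sub$inputs[[length(sub$inputs) + 1L]] <- d
    sub_models[[sc]] <- sub
  }
  for (d in model$outputs) {
    sc <- device_scale(model, assignment, d$name)
    sub <- sub_models[[sc]]
    sub$outputs[[length(sub$outputs) + 1L]] <- d
    sub_models[[sc]] <- sub
  }

  proxies <- list()
  for (p in pops) {
    if (model$entities[[p]]$cell_model == "proxy") {
      if (!has_trailing_index(p)) {
        stop_csanet("csanet_validation_error", "proxy population '", p,
                    "' has no trailing _{index}", element = p)
      }
      own <- assignment[[p]]
      counterpart <- setdiff(scales, own)
      proxies[[length(proxies) + 1L]] <- list(
        scale_id = own, region_index = trailing_index(p), population = p,
        counterpart_scale_id = if (length(counterpart) == 1L) counterpart
                               else NA_character_)
    }
  }

  interface <- structure(list(
    sub_models = stats::setNames(as.list(paste0(scales, ".xml")), scales),
    proxy_regions = proxies,
    translator_links = links,
    translators = model$translators
  ), class = "cosim_interface")
  list(sub_models = sub_models, interface = interface)
}

#' Merge sub-models back into one model
#'
#' Inverse of [split_model()] up to declaration ordering: entities and
#' intra-scale projections are unioned, translators are restored from the
#' interface, and translator links become projections again.
#'
#' @param sub_models named list of `network_model`s.
#' @param interface the `cosim_interface` from the split.
#' @param name name for the merged model.
#' @return a `network_model`.
#' @export
merge_submodels <- function(sub_models, interface, name = "merged") {
  merged <- network_model(name)
  copy_into <- function(merged, sub, ename, parent) {
    e <- sub$entities[[ename]]
    if (e$type == "population") {
      add_population(merged, parent, e$name, e$size,
                     cell_model = e$cell_model, positions = e$positions,
                     scale_label = e$scale_label)
    } else {
      merged <- add_super_population(merged, parent, e$name, 1L,
                                     scale_label = e$scale_label,
                                     indexed = FALSE)
      for (child in e$children) {
        merged <- copy_into(merged, sub, child, e$name)
      }
      merged
    }
  }
  for (sub in sub_models) {
    for (r in root_names(sub)) merged <- copy_into(merged, sub, r, NULL)
    for (d in sub$inputs) {
      merged <- add_input_device(merged, d$name, d$rate, d$targets)
    }
    for (d in sub$outputs) {
      merged <- add_output_device(merged, d$name, d$sources)
    }
  }
  for (tr in interface$translators) {
    merged <- add_translator(merged, tr$name, tr$kind)
  }
  for (sub in sub_models) {
    for (pr in sub$projections) {
      merged$projections[[length(merged$projections) + 1L]] <- pr
    }
  }
  for (lk in interface$translator_links) {
    merged$projections[[length(merged$projections) + 1L]] <- lk$projection
  }
  attr(merged, "created") <- NULL
  merged
}

#' Emit co-simulation configuration files
#'
#' Writes one dialect-XML file per sub-model plus `cosim.yaml`, a neutral
#' interface configuration recording the sub-model files, proxy region
#' indices, translator kinds and their endpoint wiring, and any atlas
#' archive referenced. Deterministic output.
#'
#' @param split result of [split_model()].
#' @param out_dir output directory.
#' @return character vector of files written, invisibly.
#' @export
emit_cosim_config <- function(split, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (sc in names(split$sub_models)) {
    path <- file.path(out_dir, paste0(sanitize_filename(sc), ".xml"))
    write_neuroml(split$sub_models[[sc]], path)
    written <- c(written, path)
  }
  iface <- split$interface
  atlas_files <- unique(unlist(lapply(split$sub_models, function(sub) {
    vapply(Filter(function(pr) pr$pattern$kind == "atlas", sub$projections),
           function(pr) pr$pattern$file, "")
  })))
  cfg <- list(
    sub_models = lapply(names(split$sub_models), function(sc) {
      list(scale = sc, file = paste0(sanitize_filename(sc), ".xml"))
    }),
    proxy_regions = lapply(iface$proxy_regions, function(p) {
      list(scale = p$scale_id, region_index = p$region_index,
           population = p$population,
           counterpart_scale = p$counterpart_scale_id)
    }),
    translators = lapply(iface$translators, function(tr) {
      list(name = tr$name, kind = tr$kind)
    }),
    translator_links = lapply(iface$translator_links, function(lk) {
      list(translator = lk$translator, kind = lk$kind,
           source = lk$source, target = lk$target)
    }),
    atlas_archives = as.list(atlas_files %||% character(0))
  )
  cpath <- file.path(out_dir, "cosim.yaml")
  yaml::write_yaml(cfg, cpath)
  invisible(c(written, cpath))
}

#' @export
print.cosim_interface <- function(x, ...) {
  cat(sprintf("<cosim_interface: %d sub-models, %d proxies, %d translator links>\n",
              length(x$sub_models), length(x$proxy_regions),
              length(x$translator_links)))
  invisible(x)
}
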