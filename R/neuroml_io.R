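## Reader/writer for the package's extended NetworkML dialect (NeuroML
## 1.8.x lineage) and a lossless JSON mirror.
##
## The dialect is self-defined and versioned; its XSD ships with the
## package (inst/schema/networkml-ext.xsd). Extensions over plain NetworkML
## level 3: spatial and atlas connectivity elements, distribution
## attributes on <weight>/<internal_delay>, scale_label attributes,
## translator/output device elements and explicit neuron instance
## positions. Units are declared on the root: lengths in micrometres,
## delays in ms, rates in Hz; weight units are simulator-defined.
##
## Parse contract: sections are processed populations -> projections ->
## inputs -> outputs -> translators regardless of their order in the file;
## after parsing every string reference must resolve (undefined references
## raise a csanet_reference_error identifying the element); no partial
## model escapes a failed parse.

DIALECT_VERSION <- "1.8.2-ext.1"

dialect_schema <- function() {
  xml2::read_xml(system.file("schema", "networkml-ext.xsd",
                             package = "csanet", mustWork = TRUE))
}

## ---- writing ---------------------------------------------------------------

dist_attrs <- function(d) {
  if (d$kind == "constant") {
    c(value = fmt_num(d$params$value))
  } else {
    ps <- vapply(d$params, fmt_num, "")
    c(distribution = d$kind, ps)
  }
}

pattern_node <- function(parent, pattern) {
  add <- function(name, attrs = character(0)) {
    node <- xml2::xml_add_child(parent, name)
    for (a in names(attrs)) xml2::xml_set_attr(node, a, attrs[[a]])
    node
  }
  switch(pattern$kind,
    all_to_all = add("all_to_all",
      if (!pattern$allow_autapses) c(allow_autapses = "false")),
    one_to_one = add("one_to_one"),
    fixed_probability = add("fixed_probability", c(
      probability = fmt_num(pattern$p),
      if (!pattern$allow_autapses) c(allow_autapses = "false"))),
    per_cell = add("per_cell_connection", c(
      n = fmt_num(pattern$n),
      if (pattern$direction != "pre_to_post")
        c(direction = pattern$direction),
      if (pattern$multapses) c(multapses = "true"),
      if (!pattern$allow_autapses) c(allow_autapses = "false"))),
    gaussian_2d = add("gaussian_connectivity_2d",
                      c(sigma = fmt_num(pattern$sigma))),
    atlas = add("atlas_connectivity", c(
      file = pattern$file,
      conduction_speed = fmt_num(pattern$conduction_speed)))
  )
}

entity_node <- function(parent, model, name) {
  e <- model$entities[[name]]
  if (e$type == "super_population") {
    node <- xml2::xml_add_child(parent, "group", name = e$name)
    if (!is.null(e$scale_label)) {
      xml2::xml_set_attr(node, "scale_label", e$scale_label)
    }
    for (child in e$children) entity_node(node, model, child)
  } else {
    node <- xml2::xml_add_child(parent, "population", name = e$name,
                                size = fmt_num(e$size),
                                cell_model = e$cell_model)
    if (!is.null(e$scale_label)) {
      xml2::xml_set_attr(node, "scale_label", e$scale_label)
    }
    if (!is.null(e$positions)) {
      if (e$positions$mode == "explicit") {
        inst <- xml2::xml_add_child(node, "instances")
        coords <- e$positions$coordinates
        for (k in seq_len(nrow(coords))) {
          ins <- xml2::xml_add_child(inst, "instance",
                                     id = fmt_num(k - 1L))
          loc <- xml2::xml_add_child(ins, "location",
                                     x = fmt_num(coords[k, 1]),
                                     y = fmt_num(coords[k, 2]))
          if (ncol(coords) == 3L) {
            xml2::xml_set_attr(loc, "z", fmt_num(coords[k, 3]))
          }
        }
      } else {
        tpl <- xml2::xml_add_child(node, "position_template",
                                   dim = fmt_num(e$positions$dim))
        for (a in names(dist_attrs(e$positions$template))) {
          xml2::xml_set_attr(tpl, a, dist_attrs(e$positions$template)[[a]])
        }
      }
    }
  }
  invisible(node)
}

#' Write a model as extended-NetworkML XML
#'
#' Refuses to serialize a model with validation errors. Output is
#' deterministic: a fixed model always produces byte-identical files, and
#' the declared element order is populations, then projections, then
#' inputs, outputs and translators.
#'
#' @param model a valid `network_model`.
#' @param path output file path (`.xml` / `.nml`).
#' @return `path`, invisibly.
#' @export
write_neuroml <- function(model, path) {
  diags <- validate_model(model)
  if (any(diags$severity == "error")) {
    stop_csanet("csanet_validation_error",
                "model has validation errors; refusing to write:\n",
                paste0("  [", diags$entity, "] ", diags$message,
                       collapse = "\n"))
  }
  doc <- xml2::xml_new_root("network", name = model$name,
                            version = DIALECT_VERSION,
                            length_units = "micrometre",
                            delay_units = "ms", rate_units = "Hz")
  pops <- xml2::xml_add_child(doc, "populations")
  for (r in root_names(model)) entity_node(pops, model, r)
  projs <- xml2::xml_add_child(doc, "projections")
  for (pr in model$projections) {
    node <- xml2::xml_add_child(projs, "projection", name = pr$name,
                                source = pr$source, target = pr$target)
    if (pr$auto) xml2::xml_set_attr(node, "auto", "true")
    pattern_node(node, pr$pattern)
    for (tag in c("weight", "internal_delay")) {
      d <- if (tag == "weight") pr$weight else pr$delay
      child <- xml2::xml_add_child(node, tag)
      attrs <- dist_attrs(d)
      for (a in names(attrs)) xml2::xml_set_attr(child, a, attrs[[a]])
    }
  }
  inputs <- xml2::xml_add_child(doc, "inputs")
  for (d in model$inputs) {
    node <- xml2::xml_add_child(inputs, "input", name = d$name,
                                kind = d$kind, rate = fmt_num(d$rate))
    for (t in d$targets) xml2::xml_add_child(node, "target", population = t)
  }
  outputs <- xml2::xml_add_child(doc, "outputs")
  for (d in model$outputs) {
    node <- xml2::xml_add_child(outputs, "output", name = d$name)
    for (s in d$sources) xml2::xml_add_child(node, "source", population = s)
  }
  translators <- xml2::xml_add_child(doc, "translators")
  for (d in model$translators) {
    xml2::xml_add_child(translators, "translator", name = d$name,
                        kind = d$kind)
  }
  xml2::write_xml(doc, path, options = "format")
  invisible(path)
}

## ---- reading ---------------------------------------------------------------

attr_or <- function(node, name, default = NULL) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) default else v
}

parse_dist_node <- function(node, exclude = character(0)) {
  kind <- attr_or(node, "distribution")
  if (is.null(kind)) {
    return(dist_constant(parse_num(xml2::xml_attr(node, "value"))))
  }
  attrs <- as.list(xml2::xml_attrs(node))
  attrs[c("distribution", exclude)] <- NULL
  params <- lapply(attrs, parse_num)
  distribution(kind, params)
}

parse_pattern_node <- function(node) {
  tag <- xml2::xml_name(node)
  autap <- !identical(attr_or(node, "allow_autapses"), "false")
  switch(tag,
    all_to_all = conn_all_to_all(allow_autapses = autap),
    one_to_one = conn_one_to_one(),
    fixed_probability = conn_fixed_probability(
      parse_num(xml2::xml_attr(node, "probability")),
      allow_autapses = autap),
    per_cell_connection = conn_per_cell(
      parse_num(xml2::xml_attr(node, "n")),
      direction = attr_or(node, "direction", "pre_to_post"),
      multapses = identical(attr_or(node, "multapses"), "true"),
      allow_autapses = autap),
    gaussian_connectivity_2d = conn_gaussian_2d(
      parse_num(xml2::xml_attr(node, "sigma"))),
    atlas_connectivity = conn_atlas(
      xml2::xml_attr(node, "file"),
      conduction_speed = parse_num(
        attr_or(node, "conduction_speed", "1"))),
    stop_csanet("csanet_schema_error", "unknown connectivity pattern tag <",
                tag, ">", element = tag)
  )
}

## children of a node that live in no namespace (foreign-namespace elements
## are ignored for forward compatibility)
own_children <- function(node) {
  kids <- xml2::xml_children(node)
  kids[!grepl(":", vapply(kids, xml2::xml_name, ""))]
}

parse_positions_node <- function(pop_node) {
  inst <- xml2::xml_find_first(pop_node, "./instances")
  if (!inherits(inst, "xml_missing")) {
    rows <- lapply(xml2::xml_find_all(inst, "./instance/location"),
                   function(loc) {
                     z <- attr_or(loc, "z")
                     c(parse_num(xml2::xml_attr(loc, "x")),
                       parse_num(xml2::xml_attr(loc, "y")),
                       if (!is.null(z)) parse_num(z))
                   })
    return(position_explicit(do.call(rbind, rows)))
  }
  tpl <- xml2::xml_find_first(pop_node, "./position_template")
  if (!inherits(tpl, "xml_missing")) {
    return(position_template(parse_dist_node(tpl, exclude = "dim"),
                             dim = parse_num(attr_or(tpl, "dim", "2"))))
  }
  NULL
}

parse_entity_node <- function(model, node, parent) {
  tag <- xml2::xml_name(node)
  if (tag == "group") {
    model <- add_super_population(model, parent,
                                  xml2::xml_attr(node, "name"), 1L,
                                  scale_label = attr_or(node, "scale_label"),
                                  indexed = FALSE)
    for (child in own_children(node)) {
      if (xml2::xml_name(child) %in% c("group", "population")) {
        model <- parse_entity_node(model, child,
                                   xml2::xml_attr(node, "name"))
      }
    }
  } else if (tag == "population") {
    model <- add_population(model, parent, xml2::xml_attr(node, "name"),
                            parse_num(xml2::xml_attr(node, "size")),
                            cell_model = xml2::xml_attr(node, "cell_model"),
                            positions = parse_positions_node(node),
                            scale_label = attr_or(node, "scale_label"))
  }
  model
}

## best-effort line lookup for error reporting: first file line mentioning
## name="<element>"
guess_line <- function(path, element) {
  if (is.null(element) || is.null(path)) return(NA_integer_)
  hits <- grep(paste0("\"", element, "\""), readLines(path, warn = FALSE),
               fixed = TRUE)
  if (length(hits)) hits[[1]] else NA_integer_
}

annotate_location <- function(expr, path, context) {
  withCallingHandlers(expr, csanet_error = function(e) {
    line <- guess_line(path, e$element)
    e$location <- if (is.na(line)) context
                  else paste0(context, ", line ", line)
    e$message <- paste0(e$message, " (", e$location, ")")
    stop(e)
  })
}

#' Read an extended-NetworkML file
#'
#' Validates the document against the shipped XSD, then parses populations
#' first, projections second, and inputs, outputs and translators last —
#' regardless of the order of the sections in the file — resolving every
#' string reference to a model object. Schema mismatches and undefined
#' references are raised as errors identifying the offending element (and,
#' best-effort, its line).
#'
#' @param path path to an `.xml`/`.nml` file in the dialect.
#' @param validate_schema set `FALSE` to skip XSD validation.
#' @return a `network_model` that passes [validate_model()].
#' @export
read_neuroml <- function(path, validate_schema = TRUE) {
  if (!file.exists(path)) {
    stop_csanet("csanet_data_error", "file not found: ", path)
  }
  doc <- xml2::read_xml(path)
  if (validate_schema) {
    ok <- xml2::xml_validate(doc, dialect_schema())
    if (!ok) {
      stop_csanet("csanet_schema_error", "schema mismatch in ", path, ":\n",
                  paste0("  ", attr(ok, "errors"), collapse = "\n"))
    }
  }
  model <- network_model(xml2::xml_attr(doc, "name"))

  ## phase 1: populations
  pops <- xml2::xml_find_first(doc, "./populations")
  if (!inherits(pops, "xml_missing")) {
    for (node in own_children(pops)) {
      model <- annotate_location(parse_entity_node(model, node, NULL),
                                 path, "populations section")
    }
  }
  ## phase 2: projections (deferred so forward references to populations
  ## declared later in the file still resolve)
  projs <- xml2::xml_find_first(doc, "./projections")
  proj_nodes <- if (inherits(projs, "xml_missing")) list()
                else own_children(projs)
  ## phase 3: inputs, outputs, translators
  ins <- xml2::xml_find_first(doc, "./inputs")
  if (!inherits(ins, "xml_missing")) {
    for (node in own_children(ins)) {
      tgts <- xml2::xml_attr(xml2::xml_find_all(node, "./target"),
                             "population")
      model <- annotate_location(
        add_input_device(model, xml2::xml_attr(node, "name"),
                         rate = parse_num(xml2::xml_attr(node, "rate")),
                         targets = tgts),
        path, "inputs section")
    }
  }
  outs <- xml2::xml_find_first(doc, "./outputs")
  if (!inherits(outs, "xml_missing")) {
    for (node in own_children(outs)) {
      srcs <- xml2::xml_attr(xml2::xml_find_all(node, "./source"),
                             "population")
      model <- annotate_location(
        add_output_device(model, xml2::xml_attr(node, "name"),
                          sources = srcs),
        path, "outputs section")
    }
  }
  trs <- xml2::xml_find_first(doc, "./translators")
  if (!inherits(trs, "xml_missing")) {
    for (node in own_children(trs)) {
      model <- annotate_location(
        add_translator(model, xml2::xml_attr(node, "name"),
                       kind = xml2::xml_attr(node, "kind")),
        path, "translators section")
    }
  }
  ## projections last: devices may be endpoints
  for (node in proj_nodes) {
    kids <- own_children(node)
    tags <- vapply(kids, xml2::xml_name, "")
    pat_node <- kids[!(tags %in% c("weight", "internal_delay"))][[1]]
    w_node <- kids[tags == "weight"][[1]]
    d_node <- kids[tags == "internal_delay"][[1]]
    model <- annotate_location(
      connect(model, xml2::xml_attr(node, "source"),
              xml2::xml_attr(node, "target"),
              pattern = parse_pattern_node(pat_node),
              weight = parse_dist_node(w_node),
              delay = parse_dist_node(d_node),
              auto = identical(attr_or(node, "auto"), "true"),
              name = xml2::xml_attr(node, "name")),
      path, "projections section")
  }
  attr(model, "created") <- NULL
  model
}

## ---- JSON mirror -----------------------------------------------------------

entity_to_list <- function(model, name) {
  e <- model$entities[[name]]
  if (e$type == "super_population") {
    out <- list(type = "group", name = e$name)
    if (!is.null(e$scale_label)) out$scale_label <- e$scale_label
    out$children <- lapply(e$children, entity_to_list, model = model)
    out
  } else {
    out <- list(type = "population", name = e$name, size = e$size,
                cell_model = e$cell_model)
    if (!is.null(e$scale_label)) out$scale_label <- e$scale_label
    if (!is.null(e$positions)) {
      out$positions <- if (e$positions$mode == "explicit") {
        list(mode = "explicit",
             coordinates = unname(apply(e$positions$coordinates, 1,
                                        as.numeric, simplify = FALSE)))
      } else {
        list(mode = "sampled", dim = e$positions$dim,
             template = dist_to_list(e$positions$template))
      }
    }
    out
  }
}

dist_to_list <- function(d) c(list(kind = d$kind), d$params)

pattern_to_list <- function(p) {
  out <- list(kind = p$kind)
  extra <- switch(p$kind,
    all_to_all = list(allow_autapses = p$allow_autapses),
    one_to_one = list(),
    fixed_probability = list(p = p$p, allow_autapses = p$allow_autapses),
    per_cell = list(n = p$n, direction = p$direction,
                    multapses = p$multapses,
                    allow_autapses = p$allow_autapses),
    gaussian_2d = list(sigma = p$sigma),
    atlas = list(file = p$file, conduction_speed = p$conduction_speed))
  c(out, extra)
}

#' Export / import the JSON mirror of a model
#'
#' A lossless JSON rendering of the same content as the XML dialect, with
#' stable key order. `model_from_json()` inverts it.
#'
#' @param model a valid `network_model`.
#' @param path optional file path; with `NULL` the JSON text is returned.
#' @return JSON text (class `json`), or `path` invisibly when writing.
#' @export
export_json <- function(model, path = NULL) {
  doc <- list(
    name = model$name,
    version = DIALECT_VERSION,
    units = list(length = "micrometre", delay = "ms", rate = "Hz"),
    populations = lapply(root_names(model), entity_to_list, model = model),
    projections = lapply(model$projections, function(pr) {
      list(name = pr$name, source = pr$source, target = pr$target,
           auto = pr$auto, pattern = pattern_to_list(pr$pattern),
           weight = dist_to_list(pr$weight), delay = dist_to_list(pr$delay))
    }),
    inputs = lapply(model$inputs, function(d) {
      list(name = d$name, kind = d$kind, rate = d$rate,
           targets = as.list(d$targets))
    }),
    outputs = lapply(model$outputs, function(d) {
      list(name = d$name, sources = as.list(d$sources))
    }),
    translators = model$translators
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) txt
  else {
    writeLines(txt, path)
    invisible(path)
  }
}

list_to_dist <- function(l) {
  distribution(l$kind, l[setdiff(names(l), "kind")])
}

list_to_pattern <- function(l) {
  switch(l$kind,
    all_to_all = conn_all_to_all(allow_autapses = l$allow_autapses),
    one_to_one = conn_one_to_one(),
    fixed_probability = conn_fixed_probability(
      l$p, allow_autapses = l$allow_autapses),
    per_cell = conn_per_cell(l$n, direction = l$direction,
                             multapses = l$multapses,
                             allow_autapses = l$allow_autapses),
    gaussian_2d = conn_gaussian_2d(l$sigma),
    atlas = conn_atlas(l$file, conduction_speed = l$conduction_speed))
}

add_entity_from_list <- function(model, l, parent) {
  if (l$type == "group") {
    model <- add_super_population(model, parent, l$name, 1L,
                                  scale_label = l$scale_label,
                                  indexed = FALSE)
    for (child in l$children) {
      model <- add_entity_from_list(model, child, l$name)
    }
  } else {
    positions <- NULL
    if (!is.null(l$positions)) {
      positions <- if (l$positions$mode == "explicit") {
        position_explicit(do.call(rbind, lapply(l$positions$coordinates,
                                                as.numeric)))
      } else {
        position_template(list_to_dist(l$positions$template),
                          dim = l$positions$dim)
      }
    }
    model <- add_population(model, parent, l$name, l$size,
                            cell_model = l$cell_model,
                            positions = positions,
                            scale_label = l$scale_label)
  }
  model
}

#' @rdname export_json
#' @param json JSON text, or a path to a JSON file.
#' @export
model_from_json <- function(json) {
  if (length(json) == 1L && !grepl("[{]", json) && file.exists(json)) {
    json <- paste(readLines(json, warn = FALSE), collapse = "\n")
  }
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  model <- network_model(doc$name)
  for (l in doc$populations) model <- add_entity_from_list(model, l, NULL)
  for (d in doc$inputs) {
    model <- add_input_device(model, d$name, rate = d$rate,
                              targets = unlist(d$targets) %||% character(0))
  }
  for (d in doc$outputs) {
    model <- add_output_device(model, d$name,
                               sources = unlist(d$sources) %||% character(0))
  }
  for (d in doc$translators) {
    model <- add_translator(model, d$name, kind = d$kind)
  }
  for (pr in doc$projections) {
    model <- connect(model, pr$source, pr$target,
                     pattern = list_to_pattern(pr$pattern),
                     weight = list_to_dist(pr$weight),
                     delay = list_to_dist(pr$delay),
                     auto = isTRUE(pr$auto), name = pr$name)
  }
  attr(model, "created") <- NULL
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
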