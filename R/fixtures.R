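## Programmatic reconstruction of the two reference use cases:
##   1. a cortical-microcircuit model (1 mm^3 of cortical tissue: four
##      layers x {excitatory, inhibitory}, a thalamic region, Poisson
##      background inputs), built from a shipped, editable parameter table
##      transcribed from the original microcircuit publication; and
##   2. a two-scale co-simulation model: the microcircuit (point-neuron
##      scale, names prefixed "l") embedded as a proxy region of a
##      68-region whole-brain neural-mass model wired through spike/rate
##      translator devices.

#' Cortical-microcircuit parameters
#'
#' Loads the editable parameter tables shipped with the package
#' (population sizes, the 8x8 connection-probability matrix with its
#' thalamic column, external-input indegrees) and combines them with the
#' synaptic and input parameters. Weights are in pA, delays in ms, rates
#' in Hz.
#'
#' @param populations_file,connectivity_file CSV paths; defaults are the
#'   shipped tables.
#' @param bg_rate background Poisson rate per external synapse (Hz).
#' @param w_mean mean excitatory synaptic strength (pA).
#' @param w_rel_sd relative standard deviation of synaptic strengths.
#' @param g ratio of inhibitory to excitatory synaptic strength
#'   (inhibitory weights are `-g * w_mean`).
#' @param delay_exc,delay_exc_sd,delay_inh,delay_inh_sd delay distribution
#'   parameters (ms) for excitatory / inhibitory sources.
#' @return a `microcircuit_params` list.
#' @export
microcircuit_params <- function(
    populations_file = system.file("extdata", "microcircuit_populations.csv",
                                   package = "csanet", mustWork = TRUE),
    connectivity_file = system.file("extdata", "microcircuit_connectivity.csv",
                                    package = "csanet", mustWork = TRUE),
    bg_rate = 8, w_mean = 87.8, w_rel_sd = 0.1, g = 4,
    delay_exc = 1.5, delay_exc_sd = 0.75,
    delay_inh = 0.8, delay_inh_sd = 0.4) {
  pops <- utils::read.csv(populations_file, comment.char = "#",
                          stringsAsFactors = FALSE)
  conn <- utils::read.csv(connectivity_file, comment.char = "#",
                          stringsAsFactors = FALSE)
  P <- as.matrix(conn[, -1])
  rownames(P) <- conn$target
  if (any(P < 0) || any(P >= 1)) {
    stop_csanet("csanet_validation_error",
                "connection probabilities must lie in [0, 1)")
  }
  needed <- pops$name[pops$type != "thalamic"]
  if (!all(needed %in% rownames(P)) || !all(needed %in% colnames(P))) {
    stop_csanet("csanet_validation_error",
                "connectivity table does not cover all cortical populations")
  }
  structure(list(populations = pops, P = P, bg_rate = bg_rate,
                 w_mean = w_mean, w_rel_sd = w_rel_sd, g = g,
                 delay_exc = delay_exc, delay_exc_sd = delay_exc_sd,
                 delay_inh = delay_inh, delay_inh_sd = delay_inh_sd),
            class = "microcircuit_params")
}

scaled_size <- function(size, scale_factor) {
  pmax(1L, as.integer(round(size * scale_factor)))
}

## adds the microcircuit (column + thalamic groups, populations,
## projections, Poisson inputs, a spike recorder) under `parent`
add_microcircuit <- function(model, parent, params, scale_factor,
                             column_group = "l_column",
                             thalamic_group = "l_thalamus") {
  pops <- params$populations
  cortical <- pops[pops$type != "thalamic", ]
  thalamic <- pops[pops$type == "thalamic", ]

  model <- add_super_population(model, parent, column_group, 1L,
                                indexed = FALSE)
  for (k in seq_len(nrow(cortical))) {
    model <- add_population(model, column_group, cortical$name[k],
                            scaled_size(cortical$size[k], scale_factor),
                            cell_model = "iaf")
  }
  model <- add_super_population(model, parent, thalamic_group, 1L,
                                indexed = FALSE)
  for (k in seq_len(nrow(thalamic))) {
    model <- add_population(model, thalamic_group, thalamic$name[k],
                            scaled_size(thalamic$size[k], scale_factor),
                            cell_model = "parrot")
  }

  is_inhibitory <- stats::setNames(pops$type == "inhibitory", pops$name)
  weight_of <- function(src) {
    mu <- if (is_inhibitory[[src]]) -params$g * params$w_mean
          else params$w_mean
    dist_gaussian(mu, abs(mu) * params$w_rel_sd)
  }
  delay_of <- function(src) {
    if (is_inhibitory[[src]]) {
      dist_gaussian(params$delay_inh, params$delay_inh_sd)
    } else {
      dist_gaussian(params$delay_exc, params$delay_exc_sd)
    }
  }
  for (tgt in rownames(params$P)) {
    for (src in colnames(params$P)) {
      p <- params$P[tgt, src]
      if (p <= 0) next
      model <- connect(model, src, tgt,
                       pattern = conn_fixed_probability(p),
                       weight = weight_of(src), delay = delay_of(src),
                       auto = identical(src, tgt))
    }
  }
  for (k in seq_len(nrow(cortical))) {
    nm <- cortical$name[k]
    if (cortical$k_ext[k] <= 0) next
    dev <- paste0("poisson_", nm)
    model <- add_input_device(model, dev,
                              rate = cortical$k_ext[k] * params$bg_rate,
                              targets = nm)
    model <- connect(model, dev, nm, pattern = conn_all_to_all(),
                     weight = dist_constant(params$w_mean),
                     delay = dist_constant(params$delay_exc))
  }
  add_output_device(model, "spike_recorder", sources = cortical$name)
}

#' Build the cortical-microcircuit model
#'
#' Two top-level super-populations (the cortical column and the thalamic
#' region); eight leaf populations (four layers, one excitatory and one
#' inhibitory each) with pairwise-Bernoulli cross- and auto-connections
#' and Gaussian weight/delay distributions; thalamic projections targeting
#' only the layer-4 and layer-6 populations; one Poisson input per
#' cortical population; one spike-recorder output.
#'
#' Connectivity is realized as pairwise Bernoulli draws with the tabulated
#' probabilities, so realized connection counts fluctuate around
#' `P * N_s * N_t`; the deterministic fixed-total convention is available
#' separately via [potjans_connection_count()].
#'
#' @param params a [microcircuit_params()] list.
#' @param scale_factor multiplicative size scaling in `(0, 1]`; every
#'   population keeps at least one neuron. Expected connection counts of
#'   the Bernoulli projections scale approximately with its square.
#' @return a `network_model`.
#' @export
build_microcircuit <- function(params = microcircuit_params(),
                               scale_factor = 1) {
  stopifnot(inherits(params, "microcircuit_params"),
            scale_factor > 0, scale_factor <= 1)
  model <- network_model("cortical_microcircuit")
  model <- add_microcircuit(model, NULL, params, scale_factor)
  attr(model, "created") <- NULL
  model
}

#' Build the two-scale co-simulation model
#'
#' One super-population holds the point-neuron-scale microcircuit (all
#' names prefixed `"l"`, see [build_microcircuit()]); a second holds
#' `n_regions` single-unit region populations `Brain_region_{i}` for the
#' neural-mass scale, all with cell model `"nmm kuramoto"` except the
#' proxy region, which carries cell model `"proxy"` and stands in for the
#' territory simulated at the fine scale. A single atlas projection
#' declared from the first to the last region carries the region-to-region
#' connectivity for the whole parcellation. Translator wiring: the proxy
#' region's output feeds the rate-to-spike translator, whose output feeds
#' the layer-4 and layer-6 populations; the layer-5 excitatory population
#' feeds the spike-to-rate translator, whose output feeds the proxy
#' region.
#'
#' @param n_regions number of atlas regions (68 for a Desikan-Killiany
#'   parcellation).
#' @param proxy_region_index index of the proxy region in `[0, n_regions)`.
#' @param atlas_archive path to the connectome-atlas zip (see
#'   [make_synthetic_atlas()]); its matrices must be
#'   `n_regions x n_regions`.
#' @param params microcircuit parameters.
#' @param scale_factor microcircuit size scaling.
#' @param conduction_speed mm/ms, for atlas delays.
#' @return a `network_model`.
#' @export
build_multiscale <- function(n_regions = 68L, proxy_region_index = 27L,
                             atlas_archive,
                             params = microcircuit_params(),
                             scale_factor = 1,
                             conduction_speed = 1) {
  if (proxy_region_index < 0 || proxy_region_index >= n_regions) {
    stop_csanet("csanet_validation_error", "proxy_region_index ",
                proxy_region_index, " outside [0, ", n_regions, ")")
  }
  model <- network_model("multiscale_cosim")
  model <- add_super_population(model, NULL, "l_region", 1L,
                                indexed = FALSE,
                                scale_label = "l")
  model <- add_microcircuit(model, "l_region", params, scale_factor)
  model <- add_super_population(model, NULL, "Brain_regions", 1L,
                                indexed = FALSE,
                                scale_label = "Brain_region")
  for (i in seq_len(n_regions) - 1L) {
    model <- add_population(model, "Brain_regions",
                            paste0("Brain_region_", i), 1L,
                            cell_model = if (i == proxy_region_index) "proxy"
                                         else "nmm kuramoto")
  }
  first <- "Brain_region_0"
  last <- paste0("Brain_region_", n_regions - 1L)
  model <- connect(model, first, last,
                   pattern = conn_atlas(atlas_archive,
                                        conduction_speed = conduction_speed),
                   weight = dist_constant(1), delay = dist_constant(1),
                   name = "atlas_regions")

  model <- add_translator(model, "spike_to_rate_translator", "spike_to_rate")
  model <- add_translator(model, "rate_to_spike_translator", "rate_to_spike")
  proxy <- paste0("Brain_region_", proxy_region_index)
  unit <- function() list(weight = dist_constant(1), delay = dist_constant(1))
  model <- connect(model, proxy, "rate_to_spike_translator",
                   weight = unit()$weight, delay = unit()$delay)
  model <- connect(model, "spike_to_rate_translator", proxy,
                   weight = unit()$weight, delay = unit()$delay)
  for (tgt in c("l4e", "l4i", "l6e", "l6i")) {
    model <- connect(model, "rate_to_spike_translator", tgt,
                     weight = unit()$weight, delay = unit()$delay)
  }
  model <- connect(model, "l5e", "spike_to_rate_translator",
                   weight = unit()$weight, delay = unit()$delay)
  attr(model, "created") <- NULL
  model
}

#' Default scale rules for the two-scale model
#'
#' Prefix `"l"` marks the point-neuron (spiking) scale, prefix
#' `"Brain_region"` the neural-mass whole-brain scale.
#'
#' @return list of [scale_rule()]s.
#' @export
multiscale_rules <- function() {
  list(scale_rule("l", "nest_point_neuron"),
       scale_rule("Brain_region", "tvb_neural_mass"))
}
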