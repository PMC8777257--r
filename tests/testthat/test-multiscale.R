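multiscale_fixture <- function(scale_factor = 0.02, n_regions = 68L,
                               proxy = 27L, seed = 1L) {
  ar <- make_synthetic_atlas(n_regions, seed = seed,
                             out_path = tempfile(fileext = ".zip"))
  build_multiscale(n_regions = n_regions, proxy_region_index = proxy,
                   atlas_archive = ar, scale_factor = scale_factor)
}

test_that("prefix rules assign every population to its scale", {
  m <- multiscale_fixture()
  asg <- assign_scales(m, multiscale_rules())
  micro <- c("l23e", "l23i", "l4e", "l4i", "l5e", "l5i", "l6e", "l6i", "lth")
  expect_true(all(asg[micro] == "nest_point_neuron"))
  regions <- grep("^Brain_region_", names(asg), value = TRUE)
  expect_length(regions, 68L)
  expect_true(all(asg[regions] == "tvb_neural_mass"))

  # single matching rule puts everything on one scale
  one <- assign_scales(hierarchy_fixture(), list(scale_rule("A", "x"),
                                                 scale_rule("B", "x"),
                                                 scale_rule("C", "x"),
                                                 scale_rule("D", "x")))
  expect_true(all(one == "x"))

  # a population matching no rule is an error naming it
  m2 <- add_population(hierarchy_fixture(), "SP_1", "X_1", 5)
  err <- expect_error(
    assign_scales(m2, list(scale_rule("A", "s1"), scale_rule("B", "s1"),
                           scale_rule("C", "s1"), scale_rule("D", "s1"))),
    class = "csanet_validation_error")
  expect_match(conditionMessage(err), "X_1")
})

test_that("splitting partitions populations and conserves projections", {
  m <- multiscale_fixture()
  sp <- split_model(m, multiscale_rules())
  expect_length(sp$sub_models, 2L)
  nest <- sp$sub_models$nest_point_neuron
  tvb <- sp$sub_models$tvb_neural_mass

  # population multiset conserved, each in exactly one sub-model
  pops_of <- function(x) csanet:::leaf_populations(x)
  expect_length(intersect(pops_of(nest), pops_of(tvb)), 0L)
  expect_setequal(c(pops_of(nest), pops_of(tvb)), pops_of(m))

  # nest side holds microcircuit + thalamus; tvb side the regions
  expect_true(all(c("l4e", "lth") %in% pops_of(nest)))
  expect_length(pops_of(tvb), 68L)

  # intra-scale projections conserved exactly
  pnames <- function(x) vapply(x$projections, `[[`, "", "name")
  cross <- vapply(sp$interface$translator_links,
                  function(l) l$projection$name, "")
  expect_setequal(c(pnames(nest), pnames(tvb), cross), pnames(m))
  expect_true("atlas_regions" %in% pnames(tvb))

  # sub-models remain valid standalone
  expect_equal(nrow(validate_model(nest)), 0L)
  expect_equal(nrow(validate_model(tvb)), 0L)
})

test_that("translator wiring crosses scales exactly once, with correct kinds", {
  m <- multiscale_fixture()
  sp <- split_model(m, multiscale_rules())
  links <- sp$interface$translator_links
  sig <- vapply(links, function(l) paste(l$source, l$target), "")

  # spiking -> coarse path: L5e output through the spike-to-rate translator
  expect_true("l5e spike_to_rate_translator" %in% sig)
  expect_true("spike_to_rate_translator Brain_region_27" %in% sig)
  # coarse -> spiking path: proxy through the rate-to-spike translator into
  # the layer 4 and 6 populations
  expect_true("Brain_region_27 rate_to_spike_translator" %in% sig)
  for (tgt in c("l4e", "l4i", "l6e", "l6i")) {
    expect_true(paste("rate_to_spike_translator", tgt) %in% sig)
  }
  kinds <- vapply(links, `[[`, "", "kind")
  expect_setequal(unique(kinds), c("spike_to_rate", "rate_to_spike"))

  # every translator appears in at least one link
  expect_setequal(unique(vapply(links, `[[`, "", "translator")),
                  c("spike_to_rate_translator", "rate_to_spike_translator"))

  # proxy region propagated with its parsed index
  expect_length(sp$interface$proxy_regions, 1L)
  px <- sp$interface$proxy_regions[[1]]
  expect_equal(px$region_index, 27L)
  expect_equal(px$scale_id, "tvb_neural_mass")
  expect_equal(px$counterpart_scale_id, "nest_point_neuron")
})

test_that("a direct cross-scale projection without translator is an error", {
  m <- multiscale_fixture()
  m <- connect(m, "l5e", "Brain_region_3", conn_all_to_all())
  expect_error(split_model(m, multiscale_rules()),
               class = "csanet_validation_error")
})

test_that("merging the split reconstructs the original model", {
  m <- multiscale_fixture()
  sp <- split_model(m, multiscale_rules())
  merged <- merge_submodels(sp$sub_models, sp$interface, name = m$name)
  expect_setequal(csanet:::leaf_populations(merged),
                  csanet:::leaf_populations(m))
  expect_setequal(vapply(merged$projections, `[[`, "", "name"),
                  vapply(m$projections, `[[`, "", "name"))
  # per-projection content identical
  by_name <- function(x) {
    prs <- x$projections
    stats::setNames(prs, vapply(prs, `[[`, "", "name"))
  }
  a <- by_name(m); b <- by_name(merged)
  for (nm in names(a)) expect_identical(b[[nm]], a[[nm]])
  expect_identical(
    lapply(merged$translators, `[[`, "name"),
    lapply(m$translators, `[[`, "name"))
})

test_that("cosim config emission writes sub-model xml plus cosim.yaml", {
  m <- multiscale_fixture()
  sp <- split_model(m, multiscale_rules())
  d <- withr::local_tempdir()
  files <- emit_cosim_config(sp, d)
  expect_setequal(basename(files),
                  c("nest_point_neuron.xml", "tvb_neural_mass.xml",
                    "cosim.yaml"))
  # each sub-model file re-reads as a valid standalone model
  for (f in files[grepl("[.]xml$", files)]) {
    expect_equal(nrow(validate_model(read_neuroml(f))), 0L)
  }
  cfg <- yaml::read_yaml(file.path(d, "cosim.yaml"))
  expect_equal(cfg$proxy_regions[[1]]$region_index, 27L)
  expect_length(cfg$translator_links, 7L)
  expect_length(cfg$atlas_archives, 1L)
})

test_that("a single-scale model splits into one sub-model, empty interface", {
  m <- hierarchy_fixture()
  m <- connect(m, "A0", "B0")
  sp <- split_model(m, list(scale_rule("A", "only"), scale_rule("B", "only"),
                            scale_rule("C", "only"), scale_rule("D", "only")))
  expect_length(sp$sub_models, 1L)
  expect_length(sp$interface$translator_links, 0L)
  expect_length(sp$interface$proxy_regions, 0L)
  d <- withr::local_tempdir()
  files <- emit_cosim_config(sp, d)
  expect_setequal(basename(files), c("only.xml", "cosim.yaml"))
})
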