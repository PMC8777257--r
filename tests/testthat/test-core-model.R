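test_that("super-population builder creates indexed groups and enforces naming", {
  m <- network_model()
  m <- add_super_population(m, NULL, "SP", 3L)
  expect_equal(attr(m, "created"), c("SP_0", "SP_1", "SP_2"))
  expect_setequal(csanet:::root_names(m), c("SP_0", "SP_1", "SP_2"))

  m <- add_super_population(m, "SP_0", "SP_0", 2L)
  expect_equal(attr(m, "created"), c("SP_0_0", "SP_0_1"))
  expect_equal(m$entities$SP_0$children, c("SP_0_0", "SP_0_1"))

  m2 <- add_super_population(network_model(), NULL, "X", 1L)
  expect_error(add_super_population(m2, NULL, "X", 1L),
               class = "csanet_naming_error")
  expect_error(add_super_population(m, "missing_parent", "Y", 1L),
               class = "csanet_reference_error")
})

test_that("population builder validates size and attaches leaves", {
  m <- add_super_population(network_model(), NULL, "SP", 3L)
  m <- add_population(m, "SP_2", "NP_2_0", 100, "iaf")
  expect_equal(m$entities$NP_2_0$parent, "SP_2")
  expect_equal(m$entities$NP_2_0$size, 100L)

  m <- add_population(m, "SP_0", "Brain_region_27", 1, "proxy")
  expect_equal(m$entities$Brain_region_27$cell_model, "proxy")

  expect_error(add_population(m, "SP_1", "bad", 0, "iaf"),
               class = "csanet_validation_error")
  # leaves cannot parent other entities
  expect_error(add_population(m, "NP_2_0", "child", 5, "iaf"),
               class = "csanet_validation_error")
})

test_that("connect resolves references and gates self-projections", {
  m <- hierarchy_fixture()
  m <- connect(m, "A0", "A0", conn_fixed_probability(0.1), auto = TRUE)
  expect_equal(m$projections[[1]]$auto, TRUE)
  expect_error(connect(m, "A1", "A1", conn_fixed_probability(0.1)),
               class = "csanet_validation_error")
  expect_error(connect(m, "A0", "missing"),
               class = "csanet_reference_error")

  m <- add_input_device(m, "poisson_in", rate = 8, targets = "B0")
  m <- connect(m, "poisson_in", "B0", conn_all_to_all())
  expect_equal(m$projections[[2]]$source, "poisson_in")
})

test_that("entity summaries give depth and additive neuron totals", {
  m <- hierarchy_fixture()
  expect_equal(summarize_entity(m, "SP_0"), list(depth = 2L, total_neurons = 400L))
  expect_equal(summarize_entity(m, "A0"), list(depth = 0L, total_neurons = 100L))
  # additivity at every internal node
  for (g in c("SP_0", "SP_0_0", "SP_0_1", "SP_1", "SP_2")) {
    kids <- m$entities[[g]]$children
    expect_equal(summarize_entity(m, g)$total_neurons,
                 sum(vapply(kids,
                            function(k) summarize_entity(m, k)$total_neurons,
                            0L)))
  }
  # halving the sibling sizes leaves SP_0 with twice the neurons
  m2 <- hierarchy_fixture()
  for (nm in c("C0", "C1", "D0", "D1")) m2$entities[[nm]]$size <- 100L
  expect_equal(summarize_entity(m2, "SP_0")$total_neurons,
               2L * summarize_entity(m2, "SP_1")$total_neurons)
})

test_that("builder invariants survive random build sequences", {
  for (seed in 1:25) {
    m <- random_model(seed)
    nms <- csanet:::all_names(m)
    expect_equal(anyDuplicated(nms), 0L)
    # forest: every child is claimed by exactly one parent
    claimed <- unlist(lapply(m$entities, `[[`, "children"))
    expect_equal(anyDuplicated(claimed), 0L)
    for (e in m$entities) {
      if (!is.na(e$parent)) {
        expect_true(e$name %in% m$entities[[e$parent]]$children)
      }
    }
    expect_equal(nrow(validate_model(m)), 0L)
  }
})

test_that("builder calls on disjoint subtrees commute", {
  base <- add_super_population(network_model("m"), NULL, "SP", 2L)
  ab <- add_population(add_population(base, "SP_0", "A", 10), "SP_1", "B", 20)
  ba <- add_population(add_population(base, "SP_1", "B", 20), "SP_0", "A", 10)
  expect_identical(model_signature(ab), model_signature(ba))
})

test_that("projection aggregation sums expected counts at ancestor level", {
  m <- hierarchy_fixture()
  # per_cell expected counts are exact: 5*10 = 50 and 7*10 = 70
  m$entities$A0$size <- 20L; m$entities$A1$size <- 20L
  m$entities$B0$size <- 10L; m$entities$B1$size <- 10L
  m <- connect(m, "A0", "B0", conn_per_cell(5L))
  m <- connect(m, "A1", "B1", conn_per_cell(7L))
  agg0 <- aggregate_projections(m, level = 0L)
  expect_equal(nrow(agg0), 1L)
  expect_equal(agg0$source, "SP_0")
  expect_equal(agg0$target, "SP_0")
  expect_equal(agg0$strength, 120)

  # one level down both projections still share the same ancestor pair
  agg1 <- aggregate_projections(m, level = 1L)
  expect_equal(agg1,
               data.frame(source = "SP_0_0", target = "SP_0_1",
                          strength = 120))

  # leaf level: identity map of projections to edges
  agg2 <- aggregate_projections(m, level = 5L)
  expect_equal(agg2$source, c("A0", "A1"))
  expect_equal(agg2$target, c("B0", "B1"))

  # conservation of total strength at every level
  leaf_total <- sum(vapply(m$projections,
                           function(pr) csanet:::projection_expected_count(m, pr),
                           0))
  for (lvl in 0:3) {
    expect_equal(sum(aggregate_projections(m, lvl)$strength), leaf_total)
  }

  expect_equal(nrow(aggregate_projections(network_model(), 0L)), 0L)
})

test_that("aggregation passes device edges through unchanged", {
  m <- hierarchy_fixture()
  m <- add_input_device(m, "pg", rate = 8, targets = "A0")
  m <- connect(m, "pg", "A0", conn_all_to_all())
  agg <- aggregate_projections(m, level = 0L)
  expect_equal(agg$source, "pg")
  expect_equal(agg$target, "SP_0")
  expect_equal(agg$strength, 100)  # device counts as one source slot
})

test_that("validation reports dangling references and atlas naming", {
  m <- hierarchy_fixture()
  m <- connect(m, "A0", "B0")
  expect_equal(nrow(validate_model(m)), 0L)

  # deletion cascades; dependent projections become diagnostics
  m2 <- delete_entity(m, "SP_0_1")
  expect_false("B0" %in% names(m2$entities))
  d <- validate_model(m2)
  expect_equal(nrow(d), 1L)
  expect_equal(d$severity, "error")
  expect_match(d$message, "B0")

  # atlas endpoints must carry a trailing index
  m3 <- hierarchy_fixture()
  m3 <- connect(m3, "A0", "B0",
                conn_atlas(tempfile(fileext = ".zip")))
  d3 <- validate_model(m3)
  expect_true(any(grepl("trailing _\\{index\\}", d3$message)))
})
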