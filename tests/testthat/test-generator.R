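two_pop_model <- function(n_a = 4L, n_b = 4L, pattern = conn_one_to_one(),
                          weight = dist_constant(2), delay = dist_constant(1.5)) {
  m <- network_model("two")
  m <- add_population(m, NULL, "A", n_a)
  m <- add_population(m, NULL, "B", n_b)
  connect(m, "A", "B", pattern, weight, delay)
}

test_that("instantiation lays out contiguous gid ranges in declaration order", {
  m <- network_model("gids")
  m <- add_population(m, NULL, "first", 3)
  m <- add_population(m, NULL, "second", 5)
  inst <- instantiate_network(m, seed = 1)
  expect_equal(inst$gid_ranges$first, c(0L, 3L))
  expect_equal(inst$gid_ranges$last, c(3L, 8L))
  expect_equal(inst$total_neurons, 8L)
})

test_that("sampled positions are reproducible and sized correctly", {
  m <- network_model("pos")
  m <- add_population(m, NULL, "P", 50,
                      positions = position_template(dist_gaussian(0, 30)))
  i1 <- instantiate_network(m, seed = 5)
  i2 <- instantiate_network(m, seed = 5)
  expect_identical(i1$positions$P, i2$positions$P)
  expect_equal(dim(i1$positions$P), c(50L, 2L))
  expect_false(identical(i1$positions$P,
                         instantiate_network(m, seed = 6)$positions$P))

  bad <- network_model("bad")
  expect_error(
    add_population(bad, NULL, "P", 5,
                   positions = position_explicit(matrix(0, 4, 2))),
    class = "csanet_validation_error")
})

test_that("projection realization maps mask indices into gid space", {
  m <- two_pop_model()
  inst <- instantiate_network(m, seed = 0)
  conns <- generate_projection(inst, m$projections[[1]])
  expect_equal(conns$pre_gid, 0:3)
  expect_equal(conns$post_gid, 4:7)
  expect_equal(conns$weight, rep(2, 4))
  expect_equal(conns$delay, rep(1.5, 4))
})

test_that("device projections use device ids and consume no neuron gids", {
  m <- network_model("dev")
  m <- add_population(m, NULL, "P", 6)
  m <- add_input_device(m, "pg", rate = 8, targets = "P")
  m <- connect(m, "pg", "P", conn_all_to_all())
  inst <- instantiate_network(m, seed = 0)
  expect_equal(unname(inst$device_ids["pg"]), 6L)  # above the neuron range
  conns <- generate_projection(inst, m$projections[[1]])
  expect_equal(nrow(conns), 6L)
  expect_true(all(conns$pre_gid == 6L))
  expect_equal(sort(conns$post_gid), 0:5)
})

test_that("bernoulli realization stays in the central binomial interval", {
  params <- microcircuit_params()
  m <- build_microcircuit(params, scale_factor = 0.05)
  inst <- instantiate_network(m, seed = 123)
  pr <- csanet:::resolve_projection(m, "l4e__to__l23e")
  expect_equal(pr$pattern$kind, "fixed_probability")
  conns <- generate_projection(inst, pr)
  n_s <- csanet:::endpoint_gid_info(inst, "l4e")$n
  n_t <- csanet:::endpoint_gid_info(inst, "l23e")$n
  p <- pr$pattern$p
  expect_gte(nrow(conns), qbinom(0.0005, n_s * n_t, p))
  expect_lte(nrow(conns), qbinom(0.9995, n_s * n_t, p))
})

test_that("atlas projections expand matrices into weighted, delayed records", {
  w <- matrix(1, 4, 4); diag(w) <- 0
  tl <- matrix(10, 4, 4); diag(tl) <- 0
  ar <- atlas_archive_from(w, tl)
  m <- network_model("atl")
  m <- add_super_population(m, NULL, "regions", 1L, indexed = FALSE)
  for (i in 0:3) {
    m <- add_population(m, "regions", paste0("R_", i), 1,
                        cell_model = if (i == 2) "proxy" else "nmm kuramoto")
  }
  m <- connect(m, "R_0", "R_3", conn_atlas(ar, conduction_speed = 2))
  inst <- instantiate_network(m, seed = 0)
  conns <- generate_projection(inst, m$projections[[1]])
  expect_equal(nrow(conns), 12L)  # zero diagonal: n (n - 1)
  expect_true(all(conns$weight == 1))
  expect_true(all(conns$delay == 5))  # 10 mm / 2 mm/ms
  # proxy region participates like any other
  expect_true(2L %in% conns$pre_gid && 2L %in% conns$post_gid)

  # a zero weight row produces no records with that source
  w2 <- w; w2[2, ] <- 0
  m2 <- m
  m2$projections[[1]]$pattern$file <- atlas_archive_from(w2, tl)
  conns2 <- generate_projection(instantiate_network(m2, seed = 0),
                                m2$projections[[1]])
  expect_false(1L %in% conns2$pre_gid)  # region index 1 silenced
  expect_equal(nrow(conns2), 9L)
})

test_that("atlas endpoints without trailing indices are rejected", {
  w <- matrix(1, 3, 3); diag(w) <- 0
  ar <- atlas_archive_from(w, w)
  m <- network_model("atl2")
  m <- add_population(m, NULL, "alpha", 1)
  m <- add_population(m, NULL, "R_2", 1)
  m$projections[[1]] <- list(name = "bad", source = "alpha", target = "R_2",
                             pattern = conn_atlas(ar),
                             weight = dist_constant(1),
                             delay = dist_constant(1), auto = FALSE)
  inst <- list(model = m,
               gid_ranges = data.frame(population = c("alpha", "R_2"),
                                       first = 0:1, last = 1:2),
               device_ids = integer(0), total_neurons = 2L, seed = 0L)
  class(inst) <- "network_instance"
  expect_error(expand_atlas_projection(inst, m$projections[[1]]),
               class = "csanet_validation_error")
})

test_that("streamed blocks concatenate to the full connection list", {
  for (seed in c(2, 9)) {
    m <- two_pop_model(12L, 9L, conn_fixed_probability(0.5),
                       dist_gaussian(1, 0.1), dist_uniform(0.5, 1.5))
    inst <- instantiate_network(m, seed = seed)
    full <- generate_projection(inst, m$projections[[1]])
    for (bs in c(1L, 7L, 10000L)) {
      it <- stream_connections(inst, m$projections[[1]], block_size = bs)
      blocks <- list()
      while (!is.null(b <- it$next_block())) {
        expect_lte(nrow(b), bs)
        blocks[[length(blocks) + 1L]] <- b
      }
      got <- do.call(rbind, blocks)
      rownames(got) <- NULL
      expect_equal(got, full)
      if (bs == 10000L) expect_length(blocks, 1L)
      if (bs == 1L) expect_length(blocks, nrow(full))
    }
  }
})

test_that("per-projection streams are isolated from one another", {
  m <- network_model("iso")
  m <- add_population(m, NULL, "A", 30)
  m <- add_population(m, NULL, "B", 30)
  m <- connect(m, "A", "B", conn_fixed_probability(0.2), name = "keep")
  m_plus <- connect(m, "B", "A", conn_fixed_probability(0.2), name = "extra")
  c1 <- generate_projection(instantiate_network(m, seed = 4), "keep")
  c2 <- generate_projection(instantiate_network(m_plus, seed = 4), "keep")
  expect_identical(c1, c2)
})

test_that("exports are deterministic and include manifest metadata", {
  m <- two_pop_model(8L, 8L, conn_fixed_probability(0.4),
                     dist_gaussian(0.5, 0.05), dist_uniform(1, 2))
  inst <- instantiate_network(m, seed = 21)
  conns <- generate_network(inst)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  export_connection_list(inst, conns, d1)
  export_connection_list(inst, conns, d2)
  f1 <- list.files(d1)
  expect_setequal(f1, c("connections_A__to__B.csv", "manifest.yaml"))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  man <- yaml::read_yaml(file.path(d1, "manifest.yaml"))
  expect_equal(man$seed, 21L)
  expect_equal(man$populations[[2]]$first_gid, 8L)

  # empty connection list -> header-only csv
  e <- list(nothing = csanet:::empty_connections())
  export_connection_list(inst, e, d1)
  expect_equal(readLines(file.path(d1, "connections_nothing.csv")),
               "pre_gid,post_gid,weight,delay")
})

test_that("delays drawn below zero are clamped to stay positive", {
  m <- two_pop_model(20L, 20L, conn_all_to_all(),
                     delay = dist_gaussian(0.01, 1))
  conns <- generate_projection(instantiate_network(m, seed = 2),
                               m$projections[[1]])
  expect_true(all(conns$delay > 0))
})
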