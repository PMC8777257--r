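# Model fixtures built in code.

# three-root hierarchy used across core tests:
# SP_0 { SP_0_0 {A0 A1} SP_0_1 {B0 B1} }  SP_1 {C0 C1}  SP_2 {D0 D1}
# all leaf sizes 100, so SP_0 holds twice the neurons of each sibling
hierarchy_fixture <- function() {
  m <- network_model("hier")
  m <- add_super_population(m, NULL, "SP", 3L)
  m <- add_super_population(m, "SP_0", "SP_0", 2L)
  for (nm in c("A0", "A1")) m <- add_population(m, "SP_0_0", nm, 100)
  for (nm in c("B0", "B1")) m <- add_population(m, "SP_0_1", nm, 100)
  for (nm in c("C0", "C1")) m <- add_population(m, "SP_1", nm, 100)
  for (nm in c("D0", "D1")) m <- add_population(m, "SP_2", nm, 100)
  m
}

# custom atlas archive from explicit matrices
atlas_archive_from <- function(weights, tract_lengths,
                               path = tempfile(fileext = ".zip")) {
  staging <- tempfile("atlasfix_")
  dir.create(staging)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  wl <- apply(weights, 1, function(r) paste(r, collapse = ","))
  tl <- apply(tract_lengths, 1, function(r) paste(r, collapse = ","))
  writeLines(wl, file.path(staging, "weights.txt"))
  writeLines(tl, file.path(staging, "tract_lengths.txt"))
  zip::zip(path, files = c("weights.txt", "tract_lengths.txt"),
           root = staging)
  path
}

# JSON text as canonical form for whole-model equality
model_signature <- function(m) as.character(export_json(m))

# property-style random model generator: depth <= 4, <= 40 entities,
# random projections/devices/translators; no atlas patterns (those need an
# archive on disk and indexed names, covered by dedicated tests)
random_model <- function(seed) {
  csanet:::with_seed(seed, {
    m <- network_model(paste0("rand_", seed))
    leaves <- character(0)
    n_groups <- sample(0:4, 1)
    parents <- c(NA)
    groups <- character(0)
    for (g in seq_len(n_groups)) {
      parent <- sample(c(NA, groups), 1)
      nm <- paste0("G", g)
      m <- add_super_population(m, if (is.na(parent)) NULL else parent,
                                nm, 1L, indexed = FALSE)
      groups <- c(groups, nm)
    }
    n_pops <- sample(1:8, 1)
    for (p in seq_len(n_pops)) {
      parent <- sample(c(NA, groups), 1)
      nm <- paste0("P", p)
      size <- sample(1:20, 1)
      positions <- NULL
      r <- stats::runif(1)
      if (r < 0.2) {
        positions <- position_explicit(matrix(stats::rnorm(size * 2), size))
      } else if (r < 0.35) {
        positions <- position_template(dist_gaussian(0, 50), dim = 2L)
      }
      m <- add_population(m, if (is.na(parent)) NULL else parent, nm, size,
                          cell_model = sample(c("iaf", "nmm kuramoto"), 1),
                          positions = positions)
      leaves <- c(leaves, nm)
    }
    if (stats::runif(1) < 0.5) {
      m <- add_input_device(m, "in_0", rate = stats::runif(1, 0, 100),
                            targets = sample(leaves, 1))
    }
    if (stats::runif(1) < 0.3) {
      m <- add_output_device(m, "out_0", sources = sample(leaves, 1))
    }
    if (stats::runif(1) < 0.3) {
      m <- add_translator(m, "tr_0",
                          kind = sample(c("spike_to_rate",
                                          "rate_to_spike"), 1))
    }
    n_proj <- sample(0:6, 1)
    for (k in seq_len(n_proj)) {
      ends <- sample(leaves, 2, replace = TRUE)
      pat <- switch(sample(4, 1),
        conn_all_to_all(),
        conn_one_to_one(),
        conn_fixed_probability(round(stats::runif(1), 3)),
        conn_per_cell(1L))
      wgt <- switch(sample(3, 1),
        dist_constant(round(stats::runif(1, -5, 5), 4)),
        dist_gaussian(round(stats::runif(1, -5, 5), 4),
                      round(stats::runif(1, 0, 2), 4)),
        dist_uniform(0, round(stats::runif(1, 0, 2), 4)))
      m <- connect(m, ends[1], ends[2], pattern = pat, weight = wgt,
                   delay = dist_constant(round(stats::runif(1, 0.1, 3), 4)),
                   auto = ends[1] == ends[2])
    }
    attr(m, "created") <- NULL
    m
  })
}
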