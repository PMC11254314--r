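small_config <- function(seed = 1L, ...) {
  simulation_config(seed = seed, n_pathways = 4L,
                    chain_length_range = c(3L, 5L), n_planted_pairs = 3L,
                    n_planted_relations = 4L, noise_genes = 3L,
                    noise_proteins = 3L, noise_metabolites = 3L, ...)
}

run_pipeline <- function(cfg) {
  kb <- simulate_kb(cfg)
  sim <- simulate_tables(cfg, kb)
  fit <- integrate_multiomics(sim$genes, sim$proteins, sim$metabolites, kb)
  list(kb = kb, sim = sim, fit = fit)
}

test_that("generation is deterministic given the seed", {
  cfg <- small_config(seed = 99L)
  kb1 <- simulate_kb(cfg); kb2 <- simulate_kb(cfg)
  expect_identical(kb1, kb2)
  s1 <- simulate_tables(cfg, kb1); s2 <- simulate_tables(cfg, kb2)
  expect_identical(s1, s2)
  # and the emitted files are byte-identical
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_differential_table(s1$genes, f1)
  write_differential_table(s2$genes, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed changes the draw
  expect_false(identical(s1, simulate_tables(small_config(seed = 100L), kb1)))
})

test_that("degenerate configurations are rejected and empty ones allowed", {
  expect_error(simulation_config(chain_length_range = c(1L, 3L)),
               "chain_length_range")
  kb0 <- simulate_kb(simulation_config(n_pathways = 0L))
  expect_equal(nrow(kb0$pathways), 0L)
  cfg_big <- small_config()
  cfg_big$n_planted_pairs <- 1000L
  expect_error(simulate_tables(cfg_big, simulate_kb(cfg_big)),
               "infeasible plant count")
})

test_that("a simulated KB round-trips through the on-disk formats", {
  kb <- simulate_kb(small_config(seed = 3L))
  mem <- withr::local_tempfile(fileext = ".tsv")
  edg <- withr::local_tempfile(fileext = ".tsv")
  write_kb(kb, mem, edg)
  back <- load_kb(mem, edg)
  expect_equal(back$edges, kb$edges)
  expect_setequal(back$pathways$pathway_id, kb$pathways$pathway_id)
})

test_that("every planted relation is realizable by the reachability query", {
  for (seed in 1:5) {
    cfg <- small_config(seed = seed)
    kb <- simulate_kb(cfg)
    sim <- simulate_tables(cfg, kb)
    rel <- sim$truth$relations
    for (i in seq_len(nrow(rel))) {
      expect_true(has_upstream_downstream(kb, rel$pathway_id[i],
                                          rel$gene_id[i],
                                          rel$metabolite_id[i]),
                  info = sprintf("seed %d relation %d", seed, i))
    }
  }
})

test_that("forcing protein-direction flips removes every planted pair", {
  cfg <- small_config(seed = 12L, p_direction_flip = 1)
  kb <- simulate_kb(cfg)
  sim <- simulate_tables(cfg, kb)
  expect_equal(nrow(sim$truth$pairs), 0L)
  pairs <- screen_all_groups(sim$genes, sim$proteins)
  # no planted pair survives; noise layers use disjoint id pools
  expect_equal(nrow(pairs), 0L)
})

test_that("noise-free instances are recovered perfectly", {
  for (seed in 1:8) {
    cfg <- simulation_config(seed = seed, n_pathways = 4L,
                             chain_length_range = c(3L, 5L),
                             n_planted_pairs = 3L, n_planted_relations = 4L,
                             noise_genes = 0L, noise_proteins = 0L,
                             noise_metabolites = 0L)
    out <- run_pipeline(cfg)
    scores <- evaluate_recovery(out$fit, out$sim$truth)
    expect_equal(scores$precision, rep(1, 3), info = paste("seed", seed))
    expect_equal(scores$recall, rep(1, 3), info = paste("seed", seed))
  }
})

test_that("noisy instances keep perfect precision on relations by construction", {
  # noise is rejection-sampled away from planted downstream sets, so the
  # relation layer stays exact even with noise present
  for (seed in c(2L, 21L, 33L)) {
    out <- run_pipeline(small_config(seed = seed))
    scores <- evaluate_recovery(out$fit, out$sim$truth)
    rel <- scores[scores$layer == "relations", ]
    expect_equal(rel$precision, 1)
    expect_equal(rel$recall, 1)
  }
})

test_that("recovery scoring follows the stated conventions", {
  truth <- list(
    pairs = data.frame(gene_id = "g1", dose = 100, time = 12,
                       direction = "up", group = "100uM-12h"),
    relations = data.frame(dose = 100, time = 12, pathway_id = c("p", "p"),
                           gene_id = "g1", metabolite_id = c("m1", "m2"),
                           group = "100uM-12h"),
    subnetworks = list(c("pair:g1", "met:m1", "met:m2", "pw:p")))
  fake_fit <- list(
    pairs = data.frame(gene_id = "g1", group = "100uM-12h",
                       direction = "up"),
    catalogue = data.frame(group = "100uM-12h", pathway_id = "p",
                           gene_id = "g1",
                           metabolite_id = c("m1", "m2", "m3")),
    subnetworks = {
      sn <- data.frame(label = "A", n_pairs = 1L, n_metabolites = 3L,
                       n_pathways = 1L)
      sn$pairs <- list("g1/G1")
      sn$metabolites <- list(c("m1", "m2", "m3"))
      sn$pathways <- list("p")
      sn
    })
  scores <- evaluate_recovery(fake_fit, truth)
  rel <- scores[scores$layer == "relations", ]
  expect_equal(rel$precision, 2 / 3)
  expect_equal(rel$recall, 1)

  empty_fit <- list(
    pairs = data.frame(gene_id = character(), group = character(),
                       direction = character()),
    catalogue = data.frame(group = character(), pathway_id = character(),
                           gene_id = character(),
                           metabolite_id = character()),
    subnetworks = {
      sn <- data.frame(label = character(), n_pairs = integer(),
                       n_metabolites = integer(), n_pathways = integer())
      sn$pairs <- list(); sn$metabolites <- list(); sn$pathways <- list()
      sn
    })
  w <- capture_warnings(scores0 <- evaluate_recovery(empty_fit, truth))
  expect_true(all(grepl("no predictions", w)))
  expect_length(w, 3)
  expect_equal(scores0$precision, rep(1, 3))
  expect_equal(scores0$recall, rep(0, 3))
})
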