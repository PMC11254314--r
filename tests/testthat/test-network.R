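test_that("fixture network has the expected tripartite composition", {
  fit <- fixture_fit()
  g <- fit$network
  type <- igraph::vertex_attr(g, "type")
  expect_equal(sum(type == "pair"), 6L)
  expect_equal(sum(type == "metabolite"), 13L)
  expect_equal(sum(type == "pathway"), 7L)
  # strictly tripartite: no edge joins two nodes of the same type
  el <- igraph::as_edgelist(g)
  t_of <- stats::setNames(type, igraph::vertex_attr(g, "name"))
  expect_false(any(t_of[el[, 1]] == t_of[el[, 2]]))
})

test_that("decomposition yields six ranked subnetworks, top one (1, 4, 2)", {
  fit <- fixture_fit()
  sn <- fit$subnetworks
  expect_equal(nrow(sn), 6L)
  expect_equal(sn$label, LETTERS[1:6])
  expect_equal(sn$n_pairs, rep(1L, 6))
  expect_equal(sn$n_metabolites, c(4L, 3L, 3L, 1L, 1L, 1L))
  expect_equal(sn$n_pathways, c(2L, 1L, 1L, 1L, 1L, 1L))
  expect_setequal(sn$pathways[[1]], c("purine", "pyrimidine"))
  # components partition the node set
  expect_equal(sum(sn$n_pairs + sn$n_metabolites + sn$n_pathways),
               igraph::vcount(fit$network))
  all_nodes <- unlist(c(sn$pairs, sn$metabolites, sn$pathways))
  expect_false(any(duplicated(all_nodes)))
})

test_that("candidate biomarkers are the top subnetwork's pair and metabolites", {
  fit <- fixture_fit()
  cand <- fit$candidates
  expect_equal(cand$gene_ids, "Rrm2")
  expect_equal(cand$protein_ids, "RRM2")
  expect_setequal(cand$metabolite_ids,
                  c("uric acid", "dgmp", "dump", "uridine"))
  expect_equal(cand$subnetwork, "A")
})

test_that("a single relation gives one (1, 1, 1) subnetwork; empty input gives none", {
  cat1 <- data.frame(dose = 100, time = 12, group = "100uM-12h",
                     pathway_id = "pw", gene_id = "G1", protein_id = "G1P",
                     metabolite_id = "m1", gene_direction = "up",
                     metabolite_direction = "up", hops = 1L,
                     stringsAsFactors = FALSE)
  sn <- decompose_network(build_network(cat1))
  expect_equal(nrow(sn), 1L)
  expect_equal(unlist(sn[1, c("n_pairs", "n_metabolites", "n_pathways")],
                      use.names = FALSE), c(1L, 1L, 1L))
  cand <- extract_candidates(sn)
  expect_equal(cand$gene_ids, "G1")
  expect_equal(cand$metabolite_ids, "m1")

  empty <- build_network(cat1[0, ])
  expect_equal(igraph::vcount(empty), 0L)
  cand0 <- extract_candidates(decompose_network(empty))
  expect_length(cand0$gene_ids, 0)
  expect_true(is.na(cand0$subnetwork))
  expect_output(print(cand0), "no candidates")
})

test_that("entities seen in several groups merge into one node with provenance", {
  cat2 <- data.frame(
    dose = c(100, 200), time = c(24, 48),
    group = c("100uM-24h", "200uM-48h"),
    pathway_id = c("pwA", "pwB"), gene_id = "Mat2a", protein_id = "MAT2A",
    metabolite_id = c("m1", "m2"), gene_direction = "down",
    metabolite_direction = "down", hops = 1L, stringsAsFactors = FALSE)
  g <- build_network(cat2)
  type <- igraph::vertex_attr(g, "type")
  expect_equal(sum(type == "pair"), 1L)
  prov <- igraph::vertex_attr(g, "groups")[type == "pair"]
  expect_equal(prov, "100uM-24h,200uM-48h")
  # both groups fall into one subnetwork through the shared pair
  expect_equal(nrow(decompose_network(g)), 1L)
})

test_that("decomposition agrees with a union-find oracle on random networks", {
  set.seed(31)
  for (i in 1:15) {
    n_rel <- sample(1:30, 1)
    cat <- data.frame(
      dose = 100, time = 12, group = "100uM-12h",
      pathway_id = sprintf("pw%d", sample(1:8, n_rel, replace = TRUE)),
      gene_id = sprintf("g%d", sample(1:10, n_rel, replace = TRUE)),
      protein_id = "x", metabolite_id = sprintf("m%d", sample(1:12, n_rel,
                                                              replace = TRUE)),
      gene_direction = "up", metabolite_direction = "up", hops = 1L,
      stringsAsFactors = FALSE)
    cat$protein_id <- toupper(cat$gene_id)
    g <- build_network(cat)
    sn <- decompose_network(g)
    got <- lapply(seq_len(nrow(sn)), function(k)
      sort(c(paste0("pair:", tolower(sub("/.*", "", sn$pairs[[k]]))),
             paste0("met:", sn$metabolites[[k]]),
             paste0("pw:", sn$pathways[[k]]))))
    got <- got[order(vapply(got, `[`, character(1), 1))]
    want <- oracle_components(
      from = c(paste0("pair:", tolower(cat$gene_id)),
               paste0("met:", cat$metabolite_id),
               paste0("pair:", tolower(cat$gene_id))),
      to = c(paste0("pw:", cat$pathway_id), paste0("pw:", cat$pathway_id),
             paste0("met:", cat$metabolite_id)))
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("network exports produce well-formed SIF and GraphML", {
  fit <- fixture_fit()
  sif <- withr::local_tempfile(fileext = ".sif")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(fit$network, sif, "sif")
  write_network(fit$network, gml, "graphml")
  lines <- readLines(sif)
  expect_equal(length(lines), igraph::ecount(fit$network))
  expect_true(all(grepl("\t(pair|metabolite|pathway)-(pair|metabolite|pathway)\t",
                        lines)))
  expect_true(any(grepl("graphml", readLines(gml, n = 5))))
})
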