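fixture_inputs <- function() {
  list(
    genes = read_differential_table(extdata("fixture_genes.tsv"), "gene"),
    proteins = read_differential_table(extdata("fixture_proteins.tsv"),
                                       "protein"),
    metabolites = read_differential_table(extdata("fixture_metabolites.tsv"),
                                          "metabolite"),
    kb = load_kb(extdata("fixture_kb_membership.tsv"),
                 extdata("fixture_kb_edges.tsv"))
  )
}

test_that("the high-dose 12 h group maps to four pathways, all with relations", {
  fx <- fixture_inputs()
  pairs <- screen_all_groups(fx$genes, fx$proteins)
  hits <- map_group(pairs, fx$metabolites, fx$kb, 200, 12)
  expect_length(hits, 4)
  expect_true(all(vapply(hits, `[[`, logical(1), "has_relation")))
  expect_setequal(vapply(hits, `[[`, character(1), "pathway_id"),
                  c("purine", "pyrimidine", "amino_sugar", "porphyrin"))
  # ordering: most relations first (pyrimidine has two links)
  expect_equal(hits[[1]]$pathway_id, "pyrimidine")
})

test_that("a group with no differential metabolites maps to nothing", {
  fx <- fixture_inputs()
  pairs <- screen_all_groups(fx$genes, fx$proteins)
  empty_mets <- differential_table(character(), numeric(), numeric(),
                                   character(), "metabolite")
  expect_length(map_group(pairs, empty_mets, fx$kb, 100, 12), 0)
})

test_that("per-group summaries reproduce the joint and relation pathway counts", {
  fx <- fixture_inputs()
  pairs <- screen_all_groups(fx$genes, fx$proteins)
  hits <- map_all_groups(pairs, fx$metabolites, fx$kb)
  sm <- summarize_groups(hits, fx$metabolites)
  expect_equal(sm$group,
               c("100uM-12h", "100uM-24h", "100uM-48h",
                 "200uM-12h", "200uM-24h", "200uM-48h"))
  expect_equal(sm$n_joint_pathways, c(4L, 2L, 0L, 4L, 2L, 2L))
  expect_equal(sm$n_relation_pathways, c(2L, 1L, 0L, 4L, 0L, 2L))
  expect_true(all(sm$n_relation_pathways <= sm$n_joint_pathways))
})

test_that("the relation catalogue matches the worked example in full", {
  fx <- fixture_inputs()
  pairs <- screen_all_groups(fx$genes, fx$proteins)
  cat <- collect_relation_catalogue(map_all_groups(pairs, fx$metabolites,
                                                   fx$kb))
  expect_equal(nrow(cat), 13L)
  expect_equal(length(unique(paste(cat$group, cat$pathway_id))), 9L)
  expect_equal(length(unique(cat$pathway_id)), 7L)
  expect_equal(length(unique(tolower(cat$gene_id))), 6L)
  expect_equal(length(unique(cat$metabolite_id)), 13L)
  expect_false(any(duplicated(paste(cat$group, cat$pathway_id,
                                    tolower(cat$gene_id),
                                    cat$metabolite_id))))
  # spot checks against the transcribed rows
  expect_true(any(cat$group == "100uM-12h" & cat$pathway_id == "purine" &
                    cat$gene_id == "Rrm2" & cat$metabolite_id == "uric acid" &
                    cat$gene_direction == "up" &
                    cat$metabolite_direction == "up"))
  expect_true(any(cat$group == "200uM-12h" & cat$pathway_id == "pyrimidine" &
                    cat$metabolite_id == "uridine" &
                    cat$metabolite_direction == "down"))
  expect_true(all(cat$hops >= 1))
})

test_that("removing a metabolite never increases any count", {
  fx <- fixture_inputs()
  pairs <- screen_all_groups(fx$genes, fx$proteins)
  base <- summarize_groups(map_all_groups(pairs, fx$metabolites, fx$kb),
                           fx$metabolites)
  for (drop_id in c("uridine", "uric acid", "l-glutamate")) {
    keep <- fx$metabolites$id != drop_id
    mets2 <- differential_table(fx$metabolites$id[keep],
                                fx$metabolites$dose[keep],
                                fx$metabolites$time[keep],
                                fx$metabolites$direction[keep], "metabolite")
    sm2 <- summarize_groups(map_all_groups(pairs, mets2, fx$kb), mets2)
    m <- match(sm2$group, base$group)
    expect_true(all(sm2$n_joint_pathways <= base$n_joint_pathways[m]))
    expect_true(all(sm2$n_relation_pathways <= base$n_relation_pathways[m]))
    expect_true(all(sm2$n_differential_metabolites <=
                      base$n_differential_metabolites[m]))
  }
})

test_that("max_hops = 1 keeps only directly adjacent relations", {
  fx <- fixture_inputs()
  pairs <- screen_all_groups(fx$genes, fx$proteins)
  cat1 <- collect_relation_catalogue(
    map_all_groups(pairs, fx$metabolites, fx$kb, max_hops = 1))
  # only the thioesterase product sits a single reaction step downstream
  expect_equal(cat1$metabolite_id, "palmitic acid")
  expect_equal(cat1$hops, 1L)
  catI <- collect_relation_catalogue(map_all_groups(pairs, fx$metabolites,
                                                    fx$kb))
  expect_equal(sum(catI$hops == 1), 1L)
  expect_equal(max(catI$hops), 6L) # deepest: sulfinylpyruvate below Mat2a
})
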