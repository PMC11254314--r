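# Independent oracles used to cross-check the implementation. Each is a
# deliberately naive algorithm kept free of the package's own code paths.

extdata <- function(name) {
  p <- system.file("extdata", name, package = "triomics")
  if (!nzchar(p)) stop("missing fixture: ", name)
  p
}

fixture_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- integrate_multiomics(
        genes = extdata("fixture_genes.tsv"),
        proteins = extdata("fixture_proteins.tsv"),
        metabolites = extdata("fixture_metabolites.tsv"),
        kb = c(extdata("fixture_kb_membership.tsv"),
               extdata("fixture_kb_edges.tsv")),
        phenotype = extdata("fixture_phenotype.tsv"))
    }
    cache
  }
})

# brute-force path enumeration by iterated edge relaxation: after k rounds
# the set holds every node reachable by a path of <= k edges whose first
# edge is catalysed by the gene (equivalent to enumerating all paths, but
# terminates on cyclic graphs)
oracle_reachable <- function(edges, gene, max_hops = Inf) {
  # edges: data.frame(source, target, catalysts = list of character vectors)
  first <- vapply(edges$catalysts, function(cs)
    tolower(gene) %in% tolower(cs), logical(1))
  reach <- unique(edges$target[first])
  n <- length(unique(c(edges$source, edges$target)))
  rounds <- min(max_hops, n) - 1
  k <- 0
  while (k < rounds) {
    k <- k + 1
    nxt <- union(reach, edges$target[edges$source %in% reach])
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  sort(reach)
}

# quadratic double loop over all gene x protein combinations
oracle_screen <- function(g_ids, g_dir, p_ids, p_dir) {
  hits <- character()
  for (i in seq_along(g_ids)) {
    for (j in seq_along(p_ids)) {
      if (tolower(g_ids[i]) == tolower(p_ids[j]) && g_dir[i] == p_dir[j]) {
        hits <- c(hits, g_ids[i])
      }
    }
  }
  sort(unique(tolower(hits)))
}

# union-find over an undirected edge list; returns membership as a list of
# sorted node-name vectors (sorted by their first element)
oracle_components <- function(from, to, nodes = sort(unique(c(from, to)))) {
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) { while (parent[[i]] != i) i <- parent[[i]]; i }
  for (k in seq_along(from)) {
    a <- find(match(from[k], nodes)); b <- find(match(to[k], nodes))
    if (a != b) parent[[b]] <- a
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  comps <- lapply(split(nodes, roots), sort)
  comps[order(vapply(comps, `[`, character(1), 1))]
}

# closed-form product-moment coefficient written out longhand
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# random directed graph over n nodes as an edge data frame with catalyst sets
random_reaction_graph <- function(n_nodes, n_edges, n_genes = 3) {
  nodes <- sprintf("m%02d", seq_len(n_nodes))
  genes <- sprintf("gene%d", seq_len(n_genes))
  src <- sample(nodes, n_edges, replace = TRUE)
  tgt <- sample(nodes, n_edges, replace = TRUE)
  keep <- src != tgt
  src <- src[keep]; tgt <- tgt[keep]
  dup <- duplicated(paste(src, tgt))
  src <- src[!dup]; tgt <- tgt[!dup]
  cats <- lapply(seq_along(src), function(i) {
    k <- sample(0:2, 1)
    if (k == 0) character() else sample(genes, k)
  })
  data.frame(source = src, target = tgt,
             catalysts = I(cats), stringsAsFactors = FALSE)
}

# wrap a random reaction graph into a single-pathway KB
kb_from_edges <- function(edges, genes) {
  mets <- sort(unique(c(edges$source, edges$target)))
  pathway_kb(
    data.frame(pathway_id = "P1", name = "random", stringsAsFactors = FALSE),
    rbind(data.frame(pathway_id = "P1", kind = "metabolite", id = mets,
                     stringsAsFactors = FALSE),
          data.frame(pathway_id = "P1", kind = "gene", id = genes,
                     stringsAsFactors = FALSE)),
    data.frame(pathway_id = "P1", source = edges$source,
               target = edges$target,
               catalyst_genes = vapply(edges$catalysts, paste,
                                       character(1), collapse = ","),
               stringsAsFactors = FALSE))
}
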