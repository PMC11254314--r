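# Tripartite pair-metabolite-pathway network. Each relation link contributes
# a pair node, a metabolite node and a pathway node plus the three pairwise
# (undirected) edges between them; identical entities observed in different
# treatment groups merge into one node, with group provenance kept as a node
# attribute. Subnetworks are the connected components, ranked by composition.

pair_node_key <- function(gene_id) paste0("pair:", tolower(gene_id))
met_node_key <- function(metabolite_id) paste0("met:", metabolite_id)
pw_node_key <- function(pathway_id) paste0("pw:", pathway_id)

#' Build the tripartite network from a relation catalogue
#'
#' @param catalogue relation catalogue from
#'   \code{\link{collect_relation_catalogue}}.
#' @return an \code{igraph} graph with vertex attributes \code{type}
#'   (\code{"pair"}, \code{"metabolite"}, \code{"pathway"}), \code{label}
#'   (display name; \code{gene/PROTEIN} for pair nodes) and \code{groups}
#'   (comma-separated provenance).
#' @export
build_network <- function(catalogue) {
  if (nrow(catalogue) == 0L) {
    g <- igraph::make_empty_graph(directed = FALSE)
    g <- igraph::set_vertex_attr(g, "type", value = character(0))
    return(g)
  }
  pairs <- unique(data.frame(key = pair_node_key(catalogue$gene_id),
                             label = paste0(catalogue$gene_id, "/",
                                            catalogue$protein_id),
                             stringsAsFactors = FALSE))
  pairs <- pairs[!duplicated(pairs$key), , drop = FALSE]
  mets <- unique(data.frame(key = met_node_key(catalogue$metabolite_id),
                            label = catalogue$metabolite_id,
                            stringsAsFactors = FALSE))
  pws <- unique(data.frame(key = pw_node_key(catalogue$pathway_id),
                           label = catalogue$pathway_id,
                           stringsAsFactors = FALSE))
  nodes <- rbind(cbind(pairs, type = "pair"),
                 cbind(mets, type = "metabolite"),
                 cbind(pws, type = "pathway"))
  # group provenance per node
  prov <- rbind(
    data.frame(key = pair_node_key(catalogue$gene_id), group = catalogue$group),
    data.frame(key = met_node_key(catalogue$metabolite_id), group = catalogue$group),
    data.frame(key = pw_node_key(catalogue$pathway_id), group = catalogue$group)
  )
  grp <- tapply(prov$group, prov$key,
                function(g) paste(sort(unique(g)), collapse = ","))
  nodes$groups <- unname(grp[nodes$key])

  pk <- pair_node_key(catalogue$gene_id)
  mk <- met_node_key(catalogue$metabolite_id)
  wk <- pw_node_key(catalogue$pathway_id)
  edges <- unique(rbind(data.frame(from = pk, to = wk),
                        data.frame(from = mk, to = wk),
                        data.frame(from = pk, to = mk)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  igraph::simplify(g, edge.attr.comb = "first")
}

subnetwork_label <- function(i) {
  if (i <= 26L) LETTERS[i] else paste0("S", i)
}

#' Decompose the tripartite network into ranked subnetworks
#'
#' Connected components, ranked by number of metabolites (descending), then
#' pathways, then pairs, then the lexicographically smallest gene id, and
#' labelled A, B, ... in rank order.
#'
#' @param network graph from \code{\link{build_network}}.
#' @return data frame with columns \code{label}, \code{n_pairs},
#'   \code{n_metabolites}, \code{n_pathways} and list-columns \code{pairs},
#'   \code{metabolites}, \code{pathways} holding the member labels.
#' @export
decompose_network <- function(network) {
  empty <- data.frame(label = character(), n_pairs = integer(),
                      n_metabolites = integer(), n_pathways = integer(),
                      stringsAsFactors = FALSE)
  empty$pairs <- list(); empty$metabolites <- list(); empty$pathways <- list()
  if (igraph::vcount(network) == 0L) return(empty)

  comp <- igraph::components(network)
  type <- igraph::vertex_attr(network, "type")
  label <- igraph::vertex_attr(network, "label")
  name <- igraph::vertex_attr(network, "name")

  rows <- lapply(seq_len(comp$no), function(ci) {
    sel <- comp$membership == ci
    prs <- sort(label[sel & type == "pair"])
    ms <- sort(label[sel & type == "metabolite"])
    ws <- sort(label[sel & type == "pathway"])
    min_gene <- if (length(prs)) min(sub("^pair:", "", name[sel & type == "pair"])) else ""
    list(n_pairs = length(prs), n_metabolites = length(ms),
         n_pathways = length(ws), min_gene = min_gene,
         pairs = prs, metabolites = ms, pathways = ws)
  })
  n_m <- vapply(rows, `[[`, integer(1), "n_metabolites")
  n_w <- vapply(rows, `[[`, integer(1), "n_pathways")
  n_p <- vapply(rows, `[[`, integer(1), "n_pairs")
  mg <- vapply(rows, `[[`, character(1), "min_gene")
  ord <- order(-n_m, -n_w, -n_p, mg)
  rows <- rows[ord]
  out <- data.frame(
    label = vapply(seq_along(rows), subnetwork_label, character(1)),
    n_pairs = vapply(rows, `[[`, integer(1), "n_pairs"),
    n_metabolites = vapply(rows, `[[`, integer(1), "n_metabolites"),
    n_pathways = vapply(rows, `[[`, integer(1), "n_pathways"),
    stringsAsFactors = FALSE
  )
  out$pairs <- lapply(rows, `[[`, "pairs")
  out$metabolites <- lapply(rows, `[[`, "metabolites")
  out$pathways <- lapply(rows, `[[`, "pathways")
  out
}

#' Extract candidate biomarkers from the top-ranked subnetwork
#'
#' The candidate set is every gene/protein pair and metabolite of the
#' top-ranked subnetwork. An empty decomposition yields an explicit empty
#' candidate set, not an error.
#'
#' @param subnetworks decomposition from \code{\link{decompose_network}}.
#' @param rank which subnetwork to extract (default 1, the top).
#' @return a \code{biomarker_set}: list with \code{gene_ids},
#'   \code{protein_ids}, \code{metabolite_ids} and \code{subnetwork} label
#'   (\code{NA} when empty).
#' @export
extract_candidates <- function(subnetworks, rank = 1L) {
  if (nrow(subnetworks) < rank) {
    return(structure(list(gene_ids = character(), protein_ids = character(),
                          metabolite_ids = character(), subnetwork = NA_character_),
                     class = "biomarker_set"))
  }
  prs <- subnetworks$pairs[[rank]]
  split_pairs <- strsplit(prs, "/", fixed = TRUE)
  structure(list(
    gene_ids = vapply(split_pairs, `[[`, character(1), 1L),
    protein_ids = vapply(split_pairs, function(p) p[length(p)], character(1)),
    metabolite_ids = subnetworks$metabolites[[rank]],
    subnetwork = subnetworks$label[rank]
  ), class = "biomarker_set")
}

#' @export
print.biomarker_set <- function(x, ...) {
  if (!length(x$gene_ids) && !length(x$metabolite_ids)) {
    cat("biomarker_set: no candidates\n")
    return(invisible(x))
  }
  cat("Candidate biomarkers (subnetwork ", x$subnetwork, "):\n", sep = "")
  cat("  genes:      ", paste(x$gene_ids, collapse = ", "), "\n", sep = "")
  cat("  proteins:   ", paste(x$protein_ids, collapse = ", "), "\n", sep = "")
  cat("  metabolites:", paste(x$metabolite_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Export the tripartite network
#'
#' SIF (\code{pair-pathway}, \code{metabolite-pathway},
#' \code{pair-metabolite} interaction labels) or GraphML with node-type and
#' group-provenance attributes.
#'
#' @param network graph from \code{\link{build_network}}.
#' @param path output file.
#' @param format \code{"sif"} or \code{"graphml"}.
#' @return \code{path}, invisibly.
#' @export
write_network <- function(network, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_edgelist(network)
  type <- stats::setNames(igraph::vertex_attr(network, "type"),
                          igraph::vertex_attr(network, "name"))
  lab <- stats::setNames(igraph::vertex_attr(network, "label"),
                         igraph::vertex_attr(network, "name"))
  inter <- paste0(type[el[, 1]], "-", type[el[, 2]])
  writeLines(sprintf("%s\t%s\t%s", lab[el[, 1]], inter, lab[el[, 2]]), path)
  invisible(path)
}
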