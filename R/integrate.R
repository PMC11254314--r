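# End-to-end integration: screen pairs, map groups onto the KB, catalogue
# upstream-downstream relations, build and decompose the tripartite network,
# extract candidate biomarkers, and (optionally) correlate per-group
# summaries with a phenotype series. One call, one classed result.

#' Integrate differential multiomics tables into candidate biomarkers
#'
#' The main fitting function. Takes per-group differential tables for the
#' three omics layers, a pathway knowledge base and optionally a phenotype
#' series, and runs the full integration: (1) gene/protein pairs with
#' direction-consistent differential expression per group; (2) joint pathway
#' mapping with upstream-downstream relation detection; (3) tripartite
#' pair-metabolite-pathway network, connected-subnetwork ranking, and
#' candidate extraction from the top subnetwork; (4) within-dose Pearson
#' correlation of the phenotype with three per-group indicators.
#'
#' @param genes,proteins,metabolites \code{differential_table}s (or paths to
#'   their TSV files).
#' @param kb a \code{pathway_kb} (or list of two paths
#'   \code{c(membership, edges)}).
#' @param phenotype optional \code{phenotype_series} (or path); doses with
#'   fewer than 3 time points are skipped with a warning.
#' @param mapping optional \code{\link{gene_protein_map}}; default pairs ids
#'   equal case-insensitively.
#' @param max_hops maximum reaction-path length for relation detection
#'   (default unbounded).
#' @param r_threshold,abs_r strong-correlation rule, see
#'   \code{\link{correlate_dose}}.
#' @return an object of class \code{triomics_fit}: list with elements
#'   \code{pairs}, \code{pair_counts}, \code{hits}, \code{summaries},
#'   \code{catalogue}, \code{network}, \code{subnetworks},
#'   \code{candidates}, \code{correlations} (or \code{NULL}) and
#'   \code{params}.
#' @examples
#' dir <- system.file("extdata", package = "triomics")
#' fit <- integrate_multiomics(
#'   genes = file.path(dir, "fixture_genes.tsv"),
#'   proteins = file.path(dir, "fixture_proteins.tsv"),
#'   metabolites = file.path(dir, "fixture_metabolites.tsv"),
#'   kb = c(file.path(dir, "fixture_kb_membership.tsv"),
#'          file.path(dir, "fixture_kb_edges.tsv")),
#'   phenotype = file.path(dir, "fixture_phenotype.tsv"))
#' fit
#' @export
integrate_multiomics <- function(genes, proteins, metabolites, kb,
                                 phenotype = NULL, mapping = NULL,
                                 max_hops = Inf, r_threshold = 0.8,
                                 abs_r = FALSE) {
  if (is.character(genes)) genes <- read_differential_table(genes, "gene")
  if (is.character(proteins)) proteins <- read_differential_table(proteins, "protein")
  if (is.character(metabolites))
    metabolites <- read_differential_table(metabolites, "metabolite")
  if (is.character(kb)) {
    stopifnot(length(kb) == 2L)
    kb <- load_kb(kb[1], kb[2])
  }
  if (is.character(phenotype)) phenotype <- read_phenotype_series(phenotype)
  if (is.character(mapping)) mapping <- read_gene_protein_map(mapping)

  pairs <- screen_all_groups(genes, proteins, mapping)
  pair_counts <- pair_counts_by_group(genes, proteins, mapping)
  hits <- map_all_groups(pairs, metabolites, kb, max_hops)
  summaries <- summarize_groups(hits, metabolites)
  catalogue <- collect_relation_catalogue(hits)
  network <- build_network(catalogue)
  subnetworks <- decompose_network(network)
  candidates <- extract_candidates(subnetworks)

  correlations <- NULL
  if (!is.null(phenotype) && nrow(phenotype)) {
    doses <- sort(unique(phenotype$dose))
    ok <- vapply(doses, function(d) sum(phenotype$dose == d) >= 3L, logical(1))
    if (any(!ok)) {
      warning("skipping correlation for dose(s) with < 3 time points: ",
              paste(doses[!ok], collapse = ", "), call. = FALSE)
    }
    if (any(ok)) {
      correlations <- do.call(rbind, lapply(doses[ok], function(d)
        correlate_dose(phenotype, summaries, d, r_threshold, abs_r)))
      rownames(correlations) <- NULL
    }
  }

  structure(list(
    pairs = pairs, pair_counts = pair_counts, hits = hits,
    summaries = summaries, catalogue = catalogue, network = network,
    subnetworks = subnetworks, candidates = candidates,
    correlations = correlations,
    params = list(max_hops = max_hops, r_threshold = r_threshold,
                  abs_r = abs_r, n_pathways_kb = nrow(kb$pathways))
  ), class = "triomics_fit")
}

#' @export
print.triomics_fit <- function(x, ...) {
  cat("Tripartite multiomics integration\n")
  cat(sprintf("  consistent gene/protein pairs: %d across %d group(s)\n",
              nrow(x$pairs), length(unique(x$pairs$group))))
  cat(sprintf("  relation links: %d (%d pathway(s), %d pair(s), %d metabolite(s))\n",
              nrow(x$catalogue), length(unique(x$catalogue$pathway_id)),
              length(unique(tolower(x$catalogue$gene_id))),
              length(unique(x$catalogue$metabolite_id))))
  cat(sprintf("  subnetworks: %d\n", nrow(x$subnetworks)))
  print(x$candidates)
  invisible(x)
}

#' @export
summary.triomics_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.triomics_fit")
}

#' @export
print.summary.triomics_fit <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nPer-group summaries:\n")
  print.data.frame(fit$summaries, row.names = FALSE)
  cat("\nSubnetworks:\n")
  print.data.frame(fit$subnetworks[, c("label", "n_pairs", "n_metabolites",
                                       "n_pathways")], row.names = FALSE)
  if (!is.null(fit$correlations)) {
    cat("\nPhenotype correlations (strong: r >",
        fit$params$r_threshold, "):\n")
    co <- fit$correlations
    co$r <- round(co$r, 3)
    print.data.frame(co, row.names = FALSE)
  }
  invisible(x)
}

#' Plot the tripartite network of a fit
#'
#' Pair nodes as squares, metabolites as circles, pathways as diamonds
#' (vertex shape \code{"rectangle"}/\code{"circle"}/\code{"crectangle"} via
#' igraph), coloured by type.
#'
#' @param x a \code{triomics_fit}.
#' @param ... passed to \code{plot.igraph}.
#' @export
plot.triomics_fit <- function(x, ...) {
  g <- x$network
  if (igraph::vcount(g) == 0L) {
    graphics::plot.new(); graphics::title("empty network")
    return(invisible(x))
  }
  type <- igraph::vertex_attr(g, "type")
  col <- c(pair = "#d95f02", metabolite = "#1b9e77", pathway = "#7570b3")[type]
  shape <- c(pair = "square", metabolite = "circle",
             pathway = "rectangle")[type]
  graphics::plot(g, vertex.color = col, vertex.shape = shape,
       vertex.label = igraph::vertex_attr(g, "label"),
       vertex.label.cex = 0.7, ...)
  invisible(x)
}

#' Write the full result bundle of a fit
#'
#' Deterministic TSV/JSON/SIF/GraphML outputs: pair table and counts,
#' per-group summaries, relation catalogue, subnetwork summary, candidate
#' biomarkers, correlation report (when computed) and the network exports.
#'
#' @param fit a \code{triomics_fit}.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_results <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    pairs = tsv(fit$pairs, "pairs.tsv"),
    pair_counts = tsv(fit$pair_counts, "pair_counts.tsv"),
    summaries = tsv(fit$summaries, "group_summaries.tsv"),
    catalogue = tsv(fit$catalogue, "relation_catalogue.tsv"),
    subnetworks = tsv(fit$subnetworks[, c("label", "n_pairs",
                                          "n_metabolites", "n_pathways")],
                      "subnetworks.tsv")
  )
  jsonlite::write_json(
    list(summaries = fit$summaries,
         subnetworks = fit$subnetworks[, c("label", "n_pairs",
                                           "n_metabolites", "n_pathways")],
         candidates = list(genes = fit$candidates$gene_ids,
                           proteins = fit$candidates$protein_ids,
                           metabolites = fit$candidates$metabolite_ids)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  paths <- c(paths, report = file.path(dir, "report.json"))
  if (!is.null(fit$correlations)) {
    co <- fit$correlations
    co$r <- round(co$r, 3)
    paths <- c(paths, correlations = tsv(co, "correlations.tsv"))
  }
  if (igraph::vcount(fit$network) > 0L) {
    write_network(fit$network, file.path(dir, "network.sif"), "sif")
    write_network(fit$network, file.path(dir, "network.graphml"), "graphml")
    paths <- c(paths, sif = file.path(dir, "network.sif"),
               graphml = file.path(dir, "network.graphml"))
  }
  invisible(paths)
}
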