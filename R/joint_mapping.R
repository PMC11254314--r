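# Joint pathway mapping: per treatment group, find pathways containing at
# least one consistent gene/protein pair (via the pair's gene; the protein's
# membership is implied by its gene) and at least one differential metabolite
# of the group, then flag pathways in which some pair sits upstream of some
# differential metabolite. A pathway counts once per group no matter how many
# pairs or metabolites it contains.

#' Map one treatment group onto the pathway knowledge base
#'
#' @param pairs data frame of consistent pairs as returned by
#'   \code{\link{screen_all_groups}} (may span several groups).
#' @param metabolites \code{differential_table} of kind metabolite.
#' @param kb a \code{pathway_kb}.
#' @param dose,time the treatment group.
#' @param max_hops maximum reaction-path length for upstream-downstream
#'   detection (default unbounded).
#' @return list of joint-pathway hits ordered by (number of relations
#'   descending, pathway id ascending); each hit is a list with elements
#'   \code{group}, \code{dose}, \code{time}, \code{pathway_id}, \code{pairs}
#'   (data frame), \code{metabolites} (character), \code{relations} (data
#'   frame: gene_id, protein_id, metabolite_id, gene_direction,
#'   metabolite_direction, hops) and \code{has_relation}.
#' @export
map_group <- function(pairs, metabolites, kb, dose, time, max_hops = Inf) {
  stopifnot(inherits(kb, "pathway_kb"),
            inherits(metabolites, "differential_table"))
  if (!identical(table_kind(metabolites), "metabolite")) {
    stop("expected a metabolite differential_table", call. = FALSE)
  }
  g <- group_key(dose, time)
  gp <- pairs[pairs$group == g, , drop = FALSE]
  met <- group_records(metabolites, dose, time)
  hits <- list()
  if (nrow(gp) == 0L || nrow(met) == 0L) return(hits)

  met_dir <- stats::setNames(met$direction, met$id)
  for (pid in kb_pathway_ids(kb)) {
    member_genes <- kb_member_keys(kb, pid, "gene")
    member_mets <- kb_member_keys(kb, pid, "metabolite")
    sel_pairs <- gp[tolower(gp$gene_id) %in% member_genes, , drop = FALSE]
    sel_mets <- met$id[met$id %in% member_mets]
    if (nrow(sel_pairs) == 0L || length(sel_mets) == 0L) next

    rel <- list()
    for (i in seq_len(nrow(sel_pairs))) {
      hops <- downstream_hops(kb, pid, sel_pairs$gene_id[i])
      reach <- intersect(sel_mets, names(hops)[hops <= max_hops])
      if (length(reach)) {
        rel[[length(rel) + 1L]] <- data.frame(
          gene_id = sel_pairs$gene_id[i], protein_id = sel_pairs$protein_id[i],
          metabolite_id = reach,
          gene_direction = sel_pairs$direction[i],
          metabolite_direction = unname(met_dir[reach]),
          hops = unname(hops[reach]), stringsAsFactors = FALSE
        )
      }
    }
    rel <- if (length(rel)) do.call(rbind, rel) else
      data.frame(gene_id = character(), protein_id = character(),
                 metabolite_id = character(), gene_direction = character(),
                 metabolite_direction = character(), hops = integer(),
                 stringsAsFactors = FALSE)
    rel <- rel[order(tolower(rel$gene_id), rel$metabolite_id), , drop = FALSE]
    rownames(rel) <- NULL
    hits[[length(hits) + 1L]] <- list(
      group = g, dose = dose, time = time, pathway_id = pid,
      pairs = sel_pairs, metabolites = sort(sel_mets), relations = rel,
      has_relation = nrow(rel) > 0L
    )
  }
  n_rel <- vapply(hits, function(h) nrow(h$relations), integer(1))
  pw <- vapply(hits, function(h) h$pathway_id, character(1))
  hits[order(-n_rel, pw)]
}

#' Map every treatment group
#'
#' @inheritParams map_group
#' @return flat list of joint-pathway hits across all groups present in the
#'   pair table or the metabolite table, groups in (dose, time) order.
#' @export
map_all_groups <- function(pairs, metabolites, kb, max_hops = Inf) {
  groups <- unique(rbind(
    data.frame(dose = pairs$dose, time = pairs$time),
    data.frame(dose = metabolites$dose, time = metabolites$time)
  ))
  groups <- groups[order_groups(groups$dose, groups$time), , drop = FALSE]
  hits <- list()
  for (i in seq_len(nrow(groups))) {
    hits <- c(hits, map_group(pairs, metabolites, kb,
                              groups$dose[i], groups$time[i], max_hops))
  }
  hits
}

#' Per-group integration summaries
#'
#' Counts, for every group, the joint pathways, the joint pathways with an
#' upstream-downstream relation, and the differential metabolites.
#'
#' @param hits list of hits from \code{\link{map_all_groups}}.
#' @param metabolites the metabolite \code{differential_table} that produced
#'   them.
#' @return data frame with columns \code{dose}, \code{time}, \code{group},
#'   \code{n_differential_metabolites}, \code{n_joint_pathways},
#'   \code{n_relation_pathways}, in (dose, time) order.
#' @export
summarize_groups <- function(hits, metabolites) {
  groups <- unique(rbind(
    data.frame(dose = metabolites$dose, time = metabolites$time),
    if (length(hits)) data.frame(
      dose = vapply(hits, `[[`, numeric(1), "dose"),
      time = vapply(hits, `[[`, numeric(1), "time")
    ) else NULL
  ))
  groups <- groups[order_groups(groups$dose, groups$time), , drop = FALSE]
  hit_g <- vapply(hits, `[[`, character(1), "group")
  hit_rel <- vapply(hits, `[[`, logical(1), "has_relation")
  res <- lapply(seq_len(nrow(groups)), function(i) {
    g <- group_key(groups$dose[i], groups$time[i])
    data.frame(
      dose = groups$dose[i], time = groups$time[i], group = g,
      n_differential_metabolites = sum(metabolites$group == g),
      n_joint_pathways = sum(hit_g == g),
      n_relation_pathways = sum(hit_g == g & hit_rel),
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(dose = numeric(), time = numeric(), group = character(),
               n_differential_metabolites = integer(),
               n_joint_pathways = integer(), n_relation_pathways = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Flat catalogue of upstream-downstream relation links
#'
#' One row per (group, pathway, gene/protein pair, metabolite) relation link,
#' deterministically ordered by (group, pathway, gene, metabolite). This is
#' the package's reproduction of the per-group relation table from which the
#' tripartite network is built.
#'
#' @param hits list of hits from \code{\link{map_all_groups}}.
#' @return data frame with columns \code{dose}, \code{time}, \code{group},
#'   \code{pathway_id}, \code{gene_id}, \code{protein_id},
#'   \code{metabolite_id}, \code{gene_direction},
#'   \code{metabolite_direction}, \code{hops}.
#' @export
collect_relation_catalogue <- function(hits) {
  rows <- lapply(hits, function(h) {
    if (!h$has_relation) return(NULL)
    cbind(data.frame(dose = h$dose, time = h$time, group = h$group,
                     pathway_id = h$pathway_id, stringsAsFactors = FALSE),
          h$relations)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(dose = numeric(), time = numeric(), group = character(),
                      pathway_id = character(), gene_id = character(),
                      protein_id = character(), metabolite_id = character(),
                      gene_direction = character(),
                      metabolite_direction = character(), hops = integer(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$dose, out$time, out$pathway_id,
                   tolower(out$gene_id), out$metabolite_id), , drop = FALSE]
  out <- out[!duplicated(paste(out$group, out$pathway_id,
                               tolower(out$gene_id), out$metabolite_id)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
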