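# Synthetic multiomics benchmark generator. Emits a pathway KB of directed
# metabolite chains (with occasional branches) whose edges carry catalysing
# genes, plus per-group differential tables in which gene/protein pairs and
# downstream metabolites are planted with known ground truth. Noise entities
# are rejection-sampled so they cannot create unplanned upstream-downstream
# relations, keeping the ground truth exact. Everything is deterministic
# given the seed.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' The default group design mirrors a 2-dose x 3-time cytotoxicity exposure
#' study (100/200 micromolar; 12/24/48 h). Noise counts are per layer and per
#' run (not per group); \code{p_direction_flip} is the probability that a
#' planted protein contradicts its gene's direction, breaking pair
#' consistency.
#'
#' @param seed integer RNG seed.
#' @param n_pathways number of simulated pathways.
#' @param chain_length_range integer range (min, max) of metabolites per
#'   pathway chain; minimum 2.
#' @param doses,times treatment design; groups are their Cartesian product.
#' @param n_planted_pairs number of consistent gene/protein pairs to plant.
#' @param n_planted_relations number of upstream-downstream relations to
#'   plant (each ties a planted pair to a downstream metabolite).
#' @param noise_genes,noise_proteins,noise_metabolites counts of non-signal
#'   differential calls per layer.
#' @param p_direction_flip probability in [0, 1] of protein-direction flips.
#' @param p_branch probability that a pathway chain gains a side branch.
#' @return a \code{simulation_config} list.
#' @export
simulation_config <- function(seed = 1L, n_pathways = 6L,
                              chain_length_range = c(4L, 7L),
                              doses = c(100, 200), times = c(12, 24, 48),
                              n_planted_pairs = 4L, n_planted_relations = 6L,
                              noise_genes = 5L, noise_proteins = 5L,
                              noise_metabolites = 5L,
                              p_direction_flip = 0, p_branch = 0.3) {
  stopifnot(n_pathways >= 0, n_planted_pairs >= 0, n_planted_relations >= 0,
            noise_genes >= 0, noise_proteins >= 0, noise_metabolites >= 0,
            p_direction_flip >= 0, p_direction_flip <= 1)
  if (length(chain_length_range) != 2L || chain_length_range[1] < 2L) {
    stop("chain_length_range must be (min >= 2, max)", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_pathways = as.integer(n_pathways),
                 chain_length_range = as.integer(chain_length_range),
                 doses = doses, times = times,
                 n_planted_pairs = as.integer(n_planted_pairs),
                 n_planted_relations = as.integer(n_planted_relations),
                 noise_genes = as.integer(noise_genes),
                 noise_proteins = as.integer(noise_proteins),
                 noise_metabolites = as.integer(noise_metabolites),
                 p_direction_flip = p_direction_flip, p_branch = p_branch),
            class = "simulation_config")
}

#' Simulate a pathway knowledge base
#'
#' Pathways are directed metabolite chains \code{p<i>m1 -> p<i>m2 -> ...}
#' with every main-chain edge catalysed by its own gene \code{Sg<i>_<j>};
#' with probability \code{p_branch} a pathway gains one uncatalysed side
#' branch. Deterministic given \code{config$seed}.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return a \code{pathway_kb}.
#' @export
simulate_kb <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    pathways <- data.frame(pathway_id = character(), name = character(),
                           stringsAsFactors = FALSE)
    members <- list(); edges <- list()
    for (i in seq_len(config$n_pathways)) {
      pid <- sprintf("SPW%02d", i)
      L <- sample(seq(config$chain_length_range[1],
                      config$chain_length_range[2]), 1L)
      mets <- sprintf("p%dm%d", i, seq_len(L))
      genes <- sprintf("Sg%d_%d", i, seq_len(L - 1L))
      pathways <- rbind(pathways, data.frame(
        pathway_id = pid, name = sprintf("simulated pathway %d", i),
        stringsAsFactors = FALSE))
      e <- data.frame(pathway_id = pid, source = mets[-L], target = mets[-1L],
                      catalyst_genes = genes, stringsAsFactors = FALSE)
      if (stats::runif(1) < config$p_branch && L >= 3L) {
        bm <- sprintf("p%dmb", i)
        at <- sample(seq_len(L - 1L), 1L)
        mets <- c(mets, bm)
        e <- rbind(e, data.frame(pathway_id = pid, source = mets[at],
                                 target = bm, catalyst_genes = "",
                                 stringsAsFactors = FALSE))
      }
      members[[i]] <- rbind(
        data.frame(pathway_id = pid, kind = "metabolite", id = mets,
                   stringsAsFactors = FALSE),
        data.frame(pathway_id = pid, kind = "gene", id = genes,
                   stringsAsFactors = FALSE))
      edges[[i]] <- e
    }
    pathway_kb(pathways,
               if (length(members)) do.call(rbind, members) else
                 data.frame(pathway_id = character(), kind = character(),
                            id = character(), stringsAsFactors = FALSE),
               if (length(edges)) do.call(rbind, edges) else
                 data.frame(pathway_id = character(), source = character(),
                            target = character(),
                            catalyst_genes = character(),
                            stringsAsFactors = FALSE))
  })
}

#' Simulate differential tables with planted ground truth
#'
#' Plants \code{n_planted_pairs} direction-consistent gene/protein pairs
#' (catalyst genes drawn from the KB, each assigned to a random treatment
#' group) and \code{n_planted_relations} upstream-downstream relations (a
#' differential metabolite downstream of a planted pair's gene in its
#' pathway, same group). Noise calls are added per layer: noise genes and
#' proteins use identifiers outside the KB and never form pairs; noise
#' metabolites are rejection-sampled from KB metabolites that are NOT
#' reachable from any planted pair gene of the same group (capped retries),
#' so no unplanned relation can arise.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param kb the KB from \code{\link{simulate_kb}} under the same config.
#' @return list with elements \code{genes}, \code{proteins},
#'   \code{metabolites} (\code{differential_table}s) and \code{truth} (list
#'   with \code{pairs}, \code{relations}, \code{subnetworks}; pairs flipped
#'   by \code{p_direction_flip} are excluded from the recoverable truth).
#' @export
simulate_tables <- function(config, kb) {
  stopifnot(inherits(config, "simulation_config"), inherits(kb, "pathway_kb"))
  with_seed(config$seed + 1L, {
    groups <- expand.grid(dose = config$doses, time = config$times,
                          KEEP.OUT.ATTRS = FALSE)
    groups <- groups[order_groups(groups$dose, groups$time), , drop = FALSE]

    catalysts <- unique(unlist(strsplit(kb$edges$catalyst_genes, ",",
                                        fixed = TRUE)))
    catalysts <- sort(catalysts[nzchar(catalysts)])
    if (config$n_planted_pairs > length(catalysts)) {
      stop("infeasible plant count: ", config$n_planted_pairs,
           " pairs requested but only ", length(catalysts),
           " catalyst genes in KB", call. = FALSE)
    }
    planted_genes <- if (config$n_planted_pairs)
      sample(catalysts, config$n_planted_pairs) else character()
    gi <- if (config$n_planted_pairs)
      sample(nrow(groups), config$n_planted_pairs, replace = TRUE) else integer()
    pair_df <- data.frame(
      gene_id = planted_genes,
      dose = groups$dose[gi], time = groups$time[gi],
      direction = sample(c("up", "down"), config$n_planted_pairs,
                         replace = TRUE),
      flipped = stats::runif(config$n_planted_pairs) < config$p_direction_flip,
      stringsAsFactors = FALSE)

    # candidate relations: every metabolite downstream of a planted gene
    cand <- list()
    for (i in seq_len(nrow(pair_df))) {
      pw <- unique(kb$edges$pathway_id[
        vapply(kb$edges$catalyst_genes, function(cg)
          tolower(pair_df$gene_id[i]) %in%
            tolower(strsplit(cg, ",", fixed = TRUE)[[1]]),
          logical(1), USE.NAMES = FALSE)])
      for (p in pw) {
        ds <- names(downstream_hops(kb, p, pair_df$gene_id[i]))
        if (length(ds)) {
          cand[[length(cand) + 1L]] <- data.frame(
            pair_idx = i, pathway_id = p, metabolite_id = ds,
            stringsAsFactors = FALSE)
        }
      }
    }
    cand <- if (length(cand)) do.call(rbind, cand) else
      data.frame(pair_idx = integer(), pathway_id = character(),
                 metabolite_id = character(), stringsAsFactors = FALSE)
    # feasibility is judged against KB capacity; direction flips later thin
    # the recoverable truth but do not make a plant infeasible
    if (config$n_planted_relations > nrow(cand)) {
      stop("infeasible plant count: ", config$n_planted_relations,
           " relations requested but only ", nrow(cand),
           " realizable (pair, pathway, metabolite) combinations",
           call. = FALSE)
    }
    rel_idx <- if (config$n_planted_relations)
      sample(nrow(cand), config$n_planted_relations) else integer()
    rel <- cand[rel_idx, , drop = FALSE]
    # emitted metabolite records: one per (metabolite, group)
    met_plant <- unique(data.frame(
      metabolite_id = rel$metabolite_id,
      dose = pair_df$dose[rel$pair_idx], time = pair_df$time[rel$pair_idx],
      stringsAsFactors = FALSE))
    met_plant$direction <- if (nrow(met_plant))
      sample(c("up", "down"), nrow(met_plant), replace = TRUE) else character()
    # ground truth = closure: every (unflipped pair, pathway) of the same
    # group whose gene reaches an emitted metabolite yields a relation, so a
    # metabolite sitting downstream of two planted genes is truth for both
    rel_rows <- list()
    for (k in seq_len(nrow(met_plant))) {
      gsel <- which(!pair_df$flipped & pair_df$dose == met_plant$dose[k] &
                      pair_df$time == met_plant$time[k])
      for (i in gsel) {
        for (p in kb_pathway_ids(kb)) {
          hops <- downstream_hops(kb, p, pair_df$gene_id[i])
          if (met_plant$metabolite_id[k] %in% names(hops)) {
            rel_rows[[length(rel_rows) + 1L]] <- data.frame(
              dose = met_plant$dose[k], time = met_plant$time[k],
              pathway_id = p, gene_id = pair_df$gene_id[i],
              metabolite_id = met_plant$metabolite_id[k],
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    rel_df <- if (length(rel_rows)) unique(do.call(rbind, rel_rows)) else
      data.frame(dose = numeric(), time = numeric(),
                 pathway_id = character(), gene_id = character(),
                 metabolite_id = character(), stringsAsFactors = FALSE)

    # --- noise ---
    noise_gene_ids <- sprintf("Ngene%d", seq_len(config$noise_genes))
    noise_prot_ids <- sprintf("Nprot%d", seq_len(config$noise_proteins))
    all_kb_mets <- unique(kb$members$id[kb$members$kind == "metabolite"])
    # metabolites reachable from any planted pair gene, per group
    reach_by_group <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(pair_df))) {
      g <- group_key(pair_df$dose[i], pair_df$time[i])
      ds <- unique(unlist(lapply(kb_pathway_ids(kb), function(p)
        names(downstream_hops(kb, p, pair_df$gene_id[i])))))
      prev <- if (exists(g, envir = reach_by_group)) get(g, envir = reach_by_group)
              else character()
      assign(g, union(prev, ds), envir = reach_by_group)
    }
    noise_met <- list()
    attempts <- 0L
    while (length(noise_met) < config$noise_metabolites) {
      attempts <- attempts + 1L
      if (attempts > 200L * max(1L, config$noise_metabolites)) {
        stop("rejection sampling of noise metabolites exhausted its retry ",
             "budget; reduce noise_metabolites or enlarge the KB",
             call. = FALSE)
      }
      gi2 <- sample(nrow(groups), 1L)
      g <- group_key(groups$dose[gi2], groups$time[gi2])
      m <- sample(all_kb_mets, 1L)
      banned <- if (exists(g, envir = reach_by_group))
        get(g, envir = reach_by_group) else character()
      in_group_rel <- met_plant$metabolite_id[
        met_plant$dose == groups$dose[gi2] & met_plant$time == groups$time[gi2]]
      if (m %in% banned || m %in% in_group_rel) next
      key <- paste(m, g)
      if (key %in% vapply(noise_met, `[[`, character(1), "key")) next
      noise_met[[length(noise_met) + 1L]] <- list(
        key = key, id = m, dose = groups$dose[gi2], time = groups$time[gi2],
        direction = sample(c("up", "down"), 1L))
    }

    noise_group <- function(n) sample(nrow(groups), n, replace = TRUE)
    ng <- noise_group(config$noise_genes)
    np <- noise_group(config$noise_proteins)

    genes <- differential_table(
      id = c(pair_df$gene_id, noise_gene_ids),
      dose = c(pair_df$dose, groups$dose[ng]),
      time = c(pair_df$time, groups$time[ng]),
      direction = c(pair_df$direction,
                    sample(c("up", "down"), config$noise_genes, replace = TRUE)),
      kind = "gene")
    prot_dir <- ifelse(pair_df$flipped,
                       ifelse(pair_df$direction == "up", "down", "up"),
                       pair_df$direction)
    proteins <- differential_table(
      id = c(toupper(pair_df$gene_id), noise_prot_ids),
      dose = c(pair_df$dose, groups$dose[np]),
      time = c(pair_df$time, groups$time[np]),
      direction = c(prot_dir,
                    sample(c("up", "down"), config$noise_proteins,
                           replace = TRUE)),
      kind = "protein")
    met_rows <- rbind(
      met_plant[, c("metabolite_id", "dose", "time", "direction")],
      if (length(noise_met)) data.frame(
        metabolite_id = vapply(noise_met, `[[`, character(1), "id"),
        dose = vapply(noise_met, `[[`, numeric(1), "dose"),
        time = vapply(noise_met, `[[`, numeric(1), "time"),
        direction = vapply(noise_met, `[[`, character(1), "direction"),
        stringsAsFactors = FALSE) else NULL)
    metabolites <- differential_table(
      id = met_rows$metabolite_id, dose = met_rows$dose,
      time = met_rows$time, direction = met_rows$direction,
      kind = "metabolite")

    truth_pairs <- pair_df[!pair_df$flipped,
                           c("gene_id", "dose", "time", "direction")]
    truth_pairs$group <- if (nrow(truth_pairs))
      group_key(truth_pairs$dose, truth_pairs$time) else character()
    rownames(truth_pairs) <- NULL
    rel_out <- rel_df[, c("dose", "time", "pathway_id", "gene_id",
                          "metabolite_id")]
    rel_out$group <- if (nrow(rel_out))
      group_key(rel_out$dose, rel_out$time) else character()
    rownames(rel_out) <- NULL

    list(genes = genes, proteins = proteins, metabolites = metabolites,
         truth = list(pairs = truth_pairs, relations = rel_out,
                      subnetworks = truth_components(rel_out)))
  })
}

# connected components of the planted tripartite links, via a small
# union-find kept local to the generator so the truth does not depend on the
# pipeline's own decomposition
truth_components <- function(relations) {
  if (nrow(relations) == 0L) return(list())
  nodes <- unique(c(pair_node_key(relations$gene_id),
                    met_node_key(relations$metabolite_id),
                    pw_node_key(relations$pathway_id)))
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(a, b) {
    ra <- find(match(a, nodes)); rb <- find(match(b, nodes))
    if (ra != rb) parent[rb] <<- ra
  }
  for (i in seq_len(nrow(relations))) {
    pk <- pair_node_key(relations$gene_id[i])
    mk <- met_node_key(relations$metabolite_id[i])
    wk <- pw_node_key(relations$pathway_id[i])
    union_(pk, wk); union_(mk, wk)
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  unname(lapply(split(nodes, roots), sort))
}

#' Score pipeline recovery of planted truth
#'
#' Precision and recall per layer: consistent pairs (keyed by gene, group,
#' direction), relation links (group, pathway, gene, metabolite) and
#' subnetwork membership (unordered node co-membership pairs). When a layer
#' has no predictions its precision is reported as 1 with a warning; when the
#' truth is empty, recall is 1.
#'
#' @param fit a \code{\link{integrate_multiomics}} result on the simulated
#'   instance.
#' @param truth the \code{truth} element from \code{\link{simulate_tables}}.
#' @return data frame with columns \code{layer}, \code{precision},
#'   \code{recall}.
#' @export
evaluate_recovery <- function(fit, truth) {
  pr <- function(pred, tr, layer) {
    tp <- length(intersect(pred, tr))
    if (length(pred) == 0L) {
      if (length(tr)) warning("no predictions for layer ", layer,
                              "; precision reported as 1", call. = FALSE)
      precision <- 1
    } else precision <- tp / length(pred)
    recall <- if (length(tr) == 0L) 1 else tp / length(tr)
    data.frame(layer = layer, precision = precision, recall = recall,
               stringsAsFactors = FALSE)
  }
  pred_pairs <- paste(tolower(fit$pairs$gene_id), fit$pairs$group,
                      fit$pairs$direction)
  true_pairs <- paste(tolower(truth$pairs$gene_id), truth$pairs$group,
                      truth$pairs$direction)
  cat <- fit$catalogue
  pred_rel <- paste(cat$group, cat$pathway_id, tolower(cat$gene_id),
                    cat$metabolite_id)
  true_rel <- paste(truth$relations$group, truth$relations$pathway_id,
                    tolower(truth$relations$gene_id),
                    truth$relations$metabolite_id)
  co_pairs <- function(node_sets) {
    unlist(lapply(node_sets, function(ns) {
      if (length(ns) < 2L) return(character())
      cmb <- utils::combn(sort(ns), 2L)
      paste(cmb[1, ], cmb[2, ])
    }))
  }
  pred_comp <- lapply(seq_len(nrow(fit$subnetworks)), function(i)
    c(pair_node_key(sub("/.*$", "", fit$subnetworks$pairs[[i]])),
      met_node_key(fit$subnetworks$metabolites[[i]]),
      pw_node_key(fit$subnetworks$pathways[[i]])))
  out <- rbind(pr(unique(pred_pairs), unique(true_pairs), "pairs"),
               pr(unique(pred_rel), unique(true_rel), "relations"),
               pr(unique(co_pairs(pred_comp)),
                  unique(co_pairs(truth$subnetworks)), "subnetwork_membership"))
  rownames(out) <- NULL
  out
}
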