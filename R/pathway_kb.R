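# Pathway knowledge base: per-pathway membership (genes + metabolites) plus a
# directed metabolite-reaction graph whose edges carry catalysing-gene
# annotations. The upstream-downstream query implemented here is directed
# reachability in which the FIRST traversed edge must be catalysed by the
# query gene: an enzyme is "upstream" of every metabolite reachable from the
# product of a reaction it catalyses, possibly several steps away. Reversible
# reactions are encoded as two opposed edges in the KB files; the query treats
# all edges as directed.

ENTRY_TOKEN <- "*entry*"

#' Load a pathway knowledge base
#'
#' The membership file is GMT-like TSV: \code{pathway_id<TAB>name<TAB>member...}
#' with members prefixed \code{g:} (gene) or \code{m:} (metabolite). The edge
#' file is TSV \code{pathway_id<TAB>source<TAB>target<TAB>catalyst_genes}
#' (comma-separated gene ids; may be empty for spontaneous or unannotated
#' steps); \code{*entry*} as source marks a pathway entry point. Edge
#' endpoints that are metabolites must be pathway members; parallel edges are
#' merged with catalyst sets unioned.
#'
#' @param membership_path path to the membership file.
#' @param edges_path path to the edge file.
#' @return a \code{pathway_kb} object.
#' @export
load_kb <- function(membership_path, edges_path) {
  if (!file.exists(membership_path)) stop("file not found: ", membership_path, call. = FALSE)
  if (!file.exists(edges_path)) stop("file not found: ", edges_path, call. = FALSE)

  mlines <- readLines(membership_path, encoding = "UTF-8")
  mlines <- mlines[nzchar(trimws(mlines)) & !startsWith(trimws(mlines), "#")]
  pathways <- data.frame(pathway_id = character(), name = character(),
                         stringsAsFactors = FALSE)
  members <- list()
  for (ln in mlines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L) stop("malformed membership line: ", ln, call. = FALSE)
    pid <- trimws(f[1])
    pathways <- rbind(pathways, data.frame(pathway_id = pid, name = trimws(f[2]),
                                           stringsAsFactors = FALSE))
    mem <- trimws(f[-(1:2)])
    mem <- mem[nzchar(mem)]
    for (m in mem) {
      if (startsWith(m, "g:")) {
        members[[length(members) + 1L]] <- data.frame(
          pathway_id = pid, kind = "gene", id = norm_id(substring(m, 3), "gene"),
          stringsAsFactors = FALSE)
      } else if (startsWith(m, "m:")) {
        members[[length(members) + 1L]] <- data.frame(
          pathway_id = pid, kind = "metabolite",
          id = norm_id(substring(m, 3), "metabolite"), stringsAsFactors = FALSE)
      } else {
        stop("member without g:/m: prefix in pathway ", pid, ": ", m, call. = FALSE)
      }
    }
  }
  if (anyDuplicated(pathways$pathway_id)) {
    stop("duplicate pathway id(s): ",
         paste(unique(pathways$pathway_id[duplicated(pathways$pathway_id)]),
               collapse = ", "), call. = FALSE)
  }
  members <- if (length(members)) unique(do.call(rbind, members)) else
    data.frame(pathway_id = character(), kind = character(), id = character(),
               stringsAsFactors = FALSE)

  edf <- utils::read.delim(edges_path, comment.char = "#",
                           stringsAsFactors = FALSE, encoding = "UTF-8",
                           colClasses = "character")
  required <- c("pathway_id", "source", "target", "catalyst_genes")
  missing <- setdiff(required, names(edf))
  if (length(missing)) {
    stop("missing required column(s) in ", edges_path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  kb <- pathway_kb(pathways, members, edf)
  kb
}

#' Construct a pathway knowledge base in memory
#'
#' @param pathways data frame with columns \code{pathway_id}, \code{name}.
#' @param members data frame with columns \code{pathway_id}, \code{kind}
#'   (\code{"gene"}/\code{"metabolite"}), \code{id}.
#' @param edges data frame with columns \code{pathway_id}, \code{source},
#'   \code{target}, \code{catalyst_genes} (comma-separated, may be empty).
#' @return a \code{pathway_kb} object.
#' @export
pathway_kb <- function(pathways, members, edges) {
  pathways <- data.frame(pathway_id = as.character(pathways$pathway_id),
                         name = as.character(pathways$name),
                         stringsAsFactors = FALSE)
  members$id <- ifelse(members$kind == "metabolite",
                       norm_id(members$id, "metabolite"),
                       norm_id(members$id, "gene"))
  members <- unique(members)

  if (nrow(edges)) {
    edges$pathway_id <- as.character(edges$pathway_id)
    edges$source <- ifelse(tolower(trimws(edges$source)) == ENTRY_TOKEN,
                           ENTRY_TOKEN, norm_id(edges$source, "metabolite"))
    edges$target <- norm_id(edges$target, "metabolite")
    edges$catalyst_genes <- vapply(edges$catalyst_genes, function(cg) {
      parts <- trimws(strsplit(as.character(cg), ",", fixed = TRUE)[[1]])
      paste(sort(unique(parts[nzchar(parts)])), collapse = ",")
    }, character(1), USE.NAMES = FALSE)

    bad_pw <- setdiff(edges$pathway_id, pathways$pathway_id)
    if (length(bad_pw)) {
      stop("edge(s) reference unknown pathway: ",
           paste(unique(bad_pw), collapse = ", "), call. = FALSE)
    }
    if (any(edges$source == edges$target)) {
      stop("self-loop edge(s) (source == target)", call. = FALSE)
    }
    # endpoints (when metabolites) must be pathway members
    memkey <- paste(members$pathway_id[members$kind == "metabolite"],
                    members$id[members$kind == "metabolite"])
    ends <- rbind(
      data.frame(pathway_id = edges$pathway_id, id = edges$source),
      data.frame(pathway_id = edges$pathway_id, id = edges$target)
    )
    ends <- ends[ends$id != ENTRY_TOKEN, ]
    bad <- !(paste(ends$pathway_id, ends$id) %in% memkey)
    if (any(bad)) {
      stop("edge endpoint(s) not members of their pathway: ",
           paste(unique(paste0(ends$id[bad], " (", ends$pathway_id[bad], ")")),
                 collapse = ", "), call. = FALSE)
    }
    # merge parallel edges, unioning catalyst sets
    ekey <- paste(edges$pathway_id, edges$source, edges$target, sep = "\r")
    if (anyDuplicated(ekey)) {
      cat_by_edge <- tapply(edges$catalyst_genes, ekey, function(cs) {
        parts <- unlist(strsplit(cs, ",", fixed = TRUE))
        paste(sort(unique(parts[nzchar(parts)])), collapse = ",")
      })
      edges <- edges[!duplicated(ekey), , drop = FALSE]
      edges$catalyst_genes <- unname(cat_by_edge[paste(edges$pathway_id,
                                                       edges$source,
                                                       edges$target, sep = "\r")])
    }
    edges <- edges[order(edges$pathway_id, edges$source, edges$target), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(pathway_id = character(), source = character(),
                        target = character(), catalyst_genes = character(),
                        stringsAsFactors = FALSE)
  }
  structure(list(pathways = pathways, members = members, edges = edges),
            class = "pathway_kb")
}

#' @export
print.pathway_kb <- function(x, ...) {
  cat(sprintf("pathway_kb: %d pathways, %d memberships, %d reaction edges\n",
              nrow(x$pathways), nrow(x$members), nrow(x$edges)))
  invisible(x)
}

kb_pathway_ids <- function(kb) kb$pathways$pathway_id

# member ids of a pathway for one kind, as match keys
kb_member_keys <- function(kb, pathway_id, kind) {
  sel <- kb$members$pathway_id == pathway_id & kb$members$kind == kind
  match_key(kb$members$id[sel], kind)
}

check_pathway <- function(kb, pathway_id) {
  if (!pathway_id %in% kb$pathways$pathway_id) {
    stop("unknown pathway: ", pathway_id, call. = FALSE)
  }
}

# hop distances (shortest path length, first edge gene-catalysed) from a gene
# to every reachable metabolite of one pathway; named integer vector
downstream_hops <- function(kb, pathway_id, gene_id) {
  check_pathway(kb, pathway_id)
  gkey <- match_key(gene_id, "gene")
  if (!(gkey %in% kb_member_keys(kb, pathway_id, "gene"))) {
    return(stats::setNames(integer(0), character(0)))
  }
  e <- kb$edges[kb$edges$pathway_id == pathway_id, , drop = FALSE]
  if (nrow(e) == 0L) return(stats::setNames(integer(0), character(0)))
  catalysed <- vapply(e$catalyst_genes, function(cg) {
    gkey %in% tolower(strsplit(cg, ",", fixed = TRUE)[[1]])
  }, logical(1), USE.NAMES = FALSE)
  if (!any(catalysed)) return(stats::setNames(integer(0), character(0)))

  adj <- split(e$target, e$source)
  dist <- new.env(parent = emptyenv())
  frontier <- unique(e$target[catalysed])
  for (m in frontier) assign(m, 1L, envir = dist)
  d <- 1L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[!vapply(nxt, exists, logical(1), envir = dist)]
    for (m in nxt) assign(m, d, envir = dist)
    frontier <- nxt
  }
  res <- unlist(as.list(dist))
  res <- res[names(res) != ENTRY_TOKEN]
  res[order(names(res))]
}

#' Metabolites downstream of a gene within a pathway
#'
#' Returns the metabolites reachable in the pathway's directed reaction graph
#' along a path whose first edge is catalysed by \code{gene_id}, using at most
#' \code{max_hops} edges. A gene that is not a member of the pathway yields an
#' empty set.
#'
#' @param kb a \code{pathway_kb}.
#' @param pathway_id pathway to query (unknown pathway is an error).
#' @param gene_id gene (enzyme) identifier; matched case-insensitively.
#' @param max_hops maximum path length in edges (>= 1); \code{Inf} (default)
#'   for unbounded.
#' @return character vector of metabolite ids (normalised), sorted.
#' @export
downstream_metabolites <- function(kb, pathway_id, gene_id, max_hops = Inf) {
  if (!is.infinite(max_hops) && max_hops < 1) {
    stop("max_hops must be >= 1 or Inf", call. = FALSE)
  }
  h <- downstream_hops(kb, pathway_id, gene_id)
  names(h)[h <= max_hops]
}

#' Does a gene sit upstream of a metabolite in a pathway?
#'
#' True iff the metabolite is in \code{\link{downstream_metabolites}} of the
#' gene for that pathway.
#'
#' @inheritParams downstream_metabolites
#' @param metabolite_id metabolite name (normalised before comparison).
#' @return logical scalar.
#' @export
has_upstream_downstream <- function(kb, pathway_id, gene_id, metabolite_id,
                                    max_hops = Inf) {
  norm_id(metabolite_id, "metabolite") %in%
    downstream_metabolites(kb, pathway_id, gene_id, max_hops)
}

#' Write a pathway knowledge base to the membership/edge file formats
#'
#' Inverse of \code{\link{load_kb}}.
#'
#' @param kb a \code{pathway_kb}.
#' @param membership_path,edges_path output paths.
#' @return invisibly, a list of the two paths.
#' @export
write_kb <- function(kb, membership_path, edges_path) {
  lines <- vapply(seq_len(nrow(kb$pathways)), function(i) {
    pid <- kb$pathways$pathway_id[i]
    sel <- kb$members$pathway_id == pid
    mem <- paste0(ifelse(kb$members$kind[sel] == "gene", "g:", "m:"),
                  kb$members$id[sel])
    paste(c(pid, kb$pathways$name[i], sort(mem)), collapse = "\t")
  }, character(1))
  writeLines(lines, membership_path)
  utils::write.table(kb$edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(membership = membership_path, edges = edges_path))
}

#' Export a pathway's reaction graph as SIF
#'
#' Writes one line \code{source<TAB>reaction<TAB>target} per directed edge of
#' each requested pathway, for Cytoscape interoperability.
#'
#' @param kb a \code{pathway_kb}.
#' @param path output file.
#' @param pathway_ids pathways to export (default: all).
#' @return \code{path}, invisibly.
#' @export
write_kb_sif <- function(kb, path, pathway_ids = kb_pathway_ids(kb)) {
  e <- kb$edges[kb$edges$pathway_id %in% pathway_ids, , drop = FALSE]
  lines <- sprintf("%s\t%s\t%s", e$source,
                   ifelse(nzchar(e$catalyst_genes),
                          paste0("reaction(", e$catalyst_genes, ")"), "reaction"),
                   e$target)
  writeLines(lines, path)
  invisible(path)
}
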