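# Screening of gene/protein pairs with direction-consistent differential
# expression in the same treatment group. A pair (g, p) qualifies when the
# gene and its protein product are both differential in the group and share
# the same direction; only direction is compared (magnitudes and p-values on
# the two layers are not reconciled).

#' Construct a gene-to-protein mapping
#'
#' Declares which protein identifier is the product of which gene. The default
#' mapping used by the screen (when \code{mapping = NULL}) pairs identifiers
#' that are equal case-insensitively (mouse convention: gene \emph{Rrm2},
#' protein RRM2). An explicit mapping must be one-to-one after case folding.
#'
#' @param gene_id,protein_id equal-length character vectors.
#' @return a \code{gene_protein_map} data frame.
#' @export
gene_protein_map <- function(gene_id, protein_id) {
  gene_id <- trimws(as.character(gene_id))
  protein_id <- trimws(as.character(protein_id))
  stopifnot(length(gene_id) == length(protein_id))
  if (any(!nzchar(gene_id)) || any(!nzchar(protein_id))) {
    stop("empty identifier in gene-protein mapping", call. = FALSE)
  }
  gk <- tolower(gene_id); pk <- tolower(protein_id)
  df <- data.frame(gene_id = gene_id, protein_id = protein_id,
                   stringsAsFactors = FALSE)[!duplicated(paste(gk, pk)), ]
  if (anyDuplicated(tolower(df$gene_id)) || anyDuplicated(tolower(df$protein_id))) {
    stop("gene-protein mapping is not one-to-one", call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, class = c("gene_protein_map", "data.frame"))
}

#' Read a gene-to-protein mapping file
#'
#' TSV with header \code{gene_id<TAB>protein_id}.
#'
#' @param path path to the mapping file.
#' @return a \code{\link{gene_protein_map}}.
#' @export
read_gene_protein_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(c("gene_id", "protein_id"), names(df))
  if (length(missing)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  gene_protein_map(df$gene_id, df$protein_id)
}

# map a vector of gene match-keys to protein match-keys under the mapping
# (identity on the case-folded key when mapping is NULL)
map_gene_to_protein_key <- function(gene_keys, mapping) {
  if (is.null(mapping)) return(gene_keys)
  idx <- match(gene_keys, tolower(mapping$gene_id))
  ifelse(is.na(idx), NA_character_, tolower(mapping$protein_id[idx]))
}

#' Screen direction-consistent gene/protein pairs in one group
#'
#' Returns every pair (gene, protein) such that the gene is differential in
#' the given group, its mapped protein is differential in the same group, and
#' both calls have the same direction. The empty set is a valid result.
#'
#' @param genes,proteins \code{differential_table}s of kind gene / protein.
#' @param dose,time the treatment group.
#' @param mapping optional \code{\link{gene_protein_map}}; \code{NULL} means
#'   protein id equals gene id case-insensitively.
#' @return data frame with columns \code{gene_id}, \code{protein_id},
#'   \code{dose}, \code{time}, \code{group}, \code{direction}, ordered by
#'   gene id.
#' @export
screen_consistent_pairs <- function(genes, proteins, dose, time, mapping = NULL) {
  stopifnot(inherits(genes, "differential_table"),
            inherits(proteins, "differential_table"))
  if (!identical(table_kind(genes), "gene") ||
      !identical(table_kind(proteins), "protein")) {
    stop("expected tables of kind 'gene' and 'protein'", call. = FALSE)
  }
  g <- group_records(genes, dose, time)
  p <- group_records(proteins, dose, time)
  empty <- data.frame(gene_id = character(), protein_id = character(),
                      dose = numeric(), time = numeric(), group = character(),
                      direction = character(), stringsAsFactors = FALSE)
  if (nrow(g) == 0L || nrow(p) == 0L) return(empty)

  gkey <- match_key(g$id, "gene")
  want_pkey <- map_gene_to_protein_key(gkey, mapping)
  pkey <- match_key(p$id, "protein")
  idx <- match(want_pkey, pkey)
  hit <- which(!is.na(idx) & g$direction == p$direction[idx])
  out <- data.frame(
    gene_id = g$id[hit], protein_id = p$id[idx[hit]],
    dose = rep(dose, length(hit)), time = rep(time, length(hit)),
    group = rep(group_key(dose, time), length(hit)),
    direction = g$direction[hit], stringsAsFactors = FALSE
  )
  out <- out[order(tolower(out$gene_id)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consistent-pair counts for every group
#'
#' Runs \code{\link{screen_consistent_pairs}} for each treatment group present
#' in either input table.
#'
#' @inheritParams screen_consistent_pairs
#' @return data frame with columns \code{dose}, \code{time}, \code{group},
#'   \code{n_pairs}, ordered by (dose, time).
#' @export
pair_counts_by_group <- function(genes, proteins, mapping = NULL) {
  groups <- table_groups(genes, proteins)
  n <- vapply(seq_len(nrow(groups)), function(i) {
    nrow(screen_consistent_pairs(genes, proteins,
                                 groups$dose[i], groups$time[i], mapping))
  }, integer(1))
  data.frame(dose = groups$dose, time = groups$time,
             group = if (nrow(groups)) group_key(groups$dose, groups$time) else character(),
             n_pairs = n, stringsAsFactors = FALSE)
}

#' Screen pairs for all groups at once
#'
#' @inheritParams screen_consistent_pairs
#' @return row-bound pair data frame across groups (see
#'   \code{\link{screen_consistent_pairs}}).
#' @export
screen_all_groups <- function(genes, proteins, mapping = NULL) {
  groups <- table_groups(genes, proteins)
  out <- lapply(seq_len(nrow(groups)), function(i)
    screen_consistent_pairs(genes, proteins, groups$dose[i], groups$time[i], mapping))
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(gene_id = character(), protein_id = character(),
                      dose = numeric(), time = numeric(), group = character(),
                      direction = character(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}
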