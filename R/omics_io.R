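# ---- treatment-group keys ----------------------------------------------------

#' Treatment group keys
#'
#' A treatment group is identified by an exposure dose (micromolar) and an
#' exposure time (hours). The canonical rendering is \code{"<dose>uM-<time>h"},
#' e.g. \code{"100uM-12h"}; it is used as the stable key in every per-group
#' table the package produces.
#'
#' @param dose numeric vector of doses in micromolar (> 0).
#' @param time numeric vector of exposure times in hours (> 0).
#' @return character vector of group keys.
#' @examples
#' group_key(100, 12) # "100uM-12h"
#' @export
group_key <- function(dose, time) {
  if (any(!is.finite(dose)) || any(!is.finite(time)) ||
      any(dose <= 0) || any(time <= 0)) {
    stop("dose and time must be positive finite numbers", call. = FALSE)
  }
  paste0(format(dose, trim = TRUE, scientific = FALSE), "uM-",
         format(time, trim = TRUE, scientific = FALSE), "h")
}

# canonical ordering of groups: dose ascending, then time ascending
order_groups <- function(dose, time) order(dose, time)

# ---- identifier normalisation ------------------------------------------------

# Genes/proteins: stored as given, compared case-insensitively (Rrm2 <-> RRM2).
# Metabolites: matched by name only, so lowercase and collapse internal
# whitespace; no synonym resolution is attempted.
norm_id <- function(id, kind) {
  id <- trimws(id)
  if (kind == "metabolite") {
    id <- tolower(gsub("[[:space:]]+", " ", id))
  }
  id
}

# case-folded key used for matching (identity for metabolites, which are
# already lowercased by norm_id)
match_key <- function(id, kind) {
  if (kind == "metabolite") id else tolower(id)
}

DIRECTION_TOKENS <- c(
  "up" = "up", "down" = "down",
  "↑" = "up", "↓" = "down",
  "+1" = "up", "-1" = "down"
)

normalize_direction <- function(x) {
  x <- trimws(x)
  out <- unname(DIRECTION_TOKENS[x])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown direction token(s): ", paste(bad, collapse = ", "),
         " (accepted: up, down, ↑, ↓, +1, -1)", call. = FALSE)
  }
  out
}

ENTITY_KINDS <- c("gene", "protein", "metabolite")

# ---- differential tables -----------------------------------------------------

#' Construct a differential-entity table
#'
#' One row per differential call: an entity (gene, protein or metabolite)
#' observed up- or down-regulated in one treatment group. Identifiers are
#' normalised (see Details), duplicate identical calls are collapsed keeping
#' the largest absolute magnitude, and contradictory calls (same entity, same
#' group, opposite directions) are an error.
#'
#' @details Gene and protein identifiers are stored as given and compared
#'   case-insensitively; metabolite names are lowercased with internal
#'   whitespace collapsed. Direction accepts \code{up}, \code{down}, the
#'   arrows \code{↑}/\code{↓}, and \code{+1}/\code{-1}.
#'
#' @param id character, entity identifiers.
#' @param dose,time numeric, treatment group coordinates (micromolar, hours).
#' @param direction direction labels, one per row.
#' @param kind one of \code{"gene"}, \code{"protein"}, \code{"metabolite"}.
#' @param magnitude optional numeric effect sizes (unitless).
#' @param pvalue optional p-like values in [0, 1].
#' @return a \code{differential_table}: a data frame with columns
#'   \code{id}, \code{dose}, \code{time}, \code{group}, \code{direction},
#'   \code{magnitude}, \code{pvalue} and attribute \code{kind}.
#' @export
differential_table <- function(id, dose, time, direction, kind,
                               magnitude = NULL, pvalue = NULL) {
  kind <- match.arg(kind, ENTITY_KINDS)
  n <- length(id)
  if (n == 0L) {
    return(empty_differential_table(kind))
  }
  id <- norm_id(as.character(id), kind)
  if (any(!nzchar(id))) stop("empty entity id after normalization", call. = FALSE)
  dose <- as.numeric(dose)
  time <- as.numeric(time)
  direction <- normalize_direction(as.character(direction))
  magnitude <- if (is.null(magnitude)) rep(NA_real_, n) else as.numeric(magnitude)
  pvalue <- if (is.null(pvalue)) rep(NA_real_, n) else as.numeric(pvalue)
  if (any(pvalue < 0 | pvalue > 1, na.rm = TRUE)) {
    stop("pvalue outside [0, 1]", call. = FALSE)
  }

  df <- data.frame(
    id = id, dose = dose, time = time,
    group = group_key(dose, time),
    direction = direction, magnitude = magnitude, pvalue = pvalue,
    stringsAsFactors = FALSE
  )

  key <- paste(match_key(df$id, kind), df$group, sep = "\r")
  # contradiction check: same (entity, group) with both directions
  dirs_per_key <- tapply(df$direction, key, function(d) length(unique(d)))
  if (any(dirs_per_key > 1L)) {
    bad <- names(dirs_per_key)[dirs_per_key > 1L]
    first <- match(bad, key)
    stop("conflicting directions for: ",
         paste(paste0(df$id[first], " in ", df$group[first]), collapse = "; "),
         call. = FALSE)
  }
  # dedup identical calls, keeping largest |magnitude| (NA ranks last)
  ord <- order(key, -abs(ifelse(is.na(df$magnitude), -Inf, df$magnitude)))
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(key[ord]), , drop = FALSE]
  df <- df[order(df$dose, df$time, match_key(df$id, kind)), , drop = FALSE]
  rownames(df) <- NULL

  structure(df, kind = kind, class = c("differential_table", "data.frame"))
}

empty_differential_table <- function(kind) {
  df <- data.frame(
    id = character(), dose = numeric(), time = numeric(), group = character(),
    direction = character(), magnitude = numeric(), pvalue = numeric(),
    stringsAsFactors = FALSE
  )
  structure(df, kind = kind, class = c("differential_table", "data.frame"))
}

#' @export
print.differential_table <- function(x, ...) {
  cat(sprintf("differential_table (%s): %d records, %d groups\n",
              attr(x, "kind"), nrow(x), length(unique(x$group))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  invisible(x)
}

table_kind <- function(x) attr(x, "kind")

# records of one group as a plain data frame
group_records <- function(tab, dose, time) {
  g <- group_key(dose, time)
  as.data.frame(tab)[tab$group == g, , drop = FALSE]
}

# all (dose, time) combinations present, canonically ordered
table_groups <- function(...) {
  tabs <- list(...)
  df <- unique(do.call(rbind, lapply(tabs, function(t)
    data.frame(dose = t$dose, time = t$time))))
  df <- df[order_groups(df$dose, df$time), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a differential-entity table from TSV
#'
#' Expected columns (tab-separated, header required):
#' \code{id}, \code{kind}, \code{dose_uM}, \code{time_h}, \code{direction},
#' and optionally \code{magnitude} and \code{pvalue}. Lines starting with
#' \code{#} are comments. Rows whose \code{kind} column disagrees with the
#' \code{kind} argument are rejected.
#'
#' @param path path to the TSV file.
#' @param kind entity kind the table holds.
#' @return a \code{\link{differential_table}}.
#' @export
read_differential_table <- function(path, kind) {
  kind <- match.arg(kind, ENTITY_KINDS)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  required <- c("id", "kind", "dose_uM", "time_h", "direction")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) return(empty_differential_table(kind))
  if (any(df$kind != kind)) {
    stop("table declared kind '", kind, "' but contains rows of kind: ",
         paste(setdiff(unique(df$kind), kind), collapse = ", "), call. = FALSE)
  }
  differential_table(
    id = df$id, dose = df$dose_uM, time = df$time_h,
    direction = df$direction, kind = kind,
    magnitude = if ("magnitude" %in% names(df)) df$magnitude else NULL,
    pvalue = if ("pvalue" %in% names(df)) df$pvalue else NULL
  )
}

#' Write a differential-entity table to TSV
#'
#' Inverse of \code{\link{read_differential_table}}: reading the written file
#' reproduces the table record-for-record.
#'
#' @param tab a \code{differential_table}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_differential_table <- function(tab, path) {
  stopifnot(inherits(tab, "differential_table"))
  out <- data.frame(
    id = tab$id, kind = table_kind(tab), dose_uM = tab$dose, time_h = tab$time,
    direction = tab$direction, magnitude = tab$magnitude, pvalue = tab$pvalue,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- phenotype series --------------------------------------------------------

#' Read a phenotype series (per-group cell proliferation)
#'
#' TSV with header \code{dose_uM<TAB>time_h<TAB>value}; one row per treatment
#' group; values are percentages in (0, 100]. Duplicate groups are an error;
#' an empty file yields an empty series with a warning.
#'
#' @param path path to the TSV file.
#' @return a \code{phenotype_series}: data frame with columns \code{dose},
#'   \code{time}, \code{group}, \code{value}, canonically ordered by
#'   (dose, time).
#' @export
read_phenotype_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("dose_uM", "time_h", "value")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    warning("empty phenotype series: ", path, call. = FALSE)
    return(phenotype_series(numeric(), numeric(), numeric()))
  }
  phenotype_series(df$dose_uM, df$time_h, df$value)
}

#' Construct a phenotype series
#'
#' @param dose,time group coordinates (micromolar, hours).
#' @param value phenotype values, percent cell proliferation in (0, 100].
#' @return a \code{phenotype_series} data frame.
#' @export
phenotype_series <- function(dose, time, value) {
  dose <- as.numeric(dose); time <- as.numeric(time); value <- as.numeric(value)
  if (length(value) && (any(value <= 0) || any(value > 100))) {
    stop("phenotype values must lie in (0, 100]", call. = FALSE)
  }
  df <- data.frame(dose = dose, time = time,
                   group = if (length(dose)) group_key(dose, time) else character(),
                   value = value, stringsAsFactors = FALSE)
  if (anyDuplicated(df$group)) {
    stop("duplicate phenotype group(s): ",
         paste(unique(df$group[duplicated(df$group)]), collapse = ", "),
         call. = FALSE)
  }
  df <- df[order_groups(df$dose, df$time), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("phenotype_series", "data.frame"))
}
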