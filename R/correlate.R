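# Pearson correlation between the per-group phenotype (percent cell
# proliferation) and integration summary counts, computed separately within
# each dose across its time points. A correlation is classified "strong" when
# the signed coefficient exceeds the threshold (default 0.8); an
# absolute-value mode is available. With three time points per dose no
# meaningful p-value exists and none is reported.

#' Pearson product-moment correlation
#'
#' Thin wrapper over \code{stats::cor} that validates its inputs: equal
#' lengths of at least 2 and nonzero variance in both sequences. The result
#' is clamped to [-1, 1] against floating-point overshoot.
#'
#' @param x,y numeric sequences of equal length.
#' @return the correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 points", call. = FALSE)
  if (stats::sd(x) == 0) stop("x is constant: correlation undefined", call. = FALSE)
  if (stats::sd(y) == 0) stop("y is constant: correlation undefined", call. = FALSE)
  r <- stats::cor(x, y, method = "pearson")
  max(-1, min(1, r))
}

CORRELATION_INDICATORS <- c("differential_metabolites", "joint_pathways",
                            "relation_pathways")

#' Correlate the phenotype with integration summaries within one dose
#'
#' For the time series of one dose, computes the Pearson correlation between
#' the phenotype values and each of three indicators: the number of
#' differential metabolites, of joint pathways, and of joint pathways with an
#' upstream-downstream relation.
#'
#' @param phenotype a \code{\link{phenotype_series}}.
#' @param summaries group summaries from \code{\link{summarize_groups}} (or
#'   any data frame with columns \code{dose}, \code{time},
#'   \code{n_differential_metabolites}, \code{n_joint_pathways},
#'   \code{n_relation_pathways}).
#' @param dose dose (micromolar) selecting the series.
#' @param r_threshold strong-correlation threshold on the coefficient
#'   (default 0.8).
#' @param abs_r if \code{TRUE}, classify on |r| instead of signed r.
#' @return data frame with columns \code{dose}, \code{indicator}, \code{r},
#'   \code{n}, \code{strong} (one row per indicator).
#' @export
correlate_dose <- function(phenotype, summaries, dose, r_threshold = 0.8,
                           abs_r = FALSE) {
  ph <- phenotype[phenotype$dose == dose, , drop = FALSE]
  if (nrow(ph) < 3L) {
    stop("need >= 3 time points at dose ", dose, "; have ", nrow(ph),
         call. = FALSE)
  }
  sm <- summaries[summaries$dose == dose, , drop = FALSE]
  idx <- match(ph$time, sm$time)
  if (anyNA(idx)) {
    stop("summaries missing group(s): ",
         paste(group_key(dose, ph$time[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  sm <- sm[idx, , drop = FALSE]
  cols <- c(differential_metabolites = "n_differential_metabolites",
            joint_pathways = "n_joint_pathways",
            relation_pathways = "n_relation_pathways")
  rows <- lapply(CORRELATION_INDICATORS, function(ind) {
    r <- pearson_r(ph$value, sm[[cols[[ind]]]])
    data.frame(dose = dose, indicator = ind, r = r, n = nrow(ph),
               strong = (if (abs_r) abs(r) else r) > r_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlate all doses
#'
#' @inheritParams correlate_dose
#' @return row-bound reports of \code{\link{correlate_dose}} over every dose
#'   in the phenotype series, dose ascending.
#' @export
correlate_all_doses <- function(phenotype, summaries, r_threshold = 0.8,
                                abs_r = FALSE) {
  doses <- sort(unique(phenotype$dose))
  out <- do.call(rbind, lapply(doses, function(d)
    correlate_dose(phenotype, summaries, d, r_threshold, abs_r)))
  rownames(out) <- NULL
  out
}
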