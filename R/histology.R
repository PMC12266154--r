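#' Four-way nuclear classification of a stained cell
#'
#' Classifies a cell from its nuclear P21 and KI67 status. Only
#' P21-positive / KI67-negative cells carry the cell-cycle-inhibitor profile
#' consistent with senescence.
#'
#' @param p21,ki67 Logical vectors (recycled to common length).
#' @return Factor with levels `SEN`, `PROLIF`, `DOUBLE_POS`, `DOUBLE_NEG`.
#' @examples
#' classify_cell(c(TRUE, TRUE, FALSE, FALSE), c(FALSE, TRUE, TRUE, FALSE))
#' @export
classify_cell <- function(p21, ki67) {
  n <- max(length(p21), length(ki67))
  p21 <- rep_len(as.logical(p21), n)
  ki67 <- rep_len(as.logical(ki67), n)
  out <- ifelse(p21 & !ki67, "SEN",
         ifelse(!p21 & ki67, "PROLIF",
         ifelse(p21 & ki67, "DOUBLE_POS", "DOUBLE_NEG")))
  factor(out, levels = c("SEN", "PROLIF", "DOUBLE_POS", "DOUBLE_NEG"))
}

#' Senescent epithelial fraction per participant
#'
#' Computes, per participant, the percentage of tubular epithelial cells
#' that are P21+/KI67-. Counts are pooled across biopsy sections *before*
#' the percentage is taken (sum of counts, never a mean of per-section
#' percentages). Non-epithelial cells are excluded from both numerator and
#' denominator. Participants with no epithelial cells are dropped with a
#' warning.
#'
#' @param cells Data.frame of classified cells as from [read_cell_table()]
#'   or [gen_biopsy_cells()].
#' @return Data.frame with columns `participant_id`, `n_epithelial`,
#'   `n_p21pos_ki67neg`, `pct_senescent`.
#' @examples
#' cells <- gen_biopsy_cells(10, n_cells = 200, n_sections = 2, seed = 1)
#' senescent_fraction(cells)
#' @export
senescent_fraction <- function(cells) {
  stopifnot(is.data.frame(cells))
  req <- c("participant_id", "epithelial", "p21_nuclear", "ki67_nuclear")
  missing_cols <- setdiff(req, names(cells))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ids <- unique(cells$participant_id)
  epi <- cells[cells$epithelial, , drop = FALSE]
  sen <- epi$p21_nuclear & !epi$ki67_nuclear
  n_epi <- table(factor(epi$participant_id, levels = ids))
  n_sen <- table(factor(epi$participant_id[sen], levels = ids))
  out <- data.frame(
    participant_id = ids,
    n_epithelial = as.integer(n_epi),
    n_p21pos_ki67neg = as.integer(n_sen),
    stringsAsFactors = FALSE
  )
  empty <- out$n_epithelial == 0L
  if (any(empty)) {
    warning("excluding participant(s) with no epithelial cells: ",
            paste(out$participant_id[empty], collapse = ", "), call. = FALSE)
    out <- out[!empty, , drop = FALSE]
  }
  out$pct_senescent <- 100 * out$n_p21pos_ki67neg / out$n_epithelial
  rownames(out) <- NULL
  out
}

#' P21/clusterin co-expression odds ratio
#'
#' Odds ratio that P21+ cells express cytoplasmic clusterin, from a 2x2
#' contingency table with cells `a` = P21+Clu+, `b` = P21+Clu-,
#' `c` = P21-Clu+, `d` = P21-Clu-. The point estimate is `ad/bc` with a 95%
#' Woolf (log-normal) confidence interval and a two-sided Fisher exact
#' p-value (sum of hypergeometric table probabilities not exceeding the
#' observed table's). Any zero cell triggers the Haldane-Anscombe +0.5
#' correction for the OR and CI (flagged in the result); the Fisher p is
#' always computed on the raw counts.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @param conf_level Confidence level for the Woolf interval.
#' @return List with `or`, `ci_low`, `ci_high`, `fisher_p`,
#'   `continuity_corrected`.
#' @examples
#' coexpression_or(20, 10, 5, 15)   # OR = 6
#' @export
coexpression_or <- function(a, b, c, d, conf_level = 0.95) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  corrected <- any(counts == 0)
  k <- if (corrected) counts + 0.5 else counts
  or <- (k[["a"]] * k[["d"]]) / (k[["b"]] * k[["c"]])
  se_log <- sqrt(sum(1 / k))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  fp <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(
    or = unname(or),
    ci_low = unname(exp(log(or) - z * se_log)),
    ci_high = unname(exp(log(or) + z * se_log)),
    fisher_p = unname(fp),
    continuity_corrected = corrected
  )
}

#' Cross-tabulate P21 against clusterin status
#'
#' Builds the 2x2 table fed to [coexpression_or()] from a clusterin-panel
#' cell table. Only epithelial cells with a recorded clusterin status enter;
#' cells with missing clusterin status are counted and reported.
#'
#' @param cells Data.frame with `epithelial`, `p21_nuclear` and
#'   `clusterin_cytoplasmic` columns.
#' @return List with `a`, `b`, `c`, `d` counts and `n_missing_clusterin`.
#' @export
p21_clusterin_table <- function(cells) {
  req <- c("epithelial", "p21_nuclear", "clusterin_cytoplasmic")
  missing_cols <- setdiff(req, names(cells))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  epi <- cells[cells$epithelial, , drop = FALSE]
  miss <- is.na(epi$clusterin_cytoplasmic)
  use <- epi[!miss, , drop = FALSE]
  list(
    a = sum(use$p21_nuclear & use$clusterin_cytoplasmic),
    b = sum(use$p21_nuclear & !use$clusterin_cytoplasmic),
    c = sum(!use$p21_nuclear & use$clusterin_cytoplasmic),
    d = sum(!use$p21_nuclear & !use$clusterin_cytoplasmic),
    n_missing_clusterin = sum(miss)
  )
}

#' Flag the highest tertile of senescence
#'
#' Labels values at or above the upper-tertile cutpoint (quantile with
#' linear interpolation, ties assigned to the upper group) — the binary
#' outcome used when selecting a biomarker threshold by ROC analysis.
#'
#' @param pct Numeric vector of senescent-epithelium percentages.
#' @return Logical vector, `TRUE` for the top tertile.
#' @export
top_tertile <- function(pct) {
  stopifnot(is.numeric(pct))
  cut <- quantile(pct, 2 / 3, na.rm = TRUE, names = FALSE)
  pct >= cut
}
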