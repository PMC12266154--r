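#' Bundle urinary proteomics samples
#'
#' Light container for a label-free urinary proteomics experiment: a
#' sample-by-protein intensity matrix plus, per sample, the alcohol
#' dehydrogenase (ADH) spike-in intensity and the urinary creatinine, and a
#' sample-by-protein matrix of unique-peptide counts.
#'
#' @param intensities Numeric matrix, samples in rows (rownames = sample
#'   ids), proteins in columns (colnames = protein ids); non-negative.
#' @param adh Positive numeric vector, ADH spike-in intensity per sample.
#' @param creatinine Positive numeric vector, urinary creatinine (mmol/L).
#' @param unique_peptides Integer matrix, same shape as `intensities`.
#' @return List of class `proteomics_samples`.
#' @export
proteomics_samples <- function(intensities, adh, creatinine, unique_peptides) {
  stopifnot(is.matrix(intensities), is.matrix(unique_peptides),
            all(dim(intensities) == dim(unique_peptides)))
  n <- nrow(intensities)
  if (length(adh) != n || length(creatinine) != n) {
    stop("`adh` and `creatinine` must have one value per sample",
         call. = FALSE)
  }
  if (any(intensities < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  bad <- !is.finite(adh) | adh <= 0 | !is.finite(creatinine) | creatinine <= 0
  if (any(bad)) {
    stop("sample(s) with non-positive ADH or creatinine: ",
         paste(rownames(intensities)[bad], collapse = ", "), call. = FALSE)
  }
  structure(
    list(intensities = intensities, adh = adh, creatinine = creatinine,
         unique_peptides = unique_peptides),
    class = "proteomics_samples"
  )
}

#' @export
print.proteomics_samples <- function(x, ...) {
  cat("proteomics_samples:", nrow(x$intensities), "samples x",
      ncol(x$intensities), "proteins\n")
  invisible(x)
}

#' Spike-in and creatinine normalisation
#'
#' Per sample, divides every protein intensity first by the ADH spike-in
#' intensity (removing instrument/run effects; the spike-in is added in
#' fixed amount after urine collection) and then by urinary creatinine
#' (removing urine-concentration effects).
#'
#' @param samples A [proteomics_samples()] object.
#' @return Normalised numeric matrix, samples x proteins.
#' @export
normalize_proteome <- function(samples) {
  stopifnot(inherits(samples, "proteomics_samples"))
  sweep(samples$intensities, 1, samples$adh * samples$creatinine, "/")
}

#' Unique-peptide identification filter
#'
#' Retains proteins identified by at least `min_unique` unique peptides in
#' at least one sample (boundary inclusive).
#'
#' @param samples A [proteomics_samples()] object.
#' @param min_unique Minimum unique-peptide count, default 2.
#' @return Character vector of retained protein ids.
#' @export
peptide_filter <- function(samples, min_unique = 2) {
  stopifnot(inherits(samples, "proteomics_samples"))
  up <- samples$unique_peptides
  if (ncol(up) == 0L) return(character(0))
  keep <- apply(up, 2, max, na.rm = TRUE) >= min_unique
  colnames(up)[keep]
}

#' Spearman correlation screen against tissue senescence
#'
#' Correlates each protein's normalised urinary level with the histologic
#' P21+/KI67- senescent-epithelium percentage across participants
#' (Spearman's rank correlation, average ranks on ties). Raw p-values use
#' the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees
#' of freedom (an exact permutation p is available for very small n), and
#' are Benjamini-Hochberg adjusted across the tested family. Proteins with
#' fewer than `min_complete` proportion of non-missing pairs, or fewer than
#' 3 pairs, or a constant value vector, are reported with `NA` statistics
#' and excluded from the BH family.
#'
#' @param mat Normalised matrix, samples x proteins (e.g. from
#'   [normalize_proteome()], columns restricted to [peptide_filter()]).
#' @param senescence Numeric vector of senescence percentages, aligned with
#'   the rows of `mat`.
#' @param min_complete Minimum fraction of non-missing pairs, default 0.8.
#' @param exact_permutation Use the exact permutation null for the p-value;
#'   only allowed when n <= 10.
#' @return Data.frame with columns `protein`, `n`, `rho`, `p`, `p_adj`,
#'   sorted by decreasing `rho` (NA rows last).
#' @export
correlation_screen <- function(mat, senescence, min_complete = 0.8,
                               exact_permutation = FALSE) {
  stopifnot(is.matrix(mat), nrow(mat) == length(senescence))
  proteins <- colnames(mat)
  if (is.null(proteins)) proteins <- paste0("P", seq_len(ncol(mat)))
  res <- lapply(seq_len(ncol(mat)), function(j) {
    x <- mat[, j]
    ok <- is.finite(x) & is.finite(senescence)
    n <- sum(ok)
    if (n < 3 || n < min_complete * length(x) ||
        length(unique(x[ok])) < 2 || length(unique(senescence[ok])) < 2) {
      return(c(n = n, rho = NA_real_, p = NA_real_))
    }
    rho <- cor(x[ok], senescence[ok], method = "spearman")
    p <- spearman_p(rho, x[ok], senescence[ok], exact_permutation)
    c(n = n, rho = rho, p = p)
  })
  res <- do.call(rbind, res)
  out <- data.frame(protein = proteins, n = as.integer(res[, "n"]),
                    rho = res[, "rho"], p = res[, "p"],
                    stringsAsFactors = FALSE)
  out$p_adj <- NA_real_
  tested <- !is.na(out$p)
  out$p_adj[tested] <- p.adjust(out$p[tested], method = "BH")
  out <- out[order(-out$rho, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

spearman_p <- function(rho, x, y, exact_permutation) {
  n <- length(x)
  if (exact_permutation) {
    if (n > 10) stop("exact permutation p only supported for n <= 10",
                     call. = FALSE)
    perms <- permutations(n)
    rx <- rank(x)
    ry <- rank(y)
    null_rho <- apply(perms, 1, function(idx) cor(rx, ry[idx]))
    return(mean(abs(null_rho) >= abs(rho) - 1e-12))
  }
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(tstat), df = n - 2)
}

permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Shortlist biomarker candidates
#'
#' Retains screened proteins with BH-adjusted p below `alpha` and Spearman
#' rho strictly above `rho_min`, then flags members of a
#' senescence-associated secretory phenotype (SASP) reference list.
#'
#' @param candidates Data.frame from [correlation_screen()].
#' @param rho_min Strict lower bound on rho, default 0.5.
#' @param alpha Adjusted-p threshold, default 0.05.
#' @param sasp_list Character vector of SASP protein ids; default
#'   [sasp_reference()].
#' @return Subset of `candidates` with an added logical `sasp_flag`.
#' @export
shortlist <- function(candidates, rho_min = 0.5, alpha = 0.05,
                      sasp_list = sasp_reference()) {
  stopifnot(all(c("protein", "rho", "p_adj") %in% names(candidates)))
  keep <- !is.na(candidates$rho) & !is.na(candidates$p_adj) &
    candidates$rho > rho_min & candidates$p_adj < alpha
  out <- candidates[keep, , drop = FALSE]
  out$sasp_flag <- out$protein %in% sasp_list
  rownames(out) <- NULL
  out
}

#' Bundled SASP reference list
#'
#' A small illustrative list of proteins reported as secreted by senescent
#' (notably renal epithelial) cells, including clusterin (CLU). It is a
#' synthetic stand-in for a full SASP atlas and is meant to be replaced by
#' the user's own list (one protein id per line).
#'
#' @param path Optional path to a user list; defaults to the packaged file.
#' @return Character vector of protein ids.
#' @export
sasp_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "sasp_list_synthetic.txt",
                        package = "senuro", mustWork = TRUE)
  }
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' qPCR relative expression by the delta-delta-Ct method
#'
#' Normalises target Ct values against the mean of two (or more) reference
#' genes and against a control group: `dCt = target_ct - mean(ref_cts)`,
#' `ddCt = dCt - mean(control dCt)`, relative expression `2^(-ddCt)`. With
#' this sign convention the control group averages 1 and upregulated
#' samples exceed 1.
#'
#' @param target_ct Numeric vector of target-gene Ct values.
#' @param ref_cts Matrix (samples x reference genes) or vector of
#'   reference-gene Ct values for the same samples.
#' @param control_dct Numeric vector of control-group dCt values (target
#'   minus reference mean, computed the same way).
#' @return Numeric vector of relative expressions.
#' @examples
#' ddct(c(20, 19), cbind(c(22, 22), c(24, 24)), control_dct = c(-3, -3))
#' @export
ddct <- function(target_ct, ref_cts, control_dct) {
  if (length(control_dct) == 0) {
    stop("control group must be non-empty", call. = FALSE)
  }
  if (is.vector(ref_cts)) ref_cts <- matrix(ref_cts, ncol = 1)
  stopifnot(nrow(ref_cts) == length(target_ct))
  if (any(!is.finite(target_ct)) || any(!is.finite(ref_cts)) ||
      any(!is.finite(control_dct))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  dct <- target_ct - rowMeans(ref_cts)
  ddct <- dct - mean(control_dct)
  2^(-ddct)
}
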