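#' Construct a spatial transcriptomics field
#'
#' Container for one tissue section of subcellular-resolution spatial
#' transcriptomics data (CosMx SMI-style export): typed cell centroids, a
#' per-cell gene count matrix, and the raw transcript point cloud.
#' Coordinates are micrometres.
#'
#' @param cells Data.frame with columns `cell_id` (unique), `x`, `y`
#'   (centroid, um) and `cell_type` (e.g. `"PT"`, `"LOH_DCT"`, `"other"`).
#' @param counts Numeric matrix of per-cell transcript counts, rows aligned
#'   with (and rownames equal to) `cells$cell_id`, columns named by gene.
#' @param transcripts Data.frame with columns `gene`, `x`, `y` (um).
#' @return List of class `spatial_field`.
#' @export
spatial_field <- function(cells, counts, transcripts) {
  stopifnot(is.data.frame(cells),
            all(c("cell_id", "x", "y", "cell_type") %in% names(cells)),
            is.data.frame(transcripts),
            all(c("gene", "x", "y") %in% names(transcripts)))
  if (anyDuplicated(cells$cell_id)) {
    stop("`cell_id` must be unique", call. = FALSE)
  }
  if (!all(is.finite(cells$x)) || !all(is.finite(cells$y)) ||
      !all(is.finite(transcripts$x)) || !all(is.finite(transcripts$y))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(cells)) {
    stop("`counts` must have one row per cell", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  rownames(counts) <- as.character(cells$cell_id)
  structure(list(cells = cells, counts = counts, transcripts = transcripts),
            class = "spatial_field")
}

#' @export
print.spatial_field <- function(x, ...) {
  cat("spatial_field:", nrow(x$cells), "cells,",
      nrow(x$transcripts), "transcripts,",
      ncol(x$counts), "gene(s) counted\n")
  print(table(x$cells$cell_type))
  invisible(x)
}

#' Transcript-count positivity call
#'
#' Flags cells as positive for a gene when at least `min_count` transcripts
#' of that gene were detected within the cell's segmentation boundary —
#' the >= 2 default guards against assay noise and segmentation errors
#' producing false positive calls.
#'
#' @param field A [spatial_field()].
#' @param gene Gene name present in the field's count matrix.
#' @param min_count Minimum transcript count, default 2 (inclusive).
#' @param cell_type Optional cell-type restriction (e.g. `"PT"`).
#' @return Character vector of positive `cell_id`s.
#' @export
classify_positive <- function(field, gene = "CDKN1A", min_count = 2,
                              cell_type = NULL) {
  stopifnot(inherits(field, "spatial_field"))
  if (!gene %in% colnames(field$counts)) {
    stop("gene `", gene, "` absent from count matrix", call. = FALSE)
  }
  pos <- field$counts[, gene] >= min_count
  if (!is.null(cell_type)) {
    pos <- pos & field$cells$cell_type %in% cell_type
  }
  field$cells$cell_id[pos]
}

#' Radial transcript enrichment around a query cell population
#'
#' For each annulus `(r - step, r]` out to `r_max` around each query cell's
#' centroid, counts the transcripts of `gene` falling in the annulus summed
#' over query cells, adds a pseudocount of 1, and normalises by annulus
#' area and the number of query cells:
#' `q(r) = (T_q(r) + 1) / (A(r) * N_q)` with `A(r) = pi (r^2 - (r-step)^2)`.
#' A background density `b(r)` is computed identically over `n_background`
#' cells sampled uniformly without replacement from the whole cell
#' population (query cells are not excluded), and the profile is
#' `e(r) = log2(q(r) / b(r))`. Transcripts at distance exactly 0 fall in
#' the first annulus. With `normalize_by = "annulus_cells"` the per-annulus
#' divisor is instead the number of other cell centroids encountered in the
#' annuli (summed over the group's cells, floored at 1).
#'
#' @param field A [spatial_field()].
#' @param query_cells Character vector of query `cell_id`s (nonempty), e.g.
#'   from [classify_positive()].
#' @param gene Gene whose transcripts are profiled.
#' @param r_max,step Search radius and annulus width, um.
#' @param n_background Number of background cells to sample; capped at the
#'   population size (with a message).
#' @param seed Seed for the background draw.
#' @param normalize_by `"query_cells"` (default) or `"annulus_cells"`.
#' @return Data.frame of class `enrichment_profile` with columns `radius`
#'   (annulus outer edge), `q`, `b`, `e`, and attributes `gene`, `n_query`,
#'   `n_background`, `seed`.
#' @export
radial_enrichment <- function(field, query_cells, gene, r_max = 50, step = 1,
                              n_background = 10000, seed = NULL,
                              normalize_by = c("query_cells",
                                               "annulus_cells")) {
  stopifnot(inherits(field, "spatial_field"))
  normalize_by <- match.arg(normalize_by)
  if (length(query_cells) == 0) {
    stop("`query_cells` must be nonempty", call. = FALSE)
  }
  if (!all(query_cells %in% field$cells$cell_id)) {
    stop("unknown cell id(s) in `query_cells`", call. = FALSE)
  }
  tx <- field$transcripts[field$transcripts$gene == gene, , drop = FALSE]
  if (nrow(tx) == 0) {
    stop("no transcripts of gene `", gene, "` in field", call. = FALSE)
  }
  n_cells <- nrow(field$cells)
  if (n_background > n_cells) {
    message("n_background exceeds cell population (", n_cells,
            "); using all cells")
    n_background <- n_cells
  }
  bg_idx <- with_seed(seed, sample.int(n_cells, n_background))

  radii <- seq(step, by = step, length.out = ceiling(r_max / step))
  area <- pi * (radii^2 - (radii - step)^2)

  qi <- match(query_cells, field$cells$cell_id)
  t_q <- annulus_counts(field$cells$x[qi], field$cells$y[qi],
                        tx$x, tx$y, r_max, step)
  t_b <- annulus_counts(field$cells$x[bg_idx], field$cells$y[bg_idx],
                        tx$x, tx$y, r_max, step)
  if (normalize_by == "query_cells") {
    den_q <- rep(length(qi), length(radii))
    den_b <- rep(length(bg_idx), length(radii))
  } else {
    den_q <- pmax(annulus_counts(field$cells$x[qi], field$cells$y[qi],
                                 field$cells$x, field$cells$y, r_max, step,
                                 drop_zero = TRUE), 1)
    den_b <- pmax(annulus_counts(field$cells$x[bg_idx], field$cells$y[bg_idx],
                                 field$cells$x, field$cells$y, r_max, step,
                                 drop_zero = TRUE), 1)
  }
  q <- (t_q + 1) / (area * den_q)
  b <- (t_b + 1) / (area * den_b)
  out <- data.frame(radius = radii, q = q, b = b, e = log2(q / b))
  structure(out,
            class = c("enrichment_profile", "data.frame"),
            gene = gene, n_query = length(qi),
            n_background = length(bg_idx), seed = seed)
}

# Aggregate counts of points per annulus around a set of centres, chunked
# so the cross-distance matrix stays small. Annulus k is ((k-1)*step,
# k*step]; points at distance exactly 0 are assigned to annulus 1 (or
# dropped when counting neighbouring centroids, `drop_zero`).
annulus_counts <- function(cx, cy, px, py, r_max, step, drop_zero = FALSE) {
  n_ann <- ceiling(r_max / step)
  out <- numeric(n_ann)
  if (length(px) == 0 || length(cx) == 0) return(out)
  chunk <- max(1L, floor(4e6 / length(px)))
  for (start in seq(1L, length(cx), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(cx))
    d2 <- outer(cx[idx], px, "-")^2 + outer(cy[idx], py, "-")^2
    d <- sqrt(d2)
    k <- ceiling(d / step)
    if (drop_zero) k[d == 0] <- 0L else k[d == 0] <- 1L
    keep <- k >= 1L & k <= n_ann
    out <- out + tabulate(k[keep], nbins = n_ann)
  }
  out
}

#' @export
print.enrichment_profile <- function(x, ...) {
  cat("Radial enrichment of", attr(x, "gene"), "around",
      attr(x, "n_query"), "query cells (background:",
      attr(x, "n_background"), "cells)\n")
  cat(sprintf("  mean log2 enrichment over %d annuli: %.3f\n",
              nrow(x), mean(x$e)))
  NextMethod()
}

#' @export
plot.enrichment_profile <- function(x, ...) {
  plot(x$radius, x$e, type = "b", pch = 16,
       xlab = "radius (um)", ylab = "log2 enrichment",
       main = paste0(attr(x, "gene"), " radial enrichment"), ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  invisible(x)
}

#' Rank-sum differential expression between two cell groups
#'
#' Per gene, a two-sided Wilcoxon rank-sum (Mann-Whitney) test between the
#' per-cell counts of two groups (e.g. CDKN1A+ vs CDKN1A- proximal tubular
#' cells), with Benjamini-Hochberg adjustment across genes and a log2
#' fold-change of group means with pseudocount 1. The p-value is exact for
#' small tie-free samples and otherwise uses the normal approximation with
#' tie correction (the `stats::wilcox.test` convention).
#'
#' @param expr_pos,expr_neg Numeric matrices (genes x cells) or vectors (one
#'   gene) of per-cell counts; both groups must be nonempty.
#' @return Data.frame with `gene`, `statistic` (Mann-Whitney U for the
#'   positive group), `p`, `p_adj`, `log2fc` (positive over negative).
#' @export
de_wilcoxon <- function(expr_pos, expr_neg) {
  if (is.vector(expr_pos)) expr_pos <- matrix(expr_pos, nrow = 1,
                                              dimnames = list("gene1"))
  if (is.vector(expr_neg)) expr_neg <- matrix(expr_neg, nrow = 1,
                                              dimnames = list("gene1"))
  stopifnot(nrow(expr_pos) == nrow(expr_neg))
  if (ncol(expr_pos) == 0 || ncol(expr_neg) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  genes <- rownames(expr_pos)
  if (is.null(genes)) genes <- paste0("gene", seq_len(nrow(expr_pos)))
  res <- lapply(seq_len(nrow(expr_pos)), function(i) {
    wt <- suppressWarnings(
      stats::wilcox.test(expr_pos[i, ], expr_neg[i, ],
                         alternative = "two.sided")
    )
    c(statistic = unname(wt$statistic), p = wt$p.value,
      log2fc = log2(mean(expr_pos[i, ]) + 1) - log2(mean(expr_neg[i, ]) + 1))
  })
  res <- do.call(rbind, res)
  data.frame(gene = genes,
             statistic = res[, "statistic"],
             p = res[, "p"],
             p_adj = p.adjust(res[, "p"], method = "BH"),
             log2fc = res[, "log2fc"],
             stringsAsFactors = FALSE, row.names = NULL)
}
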