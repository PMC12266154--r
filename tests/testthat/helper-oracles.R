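# Independent brute-force oracles used across tests. These deliberately use
# the most naive possible algorithms (nested loops, full enumeration) and
# never call the package's optimised code paths.

# Quadratic-time radial enrichment: nested loops over cells and transcripts,
# replicating the background draw of radial_enrichment (same seed contract).
brute_force_enrichment <- function(field, query_cells, gene, r_max, step,
                                   n_background, seed) {
  tx <- field$transcripts[field$transcripts$gene == gene, , drop = FALSE]
  n_cells <- nrow(field$cells)
  n_bg <- min(n_background, n_cells)
  bg_idx <- senuro:::with_seed(seed, sample.int(n_cells, n_bg))
  radii <- seq(step, by = step, length.out = ceiling(r_max / step))
  area <- pi * (radii^2 - (radii - step)^2)

  count_group <- function(xs, ys) {
    tq <- numeric(length(radii))
    for (i in seq_along(xs)) {
      for (j in seq_len(nrow(tx))) {
        d <- sqrt((xs[i] - tx$x[j])^2 + (ys[i] - tx$y[j])^2)
        k <- if (d == 0) 1L else ceiling(d / step)
        if (k >= 1 && k <= length(radii)) tq[k] <- tq[k] + 1
      }
    }
    tq
  }
  qi <- match(query_cells, field$cells$cell_id)
  t_q <- count_group(field$cells$x[qi], field$cells$y[qi])
  t_b <- count_group(field$cells$x[bg_idx], field$cells$y[bg_idx])
  q <- (t_q + 1) / (area * length(qi))
  b <- (t_b + 1) / (area * n_bg)
  data.frame(radius = radii, q = q, b = b, e = log2(q / b))
}

# Exact two-sided Fisher p by full enumeration of all 2x2 tables with the
# observed margins, summing hypergeometric probabilities <= observed.
fisher_p_enumeration <- function(a, b, c, d) {
  m <- a + b      # row 1 total
  n <- c + d      # row 2 total
  k <- a + c      # col 1 total
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided rank-sum p by enumerating all group assignments.
wilcox_p_enumeration <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  vals <- c(x, y)
  u_of <- function(idx) {
    r <- rank(vals)
    sum(r[idx]) - nx * (nx + 1) / 2
  }
  u_obs <- u_of(seq_len(nx))
  mu <- nx * (n - nx) / 2
  combos <- combn(n, nx)
  u_all <- apply(combos, 2, u_of)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# AUC by direct enumeration of all (positive, negative) pairs.
auc_enumeration <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Spearman rho from the textbook formula on tie-free data.
spearman_formula <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Tiny hand-built spatial field used in several exact tests.
toy_field <- function() {
  cells <- data.frame(
    cell_id = c("q1", "b1", "b2"),
    x = c(0, 10, 20), y = c(0, 0, 0),
    cell_type = c("PT", "other", "other"),
    stringsAsFactors = FALSE
  )
  counts <- cbind(CDKN1A = c(3, 0, 0), CLU = c(1, 0, 0))
  tx <- data.frame(gene = "CLU", x = c(0.5, 12), y = c(0, 0),
                   stringsAsFactors = FALSE)
  spatial_field(cells, counts, tx)
}
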