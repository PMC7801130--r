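# Shared fixtures and independent oracles, all built in code.

# Toy CountMatrix with deterministic random counts.
toy_count_matrix <- function(n_genes = 20, n_cells = 10, seed = 1,
                             max_count = 6, density = 0.4,
                             gene_prefix = "G", meta = NULL) {
  set.seed(seed)
  x <- matrix(rbinom(n_genes * n_cells, max_count, density), n_genes, n_cells)
  CountMatrix(x,
              gene_ids = sprintf("%s%03d", gene_prefix, seq_len(n_genes)),
              barcodes = sprintf("cell%03d", seq_len(n_cells)),
              cell_meta = meta)
}

# Small simulation shared by several tests (cheap but structured).
small_sim_cfg <- function(seed = 11, ...) {
  sim_config(cells_per_condition_per_donor = 250, n_genes = 1200,
             seed = seed, ...)
}

# Adjusted Rand index (independent of any clustering implementation).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  e0 <- si * sj / choose(n, 2)
  (sij - e0) / ((si + sj) / 2 - e0)
}

# Exhaustive hypergeometric upper tail by direct summation of binomial
# coefficients (enumeration oracle).
hyper_upper_oracle <- function(x, N, m, k) {
  i <- x:min(m, k)
  if (length(i) == 0 || x > min(m, k)) return(0)
  sum(choose(m, i) * choose(N - m, k - i)) / choose(N, k)
}

# Brute-force Benjamini-Hochberg step-up.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Direct running-sum recomputation of the classic GSEA enrichment score.
classic_es_oracle <- function(member_positions, n_total) {
  n_hit <- length(member_positions)
  step <- rep(-1 / (n_total - n_hit), n_total)
  step[member_positions] <- 1 / n_hit
  rs <- cumsum(step)
  rs[which.max(abs(rs))]
}

# Ward agglomeration oracle via the explicit centroid formula
# d(A, B) = sqrt(2 |A| |B| / (|A| + |B|)) * ||centroid_A - centroid_B||,
# independent of stats::hclust's Lance-Williams updates.
ward_oracle_heights <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), function(i) i)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        a <- clusters[[i]]; b <- clusters[[j]]
        ca <- colMeans(X[a, , drop = FALSE])
        cb <- colMeans(X[b, , drop = FALSE])
        d <- sqrt(2 * length(a) * length(b) / (length(a) + length(b))) *
          sqrt(sum((ca - cb)^2))
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters[[length(clusters) + 1]] <- merged
  }
  heights
}

# Manual NeighborSet construction for label-transfer tests.
manual_neighbor_set <- function(idx, dist, ref_barcodes, query_barcodes) {
  structure(list(idx = idx, dist = dist, ref_barcodes = ref_barcodes,
                 query_barcodes = query_barcodes),
            class = "NeighborSet")
}

expect_error_class <- function(expr, class) {
  expect_error(expr, class = class)
}
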