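# Per-gene two-group Welch differential expression with Benjamini-Hochberg
# correction, the joint FDR / fold-change / base-mean filter, top-N signature
# extraction, and binarized-overlap hierarchical clustering of gene lists.
#
# Conventions (the source analyses do not print their formulas; these are
# fixed package decisions, documented in the vignette):
#   log2_fold_change = log2((meanA' + eps) / (meanB' + eps)), eps = 1e-9,
#     where mean' is the group mean of expm1(ln-normalized expression);
#   log2_mean_expr   = log2(pooled mean of expm1 expression + eps).

DE_EPS <- 1e-9

#' Per-gene Welch t-test between two cell groups
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and two-sided p-values, computed gene-wise between two disjoint cell
#' groups. Zero-variance genes: p = 1 when the group means are also equal;
#' p = 0 and `degenerate = TRUE` when means differ (infinite t evidence).
#' The CAR pseudo-feature is excluded.
#'
#' @param e [ExprMatrix()] of ln-normalized expression.
#' @param group_a,group_b disjoint barcode vectors, each of size >= 2.
#' @param exclude_features gene_ids excluded from testing (default CAR).
#' @return data.frame of class `DEResult` with columns gene_id, gene_name,
#'   log2_fold_change, log2_mean_expr, t_statistic, df, p_value, q_value,
#'   degenerate, n_a, n_b. `q_value` is BH-adjusted across all tested genes.
#' @export
welch_ttest_by_gene <- function(e, group_a, group_b,
                                exclude_features = car_feature_id()) {
  stopifnot(inherits(e, "ExprMatrix"))
  if (length(intersect(group_a, group_b)) > 0) {
    stop_config("groups overlap: ",
                paste(head(intersect(group_a, group_b), 3), collapse = ", "))
  }
  ia <- match(group_a, e$barcodes); ib <- match(group_b, e$barcodes)
  if (anyNA(ia) || anyNA(ib)) stop_config("unknown barcodes in groups")
  na <- length(ia); nb <- length(ib)
  if (na < 2 || nb < 2) stop_config("each group needs at least 2 cells")

  keep <- !(e$gene_ids %in% exclude_features)
  A <- e$values[keep, ia, drop = FALSE]
  B <- e$values[keep, ib, drop = FALSE]
  ma <- Matrix::rowMeans(A); mb <- Matrix::rowMeans(B)
  va <- (Matrix::rowMeans(A^2) - ma^2) * na / (na - 1)
  vb <- (Matrix::rowMeans(B^2) - mb^2) * nb / (nb - 1)
  va <- pmax(va, 0); vb <- pmax(vb, 0)

  se2 <- va / na + vb / nb
  t_stat <- ifelse(se2 > 0, (ma - mb) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / (ifelse(va > 0, (va / na)^2 / (na - 1), 0) +
                          ifelse(vb > 0, (vb / nb)^2 / (nb - 1), 0)),
               NA_real_)
  p <- ifelse(se2 > 0, 2 * pt(-abs(t_stat), df), NA_real_)
  zero_var <- se2 == 0
  eq_mean <- abs(ma - mb) < 1e-12
  p[zero_var & eq_mean] <- 1
  p[zero_var & !eq_mean] <- 0
  degenerate <- zero_var & !eq_mean

  # residual-type inputs can have negative expm1 means; clamp at zero so the
  # fold change stays defined
  ea <- pmax(Matrix::rowMeans(expm1(A)), 0)
  eb <- pmax(Matrix::rowMeans(expm1(B)), 0)
  log2fc <- log2((ea + DE_EPS) / (eb + DE_EPS))
  pooled <- (na * ea + nb * eb) / (na + nb)
  log2mean <- log2(pooled + DE_EPS)

  res <- data.frame(gene_id = e$gene_ids[keep],
                    gene_name = e$gene_names[keep],
                    log2_fold_change = log2fc,
                    log2_mean_expr = log2mean,
                    t_statistic = t_stat,
                    df = df,
                    p_value = p,
                    q_value = bh_adjust(p),
                    degenerate = degenerate,
                    n_a = na, n_b = nb,
                    stringsAsFactors = FALSE)
  class(res) <- c("DEResult", "data.frame")
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control: sorted ascending,
#' `q_i = min_{j >= i} p_j * n / j`, returned in the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_config("p-values outside [0, 1]")
  p.adjust(p, method = "BH")
}

#' Differential-expression filter thresholds
#'
#' The three joint criteria for calling a gene differentially expressed:
#' FDR strictly below `max_fdr`, |log2 fold change| strictly above
#' `min_abs_log2fc`, and log2 base mean expression strictly above
#' `min_log2_mean` (analysis-dependent: -5 for most contrasts, -7 or -3 for
#' specific ones).
#'
#' @param max_fdr FDR cutoff (default 0.05, strict `<`).
#' @param min_abs_log2fc fold-change cutoff (default 1, strict `>`).
#' @param min_log2_mean base-mean cutoff (default -5, strict `>`).
#' @return object of class `DEFilter`.
#' @export
de_filter <- function(max_fdr = 0.05, min_abs_log2fc = 1, min_log2_mean = -5) {
  stopifnot(max_fdr > 0, max_fdr <= 1)
  structure(list(max_fdr = max_fdr, min_abs_log2fc = min_abs_log2fc,
                 min_log2_mean = min_log2_mean),
            class = "DEFilter")
}

#' Apply the three-criterion DE filter
#'
#' @param results `DEResult` data.frame.
#' @param f [de_filter()].
#' @return list with `up` and `down` `DEResult` subsets. Upregulated: q <
#'   max_fdr AND log2FC > min_abs_log2fc AND log2 mean > min_log2_mean;
#'   downregulated mirrors with log2FC < -min_abs_log2fc.
#' @export
apply_de_filter <- function(results, f = de_filter()) {
  stopifnot(inherits(f, "DEFilter"))
  base <- results$q_value < f$max_fdr &
    results$log2_mean_expr > f$min_log2_mean
  up <- results[base & results$log2_fold_change > f$min_abs_log2fc, , drop = FALSE]
  down <- results[base & results$log2_fold_change < -f$min_abs_log2fc, , drop = FALSE]
  list(up = up, down = down)
}

#' Top upregulated genes
#'
#' The `n` "most upregulated" genes among those with positive log2 fold
#' change, ranked by ascending q-value then descending log2 fold change.
#'
#' @param results `DEResult` data.frame.
#' @param n number of genes (default 200).
#' @return character vector of gene_ids (shorter, with a warning, when fewer
#'   genes are upregulated).
#' @export
top_upregulated <- function(results, n = 200) {
  up <- results[results$log2_fold_change > 0, , drop = FALSE]
  ord <- order(up$q_value, -up$log2_fold_change)
  up <- up[ord, , drop = FALSE]
  if (nrow(up) < n) {
    warning("only ", nrow(up), " upregulated genes available (requested ", n, ")",
            call. = FALSE)
  }
  head(up$gene_id, n)
}

#' Cluster gene lists by binarized overlap
#'
#' Converts named upregulated-gene lists into a binary membership matrix
#' (rows: union of genes, columns: comparisons; 1 when the gene is in that
#' comparison's list), then Ward hierarchical clustering on Euclidean
#' distances over rows (genes) and columns, with flat gene groups cut from
#' the gene dendrogram.
#'
#' @param gene_lists named list of character vectors (>= 2 lists).
#' @param n_groups flat gene-group count (default 5).
#' @return list with `membership` (binary matrix), `gene_hclust`,
#'   `comparison_hclust`, `gene_groups` (named integer vector).
#' @export
overlap_cluster <- function(gene_lists, n_groups = 5) {
  if (length(gene_lists) < 2) stop_config("need at least 2 gene lists")
  union_genes <- unique(unlist(gene_lists))
  memb <- vapply(gene_lists, function(g) as.integer(union_genes %in% g),
                 integer(length(union_genes)))
  rownames(memb) <- union_genes
  gene_h <- hclust(dist(memb, method = "euclidean"), method = "ward.D2")
  comp_h <- hclust(dist(t(memb), method = "euclidean"), method = "ward.D2")
  k <- min(n_groups, nrow(memb))
  groups <- cutree(gene_h, k = k)
  list(membership = memb, gene_hclust = gene_h, comparison_hclust = comp_h,
       gene_groups = groups)
}

#' Write a DE table as TSV
#'
#' Fixed column names: gene_id, gene_name, log2fc, log2_mean, t, p, q.
#'
#' @param results `DEResult` data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(results, path) {
  out <- data.frame(gene_id = results$gene_id,
                    gene_name = results$gene_name,
                    log2fc = results$log2_fold_change,
                    log2_mean = results$log2_mean_expr,
                    t = results$t_statistic,
                    p = results$p_value,
                    q = results$q_value)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
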