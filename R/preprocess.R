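# QC filtering, CAR-expressing cell calling, normalization, highly variable
# gene selection, covariate regression and cell-cycle scoring.
#
# Boundary semantics follow the QC wording literally: "at least" n genes
# detected is >=, "less than" 8% mitochondrial and "more than" the UMI floor
# are strict.

#' QC thresholds
#'
#' @param min_genes_per_cell minimum genes detected per cell (inclusive:
#'   "at least"). 400 for leukapheresis, 1000 for product samples.
#' @param max_mito_fraction mitochondrial UMI fraction cutoff (exclusive:
#'   "less than"); default 0.08.
#' @param min_total_umis total-UMI floor (exclusive: "more than"); 10,000 for
#'   leukapheresis, 30,000 for product samples.
#' @param min_gene_total_umis keep genes with at least this many total UMIs
#'   after cell filtering; default 2 ("more than 1 UMI count").
#' @return object of class `QCThresholds`.
#' @export
qc_thresholds <- function(min_genes_per_cell = 1000,
                          max_mito_fraction = 0.08,
                          min_total_umis = 30000,
                          min_gene_total_umis = 2) {
  stopifnot(min_genes_per_cell >= 0, min_total_umis >= 0,
            min_gene_total_umis >= 0,
            max_mito_fraction >= 0, max_mito_fraction <= 1)
  structure(list(min_genes_per_cell = min_genes_per_cell,
                 max_mito_fraction = max_mito_fraction,
                 min_total_umis = min_total_umis,
                 min_gene_total_umis = min_gene_total_umis),
            class = "QCThresholds")
}

#' Preset QC thresholds per sample class
#'
#' @param class `"product"` (1000 genes, > 30,000 UMIs) or `"leukapheresis"`
#'   (400 genes, > 10,000 UMIs); both use the 8% mitochondrial cutoff.
#' @return [qc_thresholds()] object.
#' @export
qc_presets <- function(class = c("product", "leukapheresis")) {
  class <- match.arg(class)
  if (class == "product") qc_thresholds(1000, 0.08, 30000, 2)
  else qc_thresholds(400, 0.08, 10000, 2)
}

#' Identify mitochondrial genes by symbol prefix
#'
#' @param m CountMatrix.
#' @param prefix symbol prefix (default `"MT-"`).
#' @return [GeneSet()] of matching symbols (possibly empty genes -> error).
#' @export
mito_gene_set <- function(m, prefix = "MT-") {
  hits <- m$gene_names[startsWith(m$gene_names, prefix)]
  if (length(hits) == 0) {
    stop_config("no gene symbols with prefix '", prefix, "'")
  }
  GeneSet("mitochondrial", unique(hits),
          paste0("symbols prefixed '", prefix, "'"))
}

#' Apply per-cell and per-gene quality control
#'
#' Keeps cells with `genes_detected >= min_genes_per_cell` AND
#' `mito_fraction < max_mito_fraction` AND `total_umis > min_total_umis`,
#' then drops genes whose total UMI count (over the retained cells) is below
#' `min_gene_total_umis`. The CAR pseudo-feature is never dropped by the gene
#' filter. Idempotent for fixed thresholds.
#'
#' @param m CountMatrix.
#' @param t [qc_thresholds()].
#' @param mito_genes GeneSet of mitochondrial symbols, or NULL to detect by
#'   the `"MT-"` prefix.
#' @param exclude_features gene_ids exempt from the gene filter and from the
#'   per-cell totals (default: the CAR pseudo-feature).
#' @return list with elements `matrix` (filtered CountMatrix) and `report`
#'   (`QCReport`: cells in/out, per-criterion removal counts, genes in/out).
#' @export
apply_qc <- function(m, t, mito_genes = NULL,
                     exclude_features = car_feature_id()) {
  stopifnot(inherits(m, "CountMatrix"), inherits(t, "QCThresholds"))
  if (is.null(mito_genes)) mito_genes <- mito_gene_set(m)
  mito_ids <- resolve_symbols(m, mito_genes$genes, missing_ok = TRUE)
  if (length(mito_ids) == 0) {
    stop_config("no mitochondrial genes resolvable in the matrix")
  }
  excl <- intersect(exclude_features, m$gene_ids)
  cellular <- !(m$gene_ids %in% excl)

  counts <- m$counts[cellular, , drop = FALSE]
  total <- Matrix::colSums(counts)
  detected <- Matrix::colSums(counts > 0)
  mito <- Matrix::colSums(m$counts[m$gene_ids %in% mito_ids, , drop = FALSE])
  mito_frac <- ifelse(total > 0, mito / total, 0)

  fail_genes <- detected < t$min_genes_per_cell
  fail_mito <- mito_frac >= t$max_mito_fraction
  fail_umis <- total <= t$min_total_umis
  keep_cell <- !(fail_genes | fail_mito | fail_umis)

  if (!any(keep_cell)) {
    warning("QC removed every cell", call. = FALSE)
  }
  kept <- subset_count_matrix(m, cells = which(keep_cell))
  gene_tot <- Matrix::rowSums(kept$counts)
  keep_gene <- gene_tot >= t$min_gene_total_umis | kept$gene_ids %in% excl
  out <- subset_count_matrix(kept, genes = which(keep_gene))

  report <- structure(list(
    cells_in = ncol(m$counts),
    cells_removed_by_criterion = c(
      min_genes_per_cell = sum(fail_genes),
      max_mito_fraction = sum(fail_mito),
      min_total_umis = sum(fail_umis)),
    cells_removed_union = sum(!keep_cell),
    cells_out = sum(keep_cell),
    genes_in = nrow(m$counts),
    genes_out = sum(keep_gene)), class = "QCReport")
  list(matrix = out, report = report)
}

#' @exportS3Method base::print
print.QCReport <- function(x, ...) {
  cat("QC: cells", x$cells_in, "->", x$cells_out,
      "(removed", x$cells_removed_union, ");",
      "genes", x$genes_in, "->", x$genes_out, "\n")
  for (nm in names(x$cells_removed_by_criterion)) {
    cat("  failing ", nm, ": ", x$cells_removed_by_criterion[[nm]], "\n", sep = "")
  }
  invisible(x)
}

#' Call CAR-expressing cells from the CAR pseudo-feature
#'
#' A cell is flagged CAR-expressing iff its CAR UMI count is at least
#' `min_car_umis`.
#'
#' @param m CountMatrix.
#' @param car_feature gene_id of the CAR feature row.
#' @param min_car_umis UMI threshold (default 1).
#' @return logical vector named by barcode, with attribute `summary`: a
#'   data.frame of CAR+ percentage overall and per sample.
#' @export
detect_car_cells <- function(m, car_feature = car_feature_id(),
                             min_car_umis = 1) {
  stopifnot(inherits(m, "CountMatrix"))
  row <- match(car_feature, m$gene_ids)
  if (is.na(row)) stop_config("CAR feature '", car_feature, "' not in matrix")
  umis <- as.numeric(m$counts[row, ])
  flag <- setNames(umis >= min_car_umis, m$barcodes)
  sample_id <- if ("sample_id" %in% colnames(m$cell_meta)) {
    m$cell_meta$sample_id
  } else rep("all", length(flag))
  summary <- data.frame(sample_id = "overall", car_pct = 100 * mean(flag))
  if (length(flag) > 0) {
    per <- aggregate(list(car_pct = flag), list(sample_id = sample_id),
                     function(z) 100 * mean(z))
    summary <- rbind(summary, per)
  }
  attr(flag, "summary") <- summary
  flag
}

#' Library-size normalization and log transform
#'
#' Scales each cell so its cellular total (excluding the CAR pseudo-feature)
#' equals `target_sum`, then applies `ln(1 + x)`. Cells with zero cellular
#' total cannot be scaled and are dropped with a warning.
#'
#' @param m CountMatrix.
#' @param target_sum per-cell total after scaling (default 10,000).
#' @param exclude_features gene_ids excluded from the per-cell total (and
#'   left on raw-count scale pass-through of the same scaling; default CAR).
#' @return [ExprMatrix()] of ln-normalized values.
#' @export
normalize_log <- function(m, target_sum = 10000,
                          exclude_features = car_feature_id()) {
  stopifnot(inherits(m, "CountMatrix"), ncol(m$counts) > 0)
  excl <- m$gene_ids %in% exclude_features
  totals <- Matrix::colSums(m$counts[!excl, , drop = FALSE])
  keep <- totals > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-total cell(s) dropped during normalization",
            call. = FALSE)
  }
  counts <- m$counts[, keep, drop = FALSE]
  totals <- totals[keep]
  scaled <- counts %*% Matrix::Diagonal(x = target_sum / totals)
  vals <- log1p(scaled)
  ExprMatrix(as(vals, "CsparseMatrix"),
             gene_ids = m$gene_ids, gene_names = m$gene_names,
             barcodes = m$barcodes[keep],
             cell_meta = m$cell_meta[keep, , drop = FALSE],
             transform_log = c(sprintf("normalize_total(%g)", target_sum),
                               "log1p"))
}

#' HVG selection parameters
#'
#' Mean/dispersion cutoffs follow the Seurat-flavor convention: per-gene mean
#' and dispersion (variance/mean) are computed on the `expm1` scale, the mean
#' cutoffs apply to `log1p(mean)` and dispersions are log-transformed and
#' z-scored within `n_bins` equal-frequency mean bins.
#'
#' @param min_mean,max_mean open interval for the (log1p) gene mean; defaults
#'   0.02 and 3.
#' @param min_disp minimum normalized dispersion (default 0.5).
#' @param n_bins number of mean bins (default 20).
#' @param batch_key cell_meta column defining batches; HVGs are selected
#'   within each batch separately and merged. NULL treats all cells as one
#'   batch.
#' @return object of class `HVGParams`.
#' @export
hvg_params <- function(min_mean = 0.02, max_mean = 3, min_disp = 0.5,
                       n_bins = 20, batch_key = "sample_id") {
  stopifnot(min_mean < max_mean, n_bins >= 1)
  structure(list(min_mean = min_mean, max_mean = max_mean,
                 min_disp = min_disp, n_bins = n_bins, batch_key = batch_key),
            class = "HVGParams")
}

# Single-batch Seurat-flavor dispersion statistics.
hvg_single_batch <- function(vals, p) {
  x <- expm1(vals)
  mu <- Matrix::rowMeans(x)
  ex2 <- Matrix::rowMeans(x^2)
  v <- (ex2 - mu^2) * ncol(x) / max(ncol(x) - 1, 1)
  disp <- ifelse(mu > 0, v / mu, NA_real_)
  log_disp <- suppressWarnings(log(disp))
  log_disp[!is.finite(log_disp)] <- NA_real_
  log_mu <- log1p(mu)
  bin <- cut(rank(log_mu, ties.method = "min"), breaks = p$n_bins,
             labels = FALSE, include.lowest = TRUE)
  norm_disp <- rep(NA_real_, length(mu))
  for (b in unique(bin)) {
    idx <- which(bin == b & !is.na(log_disp))
    if (length(idx) >= 2) {
      s <- sd(log_disp[idx])
      if (is.finite(s) && s > 0) {
        norm_disp[idx] <- (log_disp[idx] - mean(log_disp[idx])) / s
      } else {
        norm_disp[idx] <- 0
      }
    } else if (length(idx) == 1) {
      norm_disp[idx] <- 0  # singleton bin: no spread to standardize against
    }
  }
  flagged <- !is.na(norm_disp) & log_mu > p$min_mean & log_mu < p$max_mean &
    norm_disp >= p$min_disp
  list(flagged = flagged, norm_disp = norm_disp)
}

#' Select highly variable genes
#'
#' Seurat-flavor mean/dispersion selection, run within each batch and merged:
#' a gene is highly variable if flagged in at least one batch; the returned
#' list is ordered by (number of batches flagged, then median normalized
#' dispersion across batches), both descending. The CAR pseudo-feature is
#' always excluded.
#'
#' @param e [ExprMatrix()] of ln-normalized values.
#' @param p [hvg_params()].
#' @param exclude_features gene_ids never reported (default CAR feature).
#' @return character vector of highly variable gene_ids.
#' @export
select_hvgs <- function(e, p = hvg_params(),
                        exclude_features = car_feature_id()) {
  stopifnot(inherits(e, "ExprMatrix"), inherits(p, "HVGParams"))
  batches <- if (is.null(p$batch_key)) {
    rep("all", ncol(e$values))
  } else {
    if (!p$batch_key %in% colnames(e$cell_meta)) {
      stop_config("batch_key '", p$batch_key, "' not in cell_meta")
    }
    as.character(e$cell_meta[[p$batch_key]])
  }
  n_flag <- integer(nrow(e$values))
  disp_mat <- list()
  for (b in unique(batches)) {
    cells <- which(batches == b)
    if (length(cells) < 2) {
      warning("batch '", b, "' has fewer than 2 cells; skipped", call. = FALSE)
      next
    }
    res <- hvg_single_batch(e$values[, cells, drop = FALSE], p)
    n_flag <- n_flag + res$flagged
    disp_mat[[b]] <- res$norm_disp
  }
  if (length(disp_mat) == 0) stop_config("no usable batches for HVG selection")
  med_disp <- apply(do.call(cbind, disp_mat), 1, median, na.rm = TRUE)
  ok <- n_flag >= 1 & !(e$gene_ids %in% exclude_features)
  ids <- e$gene_ids[ok]
  ids[order(-n_flag[ok], -med_disp[ok])]
}

#' Regress covariates out of expression
#'
#' Per gene, ordinary least squares of expression on the covariates (with
#' intercept); returns the residuals. Used to remove read depth, detected
#' genes, mitochondrial counts and cell-cycle scores.
#'
#' @param e [ExprMatrix()].
#' @param covariates data.frame/matrix of numeric covariates, one row per
#'   cell, no missing values.
#' @return [ExprMatrix()] of residuals (dense).
#' @export
regress_out <- function(e, covariates) {
  stopifnot(inherits(e, "ExprMatrix"))
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != ncol(e$values)) {
    stop_config("covariates must have one row per cell")
  }
  if (!all(complete.cases(covariates))) stop_config("covariates contain NA")
  # constant covariates carry no information beyond the intercept
  constant <- vapply(covariates, function(z) var(z) == 0, logical(1))
  X <- cbind(`(intercept)` = 1, as.matrix(covariates[, !constant, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop_config("rank-deficient covariates; collinear column(s): ",
                paste(dropped, collapse = ", "))
  }
  Y <- t(as.matrix(e$values))          # cells x genes
  resid <- qr.resid(qrX, Y)
  ExprMatrix(t(resid), gene_ids = e$gene_ids, gene_names = e$gene_names,
             barcodes = e$barcodes, cell_meta = e$cell_meta,
             transform_log = c(e$transform_log,
                               sprintf("regress_out(%s)",
                                       paste(colnames(covariates), collapse = ","))))
}

#' Standard QC covariates for regression
#'
#' Convenience builder: per-cell total UMIs, detected genes and mitochondrial
#' counts from the raw matrix (CAR feature excluded), optionally joined with
#' cell-cycle scores.
#'
#' @param m CountMatrix (pre-normalization).
#' @param cells barcodes to keep (defaults to all).
#' @param mito_genes GeneSet or NULL for `"MT-"` prefix detection.
#' @param cc_scores optional data.frame with `S_score`/`G2M_score` columns.
#' @return data.frame of covariates.
#' @export
qc_covariates <- function(m, cells = m$barcodes, mito_genes = NULL,
                          cc_scores = NULL) {
  if (is.null(mito_genes)) mito_genes <- mito_gene_set(m)
  mito_ids <- resolve_symbols(m, mito_genes$genes)
  cellular <- !(m$gene_ids %in% car_feature_id())
  idx <- match(cells, m$barcodes)
  counts <- m$counts[cellular, idx, drop = FALSE]
  out <- data.frame(
    total_umis = Matrix::colSums(counts),
    genes_detected = Matrix::colSums(counts > 0),
    mito_counts = Matrix::colSums(m$counts[m$gene_ids %in% mito_ids, idx,
                                           drop = FALSE]),
    row.names = cells)
  if (!is.null(cc_scores)) out <- cbind(out, cc_scores[cells, , drop = FALSE])
  out
}

#' Score cell-cycle stage
#'
#' S and G2M scores via [score_signature()]; a cell's stage is the argmax of
#' the two scores if either is positive, else G1 (ties at zero fall to G1).
#'
#' @param e [ExprMatrix()].
#' @param s_genes,g2m_genes GeneSets of S-phase and G2M-phase genes.
#' @param params [score_params()].
#' @return data.frame with `S_score`, `G2M_score`, `stage` per cell.
#' @export
cellcycle_score <- function(e, s_genes, g2m_genes, params = score_params()) {
  s_ids <- resolve_symbols(e, s_genes$genes)
  g_ids <- resolve_symbols(e, g2m_genes$genes)
  if (length(s_ids) == 0 && length(g_ids) == 0) {
    stop_config("neither cell-cycle gene set is present in the matrix")
  }
  s <- if (length(s_ids)) {
    score_signature(e, GeneSet("S", e$gene_names[match(s_ids, e$gene_ids)]), params)
  } else rep(0, ncol(e$values))
  g <- if (length(g_ids)) {
    score_signature(e, GeneSet("G2M", e$gene_names[match(g_ids, e$gene_ids)]), params)
  } else rep(0, ncol(e$values))
  stage <- ifelse(s <= 0 & g <= 0, "G1", ifelse(s > g, "S", "G2M"))
  data.frame(S_score = s, G2M_score = g, stage = stage,
             row.names = e$barcodes)
}
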