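# Gene-signature scoring with expression-binned control genes, exhaustion
# classification at a fixed score threshold, and extreme-cell selection for
# the exhausted vs non-exhausted contrast.

#' Signature scoring parameters
#'
#' Parameters of the binned-control scoring scheme: genes are binned by
#' average expression, and each signature gene contributes `ctrl_per_gene`
#' control genes sampled from its bin.
#'
#' @param n_bins number of equal-frequency expression bins (default 25).
#' @param ctrl_per_gene control genes sampled per signature gene (default 50).
#' @param seed integer seed for the control sampling.
#' @return object of class `ScoreParams`.
#' @export
score_params <- function(n_bins = 25, ctrl_per_gene = 50, seed = 0L) {
  stopifnot(n_bins >= 1, ctrl_per_gene >= 1)
  structure(list(n_bins = as.integer(n_bins),
                 ctrl_per_gene = as.integer(ctrl_per_gene),
                 seed = as.integer(seed)),
            class = "ScoreParams")
}

#' Intersect a signature with the highly variable genes
#'
#' Keeps signature genes (by symbol) whose gene_ids appear in the HVG list,
#' preserving the signature's order. The size reduction is reported via
#' message (e.g. a 107-gene signature reducing to its 26 HVG members).
#'
#' @param sig [GeneSet()] of symbols.
#' @param hvgs character vector of highly variable gene_ids.
#' @param m CountMatrix/ExprMatrix used to resolve symbols to gene_ids.
#' @return [GeneSet()] restricted to HVG members.
#' @export
intersect_signature <- function(sig, hvgs, m) {
  ids <- resolve_symbols(m, sig$genes, missing_ok = TRUE)
  keep_ids <- ids[ids %in% hvgs]
  if (length(keep_ids) == 0) {
    stop_config("signature '", sig$name, "' has no genes among the HVGs; ",
                "review HVG thresholds or the signature")
  }
  syms <- m$gene_names[match(keep_ids, m$gene_ids)]
  syms <- sig$genes[sig$genes %in% syms]   # preserve signature order
  message("signature '", sig$name, "': ", length(sig$genes), " genes -> ",
          length(syms), " after HVG intersection")
  GeneSet(sig$name, syms, sig$description)
}

#' Score cells against a gene signature with binned controls
#'
#' Per cell: mean expression of the signature genes minus the mean expression
#' of a control gene pool. Controls are matched on expression level: all genes
#' are ranked by average expression across cells and split into `n_bins`
#' equal-frequency bins; for each signature gene, `ctrl_per_gene` control
#' genes are sampled (seeded, without replacement where the bin allows) from
#' the same bin, excluding signature genes. The score is invariant to adding
#' a constant to the matrix and to gene order.
#'
#' @param e [ExprMatrix()].
#' @param sig [GeneSet()] of gene symbols with at least one member present.
#' @param p [score_params()].
#' @param exclude_features gene_ids never used as signature or control
#'   (default CAR feature).
#' @return numeric score per cell, named by barcode.
#' @export
score_signature <- function(e, sig, p = score_params(),
                            exclude_features = car_feature_id()) {
  stopifnot(inherits(e, "ExprMatrix"), inherits(sig, "GeneSet"))
  usable <- !(e$gene_ids %in% exclude_features)
  sig_ids <- resolve_symbols(e, sig$genes, missing_ok = TRUE)
  sig_ids <- sig_ids[sig_ids %in% e$gene_ids[usable]]
  if (length(sig_ids) == 0) {
    stop_config("no signature gene of '", sig$name, "' present in the matrix")
  }
  vals <- e$values
  avg <- Matrix::rowMeans(vals)
  pool <- which(usable)
  # equal-frequency bins over the usable genes
  bins <- cut(rank(avg[pool], ties.method = "min"), breaks = p$n_bins,
              labels = FALSE, include.lowest = TRUE)
  bin_of <- setNames(bins, e$gene_ids[pool])
  sig_idx <- match(sig_ids, e$gene_ids)

  # candidates are addressed by sorted gene_id so that the sampled control
  # pool is invariant to the gene order of the input matrix
  ctrl_ids <- with_seed(p$seed, {
    unlist(lapply(sig_ids, function(gid) {
      b <- bin_of[[gid]]
      cand <- sort(setdiff(e$gene_ids[pool[bins == b]], sig_ids))
      if (length(cand) == 0) return(character(0))
      if (length(cand) < p$ctrl_per_gene) {
        warning("control bin for '", gid, "' smaller than ctrl_per_gene; ",
                "sampling with replacement", call. = FALSE)
        sample(cand, p$ctrl_per_gene, replace = TRUE)
      } else {
        sample(cand, p$ctrl_per_gene)
      }
    }))
  })
  ctrl_idx <- match(ctrl_ids, e$gene_ids)
  sig_mean <- Matrix::colMeans(vals[sig_idx, , drop = FALSE])
  ctrl_mean <- if (length(ctrl_idx)) {
    Matrix::colMeans(vals[ctrl_idx, , drop = FALSE])
  } else rep(0, ncol(vals))
  setNames(as.numeric(sig_mean - ctrl_mean), e$barcodes)
}

#' Classify cells as exhausted by score threshold
#'
#' A cell is called exhausted iff its score is strictly larger than
#' `threshold` (default 0.6).
#'
#' @param scores named numeric vector from [score_signature()].
#' @param threshold classification threshold (strict `>`).
#' @param cell_meta optional per-cell data.frame (row names = barcodes) used
#'   for the summary breakdown.
#' @param groups cell_meta columns to summarize over.
#' @return object of class `ExhaustionCall`: list with `score`, `exhausted`
#'   (logical, named), `threshold`, `summary` (counts and percentages per
#'   group when metadata is supplied).
#' @export
classify_exhausted <- function(scores, threshold = 0.6, cell_meta = NULL,
                               groups = intersect(c("condition", "sample_id"),
                                                  colnames(cell_meta))) {
  if (any(!is.finite(scores))) stop_config("scores must be finite")
  exhausted <- scores > threshold
  summary <- NULL
  if (!is.null(cell_meta) && length(groups)) {
    df <- cell_meta[names(scores), groups, drop = FALSE]
    summary <- aggregate(list(n_exhausted = exhausted),
                         df, sum)
    ncell <- aggregate(list(n_cells = rep(1L, length(scores))), df, sum)
    summary <- merge(summary, ncell)
    summary$pct_exhausted <- round_half_up(100 * summary$n_exhausted /
                                             summary$n_cells, 1)
  }
  structure(list(score = scores, exhausted = exhausted,
                 threshold = threshold, summary = summary),
            class = "ExhaustionCall")
}

#' @exportS3Method base::print
print.ExhaustionCall <- function(x, ...) {
  cat("ExhaustionCall:", sum(x$exhausted), "of", length(x$exhausted),
      "cells above threshold", x$threshold, "\n")
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

#' Select extreme-scoring cells
#'
#' Top `n` cells by descending score and bottom `n` by ascending score within
#' a mask, disjoint by construction; ties are broken by barcode lexicographic
#' order for determinism. When the mask holds fewer than `2n` cells, `n` is
#' reduced to `floor(|mask| / 2)` with a warning.
#'
#' @param scores named numeric vector.
#' @param cell_mask barcodes (or logical vector over `names(scores)`)
#'   restricting the selection.
#' @param n cells per extreme (default 153).
#' @return list with character vectors `top` and `bottom`.
#' @export
select_extremes <- function(scores, cell_mask = names(scores), n = 153) {
  if (is.logical(cell_mask)) cell_mask <- names(scores)[cell_mask]
  if (length(cell_mask) == 0) stop_config("empty cell mask")
  s <- scores[cell_mask]
  if (anyNA(s)) stop_config("mask contains unknown barcodes")
  if (length(s) < 2 * n) {
    n <- floor(length(s) / 2)
    warning("mask smaller than 2n; n reduced to ", n, call. = FALSE)
  }
  ord_desc <- order(-s, names(s))
  ord_asc <- order(s, names(s))
  list(top = names(s)[ord_desc][seq_len(n)],
       bottom = names(s)[ord_asc][seq_len(n)])
}

#' Packaged exhaustion signature (synthetic reconstruction)
#'
#' A chronic-stimulation T-cell exhaustion signature assembled from
#' inhibitory receptors, exhaustion-associated transcription factors and
#' chemokines reported for exhausted CAR-T and virus-exposed T cells. This is
#' a synthetic stand-in shipped for self-contained runs — not the original
#' supplementary gene list — and any GMT can be substituted.
#'
#' @return [GeneSet()].
#' @export
exhaustion_signature <- function() {
  path <- system.file("extdata", "exhaustion_signature_synthetic.gmt",
                      package = "cartatlas")
  read_gmt(path)[[1]]
}
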