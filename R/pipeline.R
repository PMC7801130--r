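# End-to-end orchestration: simulate -> QC -> CAR calling -> normalize ->
# HVG -> cluster -> integrate -> differential expression -> exhaustion
# scoring -> enrichment -> composition report.

#' Default cell-cycle gene sets
#'
#' S-phase and G2M-phase marker modules used for cell-cycle scoring. These
#' match the synthetic generator's planted cell-cycle programs; for real data
#' substitute any published cell-cycle gene list.
#'
#' @return list with GeneSets `s` and `g2m`.
#' @export
cellcycle_gene_sets <- function() {
  list(s = GeneSet("S_phase", S_GENES, "S-phase program genes"),
       g2m = GeneSet("G2M_phase", G2M_GENES, "G2M-phase program genes"))
}

#' Pipeline run configuration
#'
#' Collects every stage's parameters with the package defaults; any field can
#' be overridden. Seeds for all stochastic stages derive from `seed`.
#'
#' @param sim [sim_config()] for the synthetic input.
#' @param qc_product,qc_leukapheresis [qc_thresholds()] per sample class.
#' @param hvg [hvg_params()].
#' @param n_pcs principal components (default 50).
#' @param knn_k neighbours for the within-dataset kNN graph (default 15).
#' @param resolutions modularity-scan resolutions (default 0.1 to 2 by 0.1).
#' @param resolution optional override of the scan's suggested resolution.
#' @param cluster_method `"leiden"` (product default) or `"louvain"`.
#' @param k_within batch-balanced neighbours per batch for label transfer
#'   (default 7).
#' @param de [de_filter()] for the activation contrast.
#' @param de_extremes [de_filter()] for the exhausted-extremes contrast
#'   (base-mean cutoff -3).
#' @param score [score_params()].
#' @param signature [GeneSet()] scored for exhaustion (default the packaged
#'   synthetic signature).
#' @param exhaustion_threshold classification threshold (default 0.6).
#' @param n_extremes cells per extreme for the exhaustion contrast
#'   (default 153).
#' @param n_top_upregulated genes taken per comparison for overlap
#'   clustering (default 200).
#' @param gsea_n_perm permutations for pre-ranked GSEA (default 1000).
#' @param include_leukapheresis run the leukapheresis arm and label transfer.
#' @param regress_covariates regress out depth/genes/mito/cell-cycle before
#'   PCA (default TRUE, matching the processing recipe; scoring stays on
#'   ln-normalized values).
#' @param outdir optional artifact directory; when set, matrices, tables and
#'   the report are written with a content-hash manifest.
#' @param seed master seed.
#' @return object of class `RunConfig`.
#' @export
run_config <- function(sim = sim_config(),
                       qc_product = qc_presets("product"),
                       qc_leukapheresis = qc_presets("leukapheresis"),
                       hvg = hvg_params(),
                       n_pcs = 50,
                       knn_k = 15,
                       resolutions = seq(0.1, 2, by = 0.1),
                       resolution = NULL,
                       cluster_method = "leiden",
                       k_within = 7,
                       de = de_filter(),
                       de_extremes = de_filter(min_log2_mean = -3),
                       score = score_params(),
                       signature = NULL,
                       exhaustion_threshold = 0.6,
                       n_extremes = 153,
                       n_top_upregulated = 200,
                       gsea_n_perm = 1000,
                       include_leukapheresis = TRUE,
                       regress_covariates = TRUE,
                       outdir = NULL,
                       seed = 1L) {
  structure(as.list(environment()), class = "RunConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [run_config()] arguments; the `sim` key holds
#' [sim_config()] arguments. Unknown keys raise an error.
#'
#' @param path YAML file.
#' @return `RunConfig`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop_config("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  for (k in c("qc_product", "qc_leukapheresis")) {
    if (!is.null(y[[k]])) y[[k]] <- do.call(qc_thresholds, y[[k]])
  }
  if (!is.null(y$hvg)) y$hvg <- do.call(hvg_params, y$hvg)
  if (!is.null(y$de)) y$de <- do.call(de_filter, y$de)
  if (!is.null(y$de_extremes)) y$de_extremes <- do.call(de_filter, y$de_extremes)
  if (!is.null(y$score)) y$score <- do.call(score_params, y$score)
  do.call(run_config, y)
}

# The cluster in which stimulated CAR-expressing cells concentrate; the
# product analog of the "activated" cluster.
find_activated_cluster <- function(labels, meta, car) {
  stim_car <- meta$condition == "stimulated" & car
  share <- tapply(stim_car, labels, mean)
  names(share)[which.max(share)]
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate -> QC -> CAR calling -> normalization -> HVG selection ->
#' (optional covariate regression) -> PCA -> kNN graph -> modularity scan ->
#' Leiden clustering -> leukapheresis label transfer -> activation DE ->
#' exhaustion scoring/classification -> extremes DE -> pre-ranked GSEA ->
#' composition report. Deterministic given `cfg$seed`; when `cfg$outdir` is
#' set every artifact is written together with an md5 manifest.
#'
#' @param cfg [run_config()].
#' @return list of class `PipelineResult` with (among others) `product`
#'   (post-QC CountMatrix), `qc_reports`, `car`, `hvgs`, `clusters`, `scan`,
#'   `transfer`, `de_activation`, `scores`, `exhaustion`, `extremes`,
#'   `de_extremes`, `gsea`, `report` (CompositionReport), `manifest`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "RunConfig"))
  sig <- cfg$signature %||% exhaustion_signature()

  # --- simulate ----------------------------------------------------------
  sim <- simulate_product(cfg$sim)
  leuk <- if (cfg$include_leukapheresis) simulate_leukapheresis(cfg$sim) else NULL

  # --- QC ---------------------------------------------------------------
  qc_p <- apply_qc(sim$matrix, cfg$qc_product)
  product <- qc_p$matrix
  qc_reports <- list(product = qc_p$report)
  if (!is.null(leuk)) {
    qc_l <- apply_qc(leuk$matrix, cfg$qc_leukapheresis)
    leuk_m <- qc_l$matrix
    qc_reports$leukapheresis <- qc_l$report
  }

  # --- CAR calling ------------------------------------------------------
  car <- detect_car_cells(product)

  # --- normalize / HVG / covariates ------------------------------------
  expr <- normalize_log(product)
  product <- subset_count_matrix(product, cells = expr$barcodes)
  car <- car[expr$barcodes]
  hvgs <- select_hvgs(expr, cfg$hvg)
  cc_sets <- cellcycle_gene_sets()
  cc <- cellcycle_score(expr, cc_sets$s, cc_sets$g2m,
                        score_params(cfg$score$n_bins, cfg$score$ctrl_per_gene,
                                     seed = cfg$seed + 11L))
  expr_pca <- ExprMatrix(expr$values[match(hvgs, expr$gene_ids), , drop = FALSE],
                         gene_ids = hvgs,
                         gene_names = expr$gene_names[match(hvgs, expr$gene_ids)],
                         barcodes = expr$barcodes, cell_meta = expr$cell_meta,
                         transform_log = c(expr$transform_log, "subset_hvgs"))
  if (cfg$regress_covariates) {
    cov <- qc_covariates(product, cells = expr$barcodes,
                         cc_scores = cc[, c("S_score", "G2M_score")])
    expr_pca <- regress_out(expr_pca, cov)
  }

  # --- cluster ----------------------------------------------------------
  n_pcs <- min(cfg$n_pcs, min(dim(expr_pca$values)) - 1)
  emb <- pca_embed(expr_pca, n_components = n_pcs)
  g <- knn_graph(emb, k = cfg$knn_k)
  scan <- resolution_scan(g, cfg$resolutions, seed = cfg$seed + 21L,
                          method = cfg$cluster_method)
  res_used <- cfg$resolution %||% attr(scan, "suggested_resolution")
  clusters <- cluster_communities(g, resolution = res_used,
                                  seed = cfg$seed + 21L,
                                  method = cfg$cluster_method)

  # --- integrate leukapheresis -----------------------------------------
  transfer <- NULL
  if (!is.null(leuk)) {
    leuk_expr <- normalize_log(leuk_m)
    shared <- intersect(hvgs, leuk_expr$gene_ids)
    joint_vals <- cbind(expr$values[match(shared, expr$gene_ids), , drop = FALSE],
                        leuk_expr$values[match(shared, leuk_expr$gene_ids), , drop = FALSE])
    joint_meta <- data.frame(
      batch = rep(c("product", "leukapheresis"),
                  c(length(expr$barcodes), length(leuk_expr$barcodes))),
      row.names = c(expr$barcodes, leuk_expr$barcodes))
    joint <- ExprMatrix(joint_vals, gene_ids = shared,
                        gene_names = expr$gene_names[match(shared, expr$gene_ids)],
                        barcodes = c(expr$barcodes, leuk_expr$barcodes),
                        cell_meta = joint_meta,
                        transform_log = c(expr$transform_log, "joint_hvg_subset"))
    joint_emb <- pca_embed(joint, n_components = min(n_pcs, min(dim(joint$values)) - 1))
    is_ref <- joint_meta$batch == "product"
    split_emb <- function(keep) {
      structure(list(coords = joint_emb$coords[keep, , drop = FALSE],
                     method = "PCA", n_components = joint_emb$n_components,
                     barcodes = joint_emb$barcodes[keep],
                     cell_meta = joint_emb$cell_meta[keep, , drop = FALSE]),
                class = "Embedding")
    }
    nbrs <- batch_balanced_neighbors(split_emb(is_ref), split_emb(!is_ref),
                                     k_within = cfg$k_within)
    transfer <- transfer_labels(nbrs, clusters)
  }

  # --- activation DE ----------------------------------------------------
  meta <- product$cell_meta
  act_cluster <- find_activated_cluster(clusters$labels[product$barcodes],
                                        meta, car)
  in_act <- as.character(clusters$labels[product$barcodes]) == act_cluster
  stim_car <- meta$condition == "stimulated" & car
  grp_a <- product$barcodes[stim_car & in_act]
  grp_b <- product$barcodes[stim_car & !in_act]
  de_activation <- NULL
  if (length(grp_a) >= 2 && length(grp_b) >= 2) {
    de_activation <- welch_ttest_by_gene(expr, grp_a, grp_b)
  }

  # --- exhaustion scoring ----------------------------------------------
  sig_hvg <- intersect_signature(sig, hvgs, expr)
  scores <- score_signature(expr, sig_hvg,
                            score_params(cfg$score$n_bins, cfg$score$ctrl_per_gene,
                                         seed = cfg$seed + 31L))
  exhaustion <- classify_exhausted(scores, cfg$exhaustion_threshold,
                                   cell_meta = meta)
  extremes <- de_extremes <- gsea <- NULL
  responders <- product$barcodes[stim_car & in_act]
  if (length(responders) >= 4) {
    extremes <- select_extremes(scores, responders, n = cfg$n_extremes)
    if (length(extremes$top) >= 2) {
      de_extremes <- welch_ttest_by_gene(expr, extremes$top, extremes$bottom)
      ranked <- rank_genes_for_gsea(de_extremes)
      gsea <- gsea_preranked(ranked, sig, n_perm = cfg$gsea_n_perm,
                             seed = cfg$seed + 41L,
                             min_size = min(15, length(sig_hvg$genes)))
    }
  }

  # --- report -----------------------------------------------------------
  cells <- data.frame(
    barcode = product$barcodes,
    donor = meta$donor,
    condition = meta$condition,
    car_positive = unname(car),
    cluster = as.character(clusters$labels[product$barcodes]),
    exhausted = unname(exhaustion$exhausted[product$barcodes]),
    stringsAsFactors = FALSE)
  report <- compose_report(cells, activated_cluster = act_cluster)

  result <- structure(list(
    config = cfg, product = product, qc_reports = qc_reports, car = car,
    truth = sim$truth[product$barcodes, ],
    leuk_truth = if (!is.null(leuk)) leuk$truth else NULL,
    hvgs = hvgs, cellcycle = cc, embedding = emb, scan = scan,
    resolution_used = res_used, clusters = clusters,
    activated_cluster = act_cluster, transfer = transfer,
    de_activation = de_activation, signature = sig_hvg, scores = scores,
    exhaustion = exhaustion, extremes = extremes, de_extremes = de_extremes,
    gsea = gsea, report = report), class = "PipelineResult")

  if (!is.null(cfg$outdir)) {
    result$manifest <- write_artifacts(result, cfg$outdir)
  }
  result
}

#' @exportS3Method base::print
print.PipelineResult <- function(x, ...) {
  cat("PipelineResult:", ncol(x$product$counts), "product cells,",
      nlevels(x$clusters$labels), "clusters (resolution",
      x$resolution_used, ")\n")
  print(x$report)
  invisible(x)
}

#' Compose the cell-composition report
#'
#' Contingency counts per donor x condition x CAR status x cluster plus the
#' derived headline percentages, each recomputed from the counts with
#' conventional half-up rounding (integer precision for the exhausted share,
#' one decimal elsewhere).
#'
#' @param cells data.frame with columns barcode, donor, condition,
#'   car_positive, cluster, exhausted (one row per cell, no NAs).
#' @param activated_cluster label of the activated cluster (for the
#'   pre-activation and responder percentages).
#' @return object of class `CompositionReport`: `counts` (full contingency
#'   table), `totals`, and `percentages`.
#' @export
compose_report <- function(cells, activated_cluster) {
  required <- c("barcode", "donor", "condition", "car_positive", "cluster",
                "exhausted")
  missing_col <- setdiff(required, colnames(cells))
  if (length(missing_col)) {
    stop_config("cells table lacks column(s): ", paste(missing_col, collapse = ", "))
  }
  for (cl in required) {
    if (anyNA(cells[[cl]])) {
      bad <- cells$barcode[which(is.na(cells[[cl]]))[1]]
      stop_config("missing ", cl, " for cell ", bad)
    }
  }
  counts <- as.data.frame(table(donor = cells$donor,
                                condition = cells$condition,
                                car = ifelse(cells$car_positive, "CAR+", "CAR-"),
                                cluster = cells$cluster),
                          responseName = "n")
  n_total <- nrow(cells)
  n_car <- sum(cells$car_positive)
  stim <- cells$condition == "stimulated"
  unstim <- cells$condition == "unstimulated"
  in_act <- cells$cluster == activated_cluster

  pct <- function(num, den, digits = 1) {
    if (den == 0) return(0)
    round_half_up(100 * num / den, digits)
  }
  responders <- cells$car_positive & stim & in_act
  percentages <- list(
    car_positive_overall = pct(n_car, n_total),
    car_positive_stimulated = pct(sum(cells$car_positive & stim), sum(stim)),
    car_positive_unstimulated = pct(sum(cells$car_positive & unstim), sum(unstim)),
    unstim_car_in_activated_cluster = pct(sum(cells$car_positive & unstim & in_act),
                                          sum(cells$car_positive & unstim)),
    stim_car_in_activated_cluster = pct(sum(responders),
                                        sum(cells$car_positive & stim)),
    exhausted_among_responders = pct(sum(cells$exhausted & responders),
                                     sum(responders), digits = 0))
  cluster_shares <- 100 * prop.table(table(cells$cluster, cells$condition),
                                     margin = 2)
  structure(list(counts = counts,
                 totals = c(cells = n_total, car_positive = n_car,
                            stimulated = sum(stim), unstimulated = sum(unstim),
                            responders = sum(responders),
                            exhausted_responders = sum(cells$exhausted & responders)),
                 activated_cluster = activated_cluster,
                 cluster_condition_shares = cluster_shares,
                 percentages = percentages),
            class = "CompositionReport")
}

#' @exportS3Method base::print
print.CompositionReport <- function(x, ...) {
  cat("CompositionReport:", x$totals["cells"], "cells;",
      x$totals["car_positive"], "CAR+ (",
      x$percentages$car_positive_overall, "%)\n", sep = " ")
  cat("  activated cluster:", x$activated_cluster,
      "| responders:", x$totals["responders"],
      "| exhausted among responders:", x$totals["exhausted_responders"],
      "(", x$percentages$exhausted_among_responders, "%)\n")
  invisible(x)
}

# Write pipeline artifacts and an md5 manifest.
write_artifacts <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_10x_mtx(result$product, file.path(outdir, "product"))
  lab <- data.frame(barcode = names(result$clusters$labels),
                    cluster = as.character(result$clusters$labels))
  write.table(lab, file.path(outdir, "clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(result$scan, file.path(outdir, "resolution_scan.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sc <- data.frame(barcode = names(result$scores), score = result$scores,
                   exhausted = result$exhaustion$exhausted)
  write.table(sc, file.path(outdir, "exhaustion_scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(result$de_activation)) {
    write_de_table(result$de_activation, file.path(outdir, "de_activation.tsv"))
  }
  if (!is.null(result$de_extremes)) {
    write_de_table(result$de_extremes, file.path(outdir, "de_extremes.tsv"))
  }
  if (!is.null(result$transfer)) {
    tr <- data.frame(barcode = names(result$transfer),
                     cluster = as.character(result$transfer))
    write.table(tr, file.path(outdir, "label_transfer.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  report <- result$report
  jsonlite::write_json(
    list(totals = as.list(report$totals),
         activated_cluster = report$activated_cluster,
         percentages = report$percentages),
    file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA)
  rel <- setdiff(list.files(outdir, recursive = TRUE), "manifest.json")
  hashes <- tools::md5sum(file.path(outdir, rel))
  manifest <- list(seed = result$config$seed,
                   resolution_used = result$resolution_used,
                   files = setNames(as.list(unname(hashes)), rel))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
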