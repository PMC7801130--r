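# PCA, kNN graph, community clustering, modularity scan, UMAP, batch-balanced
# neighbours and label transfer.

make_embedding <- function(coords, prefix = "c") {
  rownames(coords) <- sprintf("%s%04d", prefix, seq_len(nrow(coords)))
  structure(list(coords = coords, method = "PCA", n_components = ncol(coords),
                 barcodes = rownames(coords),
                 cell_meta = data.frame(row.names = rownames(coords))),
            class = "Embedding")
}

test_that("PCA captures exact low-rank structure and fixes signs", {
  set.seed(1)
  basis <- qr.Q(qr(matrix(rnorm(100), 10, 10)))[, 1:2]
  scores <- matrix(rnorm(400, sd = c(3, 1)), 200, 2, byrow = TRUE)
  X <- scores %*% t(basis)                      # exactly planar in 10-D
  e <- ExprMatrix(t(X), gene_ids = sprintf("g%02d", 1:10),
                  barcodes = sprintf("c%03d", 1:200))
  emb <- pca_embed(e, n_components = 5)
  ev <- emb$explained_variance
  expect_gt(sum(ev[1:2]) / sum(ev), 0.9999)

  # orthogonal rotation leaves the explained-variance spectrum unchanged
  R <- qr.Q(qr(matrix(rnorm(100), 10, 10)))
  e_rot <- ExprMatrix(t(X %*% R), gene_ids = e$gene_ids, barcodes = e$barcodes)
  emb_rot <- pca_embed(e_rot, n_components = 5)
  expect_equal(emb_rot$explained_variance, emb$explained_variance,
               tolerance = 1e-6)

  # sign convention: the largest-|loading| gene is positive on each component
  for (j in 1:5) {
    v <- emb$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }

  expect_error(pca_embed(e, n_components = 50), class = "cartatlas_config_error")
  e_const <- ExprMatrix(matrix(2, 5, 8), gene_ids = sprintf("g%d", 1:5),
                        barcodes = sprintf("c%d", 1:8))
  expect_error(pca_embed(e_const, 2), class = "cartatlas_config_error")
})

test_that("kNN graph respects blob topology and edge cases", {
  set.seed(2)
  blob1 <- matrix(rnorm(60, 0, 0.1), 30, 2)
  blob2 <- matrix(rnorm(60, 50, 0.1), 30, 2)
  emb <- make_embedding(rbind(blob1, blob2))
  g <- knn_graph(emb, k = 5)
  comp <- igraph::components(g)
  expect_equal(comp$no, 2)
  expect_equal(sort(unname(comp$csize)), c(30, 30))

  # k = n - 1 yields the complete graph
  small <- make_embedding(matrix(rnorm(12), 6, 2))
  gc <- knn_graph(small, k = 5)
  expect_equal(igraph::ecount(gc), choose(6, 2))

  expect_error(knn_graph(small, k = 0), class = "cartatlas_config_error")
  expect_error(knn_graph(small, k = 6), class = "cartatlas_config_error")

  # three equidistant points, k = 1: every point keeps at least one edge
  tri <- make_embedding(rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)))
  gt <- knn_graph(tri, k = 1)
  expect_true(all(igraph::degree(gt) >= 1))
})

test_that("community clustering separates disconnected cliques deterministically", {
  g <- igraph::disjoint_union(igraph::make_full_graph(10),
                              igraph::make_full_graph(12))
  igraph::V(g)$name <- sprintf("v%02d", 1:22)
  igraph::E(g)$weight <- 1
  for (r in c(0.1, 0.5, 1, 1.5)) {
    for (method in c("leiden", "louvain")) {
      cl <- cluster_communities(g, resolution = r, seed = 3, method = method)
      expect_equal(nlevels(cl$labels), 2)
      expect_equal(length(unique(cl$labels[1:10])), 1)
      expect_gte(cl$modularity, -0.5)
      expect_lte(cl$modularity, 1)
    }
  }
  # at very high resolution cliques may split further, but communities never
  # straddle the disconnected components
  cl2 <- cluster_communities(g, resolution = 2, seed = 3)
  expect_equal(length(intersect(unique(cl2$labels[1:10]),
                                unique(cl2$labels[11:22]))), 0)
  a <- cluster_communities(g, 1, seed = 5)
  b <- cluster_communities(g, 1, seed = 5)
  expect_identical(a$labels, b$labels)
  expect_error(cluster_communities(igraph::make_empty_graph(0), 1, seed = 1),
               class = "cartatlas_config_error")
})

test_that("the resolution scan tabulates and suggests reproducibly", {
  g <- igraph::disjoint_union(igraph::make_full_graph(10),
                              igraph::make_full_graph(10))
  igraph::V(g)$name <- sprintf("v%02d", 1:20)
  igraph::E(g)$weight <- 1
  scan <- resolution_scan(g, resolutions = seq(0.1, 2, 0.1), seed = 4)
  expect_equal(nrow(scan), 20)
  expect_true(all(scan$n_clusters == 2))
  s1 <- attr(scan, "suggested_resolution")
  s2 <- attr(resolution_scan(g, seq(0.1, 2, 0.1), seed = 4),
             "suggested_resolution")
  expect_identical(s1, s2)
  expect_error(resolution_scan(g, numeric(0)), class = "cartatlas_config_error")
})

test_that("clustering recovers well-separated planted programs (ARI >= 0.9)", {
  cfg <- sim_config(cells_per_condition_per_donor = 250, n_genes = 1200,
                    seed = 6)
  sim <- simulate_product(cfg)
  e <- normalize_log(sim$matrix)
  hv <- select_hvgs(e)
  ep <- ExprMatrix(e$values[match(hv, e$gene_ids), , drop = FALSE],
                   gene_ids = hv, barcodes = e$barcodes, cell_meta = e$cell_meta)
  sets <- cellcycle_gene_sets()
  cc <- suppressWarnings(cellcycle_score(e, sets$s, sets$g2m, score_params(seed = 7)))
  cov <- qc_covariates(subset_count_matrix(sim$matrix, cells = e$barcodes),
                       cells = e$barcodes, cc_scores = cc[, 1:2])
  emb <- pca_embed(regress_out(ep, cov), n_components = 30)
  g <- knn_graph(emb, k = 15)
  cl <- cluster_communities(g, resolution = 0.8, seed = 8)
  tr <- sim$truth[e$barcodes, ]
  expect_gte(ari(as.character(cl$labels), tr$true_cluster), 0.9)
})

test_that("UMAP embeds deterministically and separates blobs", {
  set.seed(9)
  pts <- rbind(matrix(rnorm(100, 0, 0.3), 50, 2),
               matrix(rnorm(100, 30, 0.3), 50, 2))
  emb <- make_embedding(cbind(pts, matrix(rnorm(300, 0, 0.1), 100, 3)))
  u1 <- umap_embed(emb, seed = 10)
  u2 <- umap_embed(emb, seed = 10)
  expect_equal(dim(u1$coords), c(100L, 2L))
  expect_identical(u1$coords, u2$coords)
  c1 <- colMeans(u1$coords[1:50, ]); c2 <- colMeans(u1$coords[51:100, ])
  within <- mean(c(sqrt(rowSums(sweep(u1$coords[1:50, ], 2, c1)^2)),
                   sqrt(rowSums(sweep(u1$coords[51:100, ], 2, c2)^2))))
  expect_gt(sqrt(sum((c1 - c2)^2)), 3 * within)
})

test_that("batch-balanced neighbours match the exhaustive all-pairs oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    n_ref <- sample(100:200, 1)
    n_query <- sample(50:150, 1)
    ref <- make_embedding(matrix(rnorm(n_ref * 5), n_ref, 5), "r")
    query <- make_embedding(matrix(rnorm(n_query * 5), n_query, 5), "q")
    nb <- batch_balanced_neighbors(ref, query, k_within = 7)
    expect_equal(dim(nb$idx), c(n_query, 7L))
    d_all <- as.matrix(stats::dist(rbind(query$coords, ref$coords)))
    d_qr <- d_all[seq_len(n_query), n_query + seq_len(n_ref), drop = FALSE]
    for (i in seq_len(n_query)) {
      oracle <- order(d_qr[i, ])[1:7]
      expect_setequal(nb$idx[i, ], oracle)
      expect_equal(nb$dist[i, ], unname(sort(d_qr[i, ])[1:7]), tolerance = 1e-10)
    }
  }
  ref <- make_embedding(matrix(rnorm(20), 4, 5), "r")
  query <- make_embedding(ref$coords[2, , drop = FALSE], "q")
  nb <- batch_balanced_neighbors(ref, query, k_within = 2)
  expect_equal(nb$idx[1, 1], 2L)
  expect_equal(nb$dist[1, 1], 0)
  expect_error(batch_balanced_neighbors(ref, query, k_within = 10),
               class = "cartatlas_config_error")
})

test_that("label transfer takes the 7-neighbour mode with the nearest tie rule", {
  ref_barcodes <- sprintf("r%d", 1:7)
  labels <- factor(setNames(c("A", "A", "A", "B", "B", "C", "C"), ref_barcodes))
  nb <- manual_neighbor_set(matrix(1:7, 1), matrix(seq(0.1, 0.7, 0.1), 1),
                            ref_barcodes, "q1")
  expect_equal(as.character(transfer_labels(nb, labels)), "A")

  # 3-3 tie between A and B; the nearest neighbour carrying a tied label is B
  labels2 <- factor(setNames(c("B", "A", "A", "A", "B", "B", "C"), ref_barcodes))
  expect_equal(as.character(transfer_labels(nb, labels2)), "B")

  labels3 <- factor(setNames(rep("Z", 7), ref_barcodes))
  expect_equal(as.character(transfer_labels(nb, labels3)), "Z")

  nb_empty <- manual_neighbor_set(matrix(integer(), 1, 0), matrix(numeric(), 1, 0),
                                  ref_barcodes, "q1")
  expect_error(transfer_labels(nb_empty, labels), class = "cartatlas_config_error")
})

test_that("label transfer recovers planted programs across datasets", {
  cfg <- sim_config(cells_per_condition_per_donor = 200, n_genes = 1000,
                    seed = 12)
  sim <- simulate_product(cfg, conditions = "unstimulated")
  leuk <- simulate_leukapheresis(sim_config(cells_per_condition_per_donor = 150,
                                            n_genes = 1000, seed = 12))
  e <- normalize_log(sim$matrix)
  el <- normalize_log(leuk$matrix)
  hv <- select_hvgs(e)
  shared <- intersect(hv, el$gene_ids)
  joint <- ExprMatrix(cbind(e$values[match(shared, e$gene_ids), ],
                            el$values[match(shared, el$gene_ids), ]),
                      gene_ids = shared,
                      barcodes = c(e$barcodes, el$barcodes))
  jemb <- pca_embed(joint, n_components = 30)
  is_ref <- seq_along(e$barcodes)
  sub_emb <- function(k) make_embedding(jemb$coords[k, , drop = FALSE])
  ref_emb <- sub_emb(is_ref); ref_emb$barcodes <- e$barcodes
  q_emb <- sub_emb(-is_ref); q_emb$barcodes <- el$barcodes
  nb <- batch_balanced_neighbors(ref_emb, q_emb, k_within = 7)
  ref_truth <- factor(setNames(sim$truth[e$barcodes, "true_cluster"], e$barcodes))
  pred <- transfer_labels(nb, ref_truth)
  lt <- leuk$truth[el$barcodes, ]
  shared_programs <- lt$true_cluster %in% levels(ref_truth)
  acc <- mean(as.character(pred)[shared_programs] ==
                lt$true_cluster[shared_programs])
  expect_gte(acc, 0.9)
})
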