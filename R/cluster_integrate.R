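# Dimensionality reduction, kNN graph construction, community clustering with
# a modularity-resolution scan, 2-D embedding (visualization only), and
# batch-balanced kNN label transfer from product clusters to leukapheresis
# cells.

#' Principal component analysis of an expression matrix
#'
#' Centered (unscaled) PCA of cells over genes. Component signs are fixed by
#' convention: the gene with the largest absolute loading on each component is
#' made positive, so scores are reproducible across platforms.
#'
#' @param e [ExprMatrix()].
#' @param n_components number of components (default 50); must be at most
#'   `min(genes, cells) - 1`.
#' @return object of class `Embedding`: list with `coords` (cells x
#'   components), `method = "PCA"`, `n_components`, `explained_variance`,
#'   `loadings`, `barcodes`, `cell_meta`.
#' @export
pca_embed <- function(e, n_components = 50) {
  stopifnot(inherits(e, "ExprMatrix"))
  maxc <- min(dim(e$values)) - 1
  if (n_components > maxc) {
    stop_config("n_components (", n_components, ") exceeds min(genes, cells) - 1 = ", maxc)
  }
  X <- t(as.matrix(e$values))           # cells x genes
  if (all(apply(X, 2, var) < .Machine$double.eps)) {
    stop_config("expression matrix is constant; PCA undefined")
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = n_components)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    v <- pc$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  coords <- sweep(pc$x, 2, flip, `*`)
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  structure(list(coords = coords,
                 method = "PCA",
                 n_components = n_components,
                 explained_variance = pc$sdev[seq_len(n_components)]^2,
                 loadings = loadings,
                 barcodes = e$barcodes,
                 cell_meta = e$cell_meta),
            class = "Embedding")
}

#' @exportS3Method base::print
print.Embedding <- function(x, ...) {
  cat("Embedding (", x$method, "): ", nrow(x$coords), " cells x ",
      ncol(x$coords), " components\n", sep = "")
  invisible(x)
}

#' Build a k-nearest-neighbour graph
#'
#' Undirected graph over cells: an edge joins two cells when either lists the
#' other among its `k` Euclidean nearest neighbours. Edge weights use the
#' shared-neighbour kernel `|kNN(i) intersect kNN(j)| / k` (minimum weight
#' `1/k` so mutual-nearest edges with no other shared neighbours survive).
#'
#' @param emb [pca_embed()] result (or any Embedding).
#' @param k neighbours per cell (default 15); must satisfy 0 < k < n_cells.
#' @return igraph graph with vertex names = barcodes.
#' @export
knn_graph <- function(emb, k = 15) {
  stopifnot(inherits(emb, "Embedding"))
  n <- nrow(emb$coords)
  if (k <= 0) stop_config("k must be positive")
  if (k >= n) stop_config("k must be smaller than the number of cells")
  nn <- RANN::nn2(emb$coords, k = k + 1)$nn.idx
  # drop self-matches (first column unless duplicates push self elsewhere)
  nbrs <- t(vapply(seq_len(n), function(i) {
    row <- nn[i, ]
    row <- row[row != i]
    row[seq_len(k)]
  }, integer(k)))
  if (k == 1) nbrs <- matrix(nbrs, ncol = 1)
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nbrs)))
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  nbr_sets <- lapply(seq_len(n), function(i) nbrs[i, ])
  w <- vapply(seq_len(nrow(edges)), function(r) {
    i <- edges[r, 1]; j <- edges[r, 2]
    max(length(intersect(nbr_sets[[i]], nbr_sets[[j]])), 1) / k
  }, numeric(1))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- w
  if (igraph::vcount(g) < n) {
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  }
  igraph::V(g)$name <- emb$barcodes
  g
}

#' Community clustering at a fixed resolution
#'
#' Modularity-maximizing community detection on the kNN graph, Leiden
#' (default, used for product cells) or Louvain (used for leukapheresis
#' cells). Deterministic given `seed`.
#'
#' @param g igraph graph from [knn_graph()].
#' @param resolution resolution parameter.
#' @param seed integer seed.
#' @param method `"leiden"` or `"louvain"`.
#' @return object of class `ClusterLabeling`: `labels` (factor named by
#'   vertex), `resolution`, `modularity`, `method`.
#' @export
cluster_communities <- function(g, resolution = 1, seed = 0L,
                                method = c("leiden", "louvain")) {
  method <- match.arg(method)
  if (igraph::vcount(g) == 0) stop_config("empty graph")
  comm <- with_seed(seed, {
    if (method == "leiden") {
      igraph::cluster_leiden(g, objective_function = "modularity",
                             resolution = resolution, n_iterations = 5)
    } else {
      igraph::cluster_louvain(g, resolution = resolution)
    }
  })
  mem <- igraph::membership(comm)
  labels <- factor(as.integer(mem))
  names(labels) <- igraph::V(g)$name
  structure(list(labels = labels,
                 resolution = resolution,
                 modularity = igraph::modularity(g, mem,
                                                 weights = igraph::E(g)$weight),
                 method = method),
            class = "ClusterLabeling")
}

#' @exportS3Method base::print
print.ClusterLabeling <- function(x, ...) {
  cat("ClusterLabeling (", x$method, "): ", nlevels(x$labels),
      " clusters at resolution ", x$resolution,
      "; modularity ", round(x$modularity, 4), "\n", sep = "")
  invisible(x)
}

#' Modularity scan over clustering resolutions
#'
#' Clusters the graph at each resolution and tabulates cluster count and
#' modularity. The suggested resolution is the largest one whose modularity is
#' within `tol` of the maximum — an automatable proxy for the trade-off
#' between modularity and granularity; the final choice remains a user
#' decision.
#'
#' @param g igraph graph.
#' @param resolutions numeric vector (default 0.1 to 2 in steps of 0.1).
#' @param seed integer seed (shared across resolutions).
#' @param method `"leiden"` or `"louvain"`.
#' @param tol relative modularity tolerance for the suggestion (default 0.01).
#' @return data.frame (resolution, n_clusters, modularity) with attribute
#'   `suggested_resolution`.
#' @export
resolution_scan <- function(g, resolutions = seq(0.1, 2, by = 0.1), seed = 0L,
                            method = c("leiden", "louvain"), tol = 0.01) {
  if (length(resolutions) == 0) stop_config("no resolutions given")
  method <- match.arg(method)
  rows <- lapply(resolutions, function(r) {
    cl <- cluster_communities(g, resolution = r, seed = seed, method = method)
    data.frame(resolution = r, n_clusters = nlevels(cl$labels),
               modularity = cl$modularity)
  })
  tab <- do.call(rbind, rows)
  best <- max(tab$modularity)
  ok <- tab$modularity >= best - tol * abs(best) - 1e-12
  attr(tab, "suggested_resolution") <- max(tab$resolution[ok])
  tab
}

#' 2-D UMAP embedding for visualization
#'
#' Projects a PCA embedding to two dimensions. The output is for plotting
#' only; no downstream computation consumes the coordinates.
#'
#' @param emb [pca_embed()] result.
#' @param seed integer seed (single-threaded exact reproduction).
#' @param n_neighbors,min_dist usual UMAP parameters.
#' @return `Embedding` with 2-D `coords`, method `"UMAP"`.
#' @export
umap_embed <- function(emb, seed = 0L, n_neighbors = 15, min_dist = 0.3) {
  stopifnot(inherits(emb, "Embedding"))
  coords <- with_seed(seed, {
    uwot::umap(emb$coords, n_neighbors = min(n_neighbors, nrow(emb$coords) - 1),
               min_dist = min_dist, n_threads = 1, n_sgd_threads = 1)
  })
  rownames(coords) <- emb$barcodes
  structure(list(coords = coords, method = "UMAP", n_components = 2,
                 barcodes = emb$barcodes, cell_meta = emb$cell_meta),
            class = "Embedding")
}

#' Batch-balanced nearest neighbours
#'
#' For every query cell, its `k_within` nearest reference cells by Euclidean
#' distance in a shared component space (reference and query must come from a
#' joint PCA).
#'
#' @param ref reference [pca_embed()] Embedding.
#' @param query query Embedding in the same component space.
#' @param k_within neighbours per reference batch (default 7).
#' @return object of class `NeighborSet`: list with integer matrix `idx`
#'   (query x k, indices into reference cells), matrix `dist`, `ref_barcodes`,
#'   `query_barcodes`.
#' @export
batch_balanced_neighbors <- function(ref, query, k_within = 7) {
  stopifnot(inherits(ref, "Embedding"), inherits(query, "Embedding"))
  if (ncol(ref$coords) != ncol(query$coords)) {
    stop_config("reference and query embeddings have different dimensions")
  }
  if (k_within > nrow(ref$coords)) {
    stop_config("k_within (", k_within, ") exceeds reference size (",
                nrow(ref$coords), ")")
  }
  nn <- RANN::nn2(ref$coords, query$coords, k = k_within)
  structure(list(idx = nn$nn.idx, dist = nn$nn.dists,
                 ref_barcodes = ref$barcodes,
                 query_barcodes = query$barcodes),
            class = "NeighborSet")
}

#' Transfer cluster labels across datasets
#'
#' Each query cell receives the most frequent label among its reference
#' neighbours; when modes tie, the label of the single nearest neighbour that
#' carries one of the tied labels wins (deterministic, distance-respecting).
#'
#' @param n [batch_balanced_neighbors()] result.
#' @param ref_labels [cluster_communities()] labelling of the reference cells
#'   (or any vector named by reference barcode).
#' @return factor of transferred labels named by query barcode.
#' @export
transfer_labels <- function(n, ref_labels) {
  stopifnot(inherits(n, "NeighborSet"))
  labels <- if (inherits(ref_labels, "ClusterLabeling")) ref_labels$labels else ref_labels
  labels <- labels[n$ref_barcodes]
  if (anyNA(labels)) stop_config("reference label missing for some neighbours")
  if (ncol(n$idx) == 0) stop_config("empty neighbour lists")
  out <- vapply(seq_len(nrow(n$idx)), function(i) {
    labs <- as.character(labels[n$idx[i, ]])
    tab <- table(labs)
    modes <- names(tab)[tab == max(tab)]
    if (length(modes) == 1) return(modes)
    # neighbours arrive sorted by ascending distance
    labs[labs %in% modes][1]
  }, character(1))
  factor(setNames(out, n$query_barcodes))
}
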