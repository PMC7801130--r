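# QC, CAR calling, normalization, HVG selection, regression, cell cycle.

# Build a matrix where each cell's detected genes, mitochondrial share and
# total UMIs are controlled exactly. Two mitochondrial genes ("MT-1","MT-2").
make_qc_matrix <- function(spec) {
  n_genes <- 1600
  gene_names <- c("MT-1", "MT-2", sprintf("GENE%04d", seq_len(n_genes - 2)))
  cols <- lapply(spec, function(s) {
    v <- numeric(n_genes)
    mito <- round(s$total * s$mito_frac)
    v[1] <- mito
    rest <- s$total - mito
    k <- s$genes_detected - 1          # MT-1 counts as one detected gene
    base <- rest %/% k
    v[2 + seq_len(k)] <- base
    v[3] <- v[3] + rest - base * k     # remainder on one gene
    v
  })
  m <- do.call(cbind, cols)
  CountMatrix(m, gene_ids = sprintf("id%04d", seq_len(n_genes)),
              gene_names = gene_names,
              barcodes = names(spec))
}

test_that("hand-evaluated QC predicates keep exactly the passing cell", {
  m <- make_qc_matrix(list(
    A = list(genes_detected = 1200, mito_frac = 0.05, total = 40000),
    B = list(genes_detected = 900, mito_frac = 0.05, total = 40000),
    C = list(genes_detected = 1500, mito_frac = 0.09, total = 40000),
    D = list(genes_detected = 1100, mito_frac = 0.02, total = 20000)))
  res <- apply_qc(m, qc_presets("product"))
  expect_equal(res$matrix$barcodes, "A")
  expect_equal(res$report$cells_out, 1L)
  expect_equal(unname(res$report$cells_removed_by_criterion["min_genes_per_cell"]), 1L)
  expect_equal(unname(res$report$cells_removed_by_criterion["max_mito_fraction"]), 1L)
  expect_equal(unname(res$report$cells_removed_by_criterion["min_total_umis"]), 1L)
})

test_that("QC boundary semantics follow the stated inequalities", {
  m <- make_qc_matrix(list(
    exact_genes = list(genes_detected = 1000, mito_frac = 0.05, total = 40000),
    exact_mito = list(genes_detected = 1200, mito_frac = 0.08, total = 40000),
    exact_umis = list(genes_detected = 1200, mito_frac = 0.05, total = 30000)))
  res <- apply_qc(m, qc_presets("product"))
  # "at least 1,000 genes" keeps the boundary cell; "less than 8%" and
  # "more than 30,000" exclude theirs
  expect_equal(res$matrix$barcodes, "exact_genes")
})

test_that("vacuous cell thresholds reduce QC to the gene filter", {
  m <- toy_count_matrix(n_genes = 30, n_cells = 8, seed = 3)
  m$gene_names[1] <- "MT-1"
  res <- apply_qc(m, qc_thresholds(0, 1, 0, 2))
  expect_equal(res$matrix$barcodes, m$barcodes)
  expect_true(all(Matrix::rowSums(res$matrix$counts) >= 2))
  dropped <- setdiff(m$gene_ids, res$matrix$gene_ids)
  expect_true(all(Matrix::rowSums(m$counts)[dropped] < 2))
})

test_that("QC is idempotent and its report arithmetic is consistent", {
  for (seed in 1:5) {
    cfg <- sim_config(cells_per_condition_per_donor = 60, n_genes = 600,
                      seed = seed)
    sim <- simulate_product(cfg, conditions = "stimulated")
    t <- qc_thresholds(400, 0.08, 10000, 2)
    r1 <- apply_qc(sim$matrix, t)
    expect_equal(r1$report$cells_in - r1$report$cells_removed_union,
                 r1$report$cells_out)
    r2 <- apply_qc(r1$matrix, t)
    expect_equal(r2$report$cells_removed_union, 0L)
    expect_identical(as.matrix(r2$matrix$counts), as.matrix(r1$matrix$counts))
  }
})

test_that("CAR calling thresholds UMIs as specified", {
  counts <- rbind(matrix(5, 3, 3), c(0, 1, 3))
  m <- CountMatrix(counts, gene_ids = c("g1", "g2", "g3", car_feature_id()),
                   barcodes = c("c1", "c2", "c3"))
  expect_equal(as.vector(detect_car_cells(m)), c(FALSE, TRUE, TRUE))
  expect_equal(as.vector(detect_car_cells(m, min_car_umis = 2)),
               c(FALSE, FALSE, TRUE))
  expect_error(detect_car_cells(m, car_feature = "nope"), "nope",
               class = "cartatlas_config_error")
})

test_that("CAR calling is sensitive and calibrated on simulated products", {
  cfg <- sim_config(cells_per_condition_per_donor = 500, n_genes = 600,
                    seed = 21)
  sim <- simulate_product(cfg)
  flag <- detect_car_cells(sim$matrix)
  tr <- sim$truth
  sens <- mean(flag[tr$car_positive])
  expect_gte(sens, 0.95)   # default CAR UMI mean (5) is above the 3-UMI floor
  n <- length(flag)
  expect_lt(abs(mean(flag) - cfg$car_fraction),
            3 * sqrt(cfg$car_fraction * (1 - cfg$car_fraction) / n))
  summ <- attr(flag, "summary")
  expect_true("overall" %in% summ$sample_id)
})

test_that("normalization hits the target sum and the stated closed forms", {
  # cell with total 20,000 over genes of equal counts: one gene carrying 2
  # of every 20000/10000 = 2 units scales to 1 -> ln(2)
  counts <- cbind(c(2, rep(2, 9999)), c(rep(1, 10000)))
  m <- CountMatrix(counts, gene_ids = sprintf("g%05d", 1:10000),
                   barcodes = c("c20k", "c10k"))
  e <- normalize_log(m)
  expect_equal(e$values["g00001", "c20k"], log(2), tolerance = 1e-12)
  # cell already summing to 10,000 -> values are ln(1 + count)
  expect_equal(e$values["g00001", "c10k"], log1p(1), tolerance = 1e-12)

  # expm1 totals equal target_sum (CAR excluded), all-zero gene stays zero
  cfg <- sim_config(cells_per_condition_per_donor = 40, n_genes = 600, seed = 22)
  sim <- simulate_product(cfg)
  e2 <- normalize_log(sim$matrix)
  cellular <- !(e2$gene_ids %in% car_feature_id())
  totals <- Matrix::colSums(expm1(e2$values[cellular, ]))
  expect_true(all(abs(totals - 10000) / 10000 < 1e-6))
  zero_gene <- which(Matrix::rowSums(sim$matrix$counts) == 0)
  if (length(zero_gene)) {
    expect_true(all(e2$values[zero_gene, ] == 0))
  }
})

test_that("zero-total cells are dropped with a warning", {
  counts <- cbind(c(3, 1), c(0, 0))
  m <- CountMatrix(counts, gene_ids = c("g1", "g2"), barcodes = c("ok", "empty"))
  expect_warning(e <- normalize_log(m), "zero-total")
  expect_equal(e$barcodes, "ok")
})

test_that("HVG selection flags dispersion outliers within mean bins", {
  set.seed(31)
  n_genes <- 100; n_cells <- 200
  vals <- matrix(rnorm(n_genes * n_cells, mean = 1, sd = 0.1), n_genes, n_cells)
  vals[50, ] <- rnorm(n_cells, mean = 1, sd = 1)      # 10x the sd, same mean
  vals <- pmax(vals, 0)
  e <- ExprMatrix(vals, gene_ids = sprintf("g%03d", 1:n_genes),
                  barcodes = sprintf("c%03d", 1:n_cells))
  hv <- select_hvgs(e, hvg_params(batch_key = NULL, n_bins = 5))
  expect_true("g050" %in% hv)
  expect_equal(hv[1], "g050")   # ranked first by normalized dispersion

  # a high-mean housekeeping-like gene is excluded by max_mean
  vals2 <- vals
  vals2[10, ] <- rnorm(n_cells, mean = 6, sd = 2)     # log1p(mean expm1) > 3
  e2 <- ExprMatrix(vals2, gene_ids = e$gene_ids, barcodes = e$barcodes)
  hv2 <- select_hvgs(e2, hvg_params(batch_key = NULL, n_bins = 5))
  expect_false("g010" %in% hv2)
})

test_that("HVGs merge across batches with the >= 1 batch rule", {
  set.seed(32)
  n_genes <- 60; n_cells <- 120
  base <- matrix(rnorm(n_genes * n_cells, 1, 0.1), n_genes, n_cells)
  batch <- rep(c("b1", "b2"), each = n_cells / 2)
  base[20, batch == "b1"] <- rnorm(n_cells / 2, 1, 1)  # variable in b1 only
  e <- ExprMatrix(pmax(base, 0), gene_ids = sprintf("g%03d", 1:n_genes),
                  barcodes = sprintf("c%03d", 1:n_cells),
                  cell_meta = data.frame(sample_id = batch))
  hv_merged <- select_hvgs(e, hvg_params(n_bins = 4, batch_key = "sample_id"))
  expect_true("g020" %in% hv_merged)
  hv_b2 <- select_hvgs(
    ExprMatrix(pmax(base[, batch == "b2"], 0), gene_ids = e$gene_ids,
               barcodes = e$barcodes[batch == "b2"]),
    hvg_params(n_bins = 4, batch_key = NULL))
  expect_false("g020" %in% hv_b2)
  # the CAR pseudo-feature is never reported
  e_car <- ExprMatrix(rbind(pmax(base, 0), runif(n_cells) * 5),
                      gene_ids = c(sprintf("g%03d", 1:n_genes), car_feature_id()),
                      barcodes = e$barcodes,
                      cell_meta = data.frame(sample_id = batch))
  expect_false(car_feature_id() %in%
                 select_hvgs(e_car, hvg_params(n_bins = 4, batch_key = "sample_id")))
})

test_that("covariate regression returns exact OLS residuals", {
  set.seed(41)
  n_cells <- 50
  cov <- data.frame(depth = rnorm(n_cells))
  # expression exactly linear in the covariate -> residuals ~ 0
  vals <- rbind(2 + 3 * cov$depth, -1 + 0.5 * cov$depth)
  e <- ExprMatrix(vals, gene_ids = c("lin1", "lin2"),
                  barcodes = sprintf("c%02d", 1:n_cells))
  r <- regress_out(e, cov)
  expect_lt(max(abs(r$values)), 1e-8)

  # covariate orthogonal to centered expression -> residuals = centered values
  x <- rnorm(n_cells)
  g <- rnorm(n_cells)
  g_c <- g - mean(g)
  x_c <- x - mean(x)
  g_orth <- g_c - sum(g_c * x_c) / sum(x_c^2) * x_c  # remove any incidental fit
  e2 <- ExprMatrix(matrix(g_orth + 5, 1), gene_ids = "g",
                   barcodes = sprintf("c%02d", 1:n_cells))
  r2 <- regress_out(e2, data.frame(depth = x))
  expect_equal(as.numeric(r2$values), g_orth, tolerance = 1e-10)

  # constant covariate reduces to intercept-only centering
  r3 <- regress_out(e2, data.frame(const = rep(2, n_cells)))
  expect_equal(as.numeric(r3$values),
               as.numeric(e2$values) - mean(e2$values), tolerance = 1e-10)

  # collinear covariates are named in the error
  expect_error(regress_out(e2, data.frame(a = x, b = 2 * x)), "b",
               class = "cartatlas_config_error")
})

test_that("cell-cycle scoring recovers planted stages", {
  cfg <- sim_config(cells_per_condition_per_donor = 200, n_genes = 800,
                    seed = 51)
  sim <- simulate_product(cfg, conditions = "unstimulated")
  e <- normalize_log(sim$matrix)
  sets <- cellcycle_gene_sets()
  cc <- suppressWarnings(cellcycle_score(e, sets$s, sets$g2m,
                                         score_params(seed = 4)))
  tr <- sim$truth[e$barcodes, ]
  expect_gt(mean(cc$stage[tr$cellcycle_stage == "G2M"] == "G2M"), 0.8)
  expect_gt(mean(cc$stage[tr$cellcycle_stage == "S"] == "S"), 0.8)
  # planted cycling programs are far likelier to be called in cycling cells
  expect_gt(mean(cc$stage[tr$cellcycle_stage == "G2M"] == "G2M"),
            mean(cc$stage[tr$cellcycle_stage == "G1"] == "G2M") + 0.5)

  # all-constant expression scores 0 for both phases -> G1 by the tie rule
  vals <- matrix(1, 25, 10)
  rn <- c(sets$s$genes[1:5], sets$g2m$genes[1:5], sprintf("f%02d", 1:15))
  e0 <- ExprMatrix(vals, gene_ids = rn, barcodes = sprintf("c%02d", 1:10))
  cc0 <- suppressWarnings(cellcycle_score(e0, sets$s, sets$g2m,
                                          score_params(n_bins = 2, ctrl_per_gene = 3,
                                                       seed = 1)))
  expect_true(all(cc0$S_score == 0))
  expect_true(all(cc0$stage == "G1"))
})
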