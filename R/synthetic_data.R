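# Multi-donor, multi-condition synthetic CAR-T count-matrix generator with
# planted ground truth. The generative model is negative binomial on top of
# per-cluster gene programs, per-donor multiplicative effects and per-cell
# library sizes; a vector-derived CAR pseudo-feature ("CAR-3LTR") marks
# transduced cells at the UMI level.

CAR_FEATURE_ID <- "CAR-3LTR"

# Gene programs named in the study's activation / exhaustion signatures.
ACTIVATION_UP <- c("IL2RA", "MYC", "GZMB", "IL2", "IL3", "IL4", "IL5", "IL8",
                   "IL13", "CSF2", "CCR4", "BATF3", "IRF4")
ACTIVATION_DOWN <- c("SELL", "CD3D", "CD3E", "CD3G", "B2M")
EXHAUSTION_UP <- c("LAG3", "HAVCR2", "CTLA4", "TIGIT", "TBX21", "IFNG",
                   "CCL1", "CCL3", "CCL4", "CCL5", "ENTPD1")
S_GENES <- c("MCM2", "MCM3", "MCM4", "MCM5", "MCM6", "PCNA", "RRM2", "TYMS",
             "FEN1", "GINS2")
G2M_GENES <- c("MKI67", "TOP2A", "CCNB1", "CDK1", "UBE2C", "BUB1", "AURKA",
               "PLK1", "CENPA", "TPX2")

#' Default CAR feature identifier
#'
#' The CAR transcript is carried as an ordinary feature row named after the
#' vector's 3' long terminal repeat; it is excluded from normalization, HVG
#' selection and differential expression by the standing exclusion list.
#' @return character scalar `"CAR-3LTR"`.
#' @export
car_feature_id <- function() CAR_FEATURE_ID

#' Simulation configuration
#'
#' Builds the configuration for [simulate_product()] and
#' [simulate_leukapheresis()]. Defaults reproduce the cellular structure of a
#' three-donor CAR-T product study: per stimulated sample, 22.5% of cells carry
#' detectable CAR UMIs, half of the CAR-expressing cells respond to antigen by
#' adopting an activation program, 7% of responders additionally carry an
#' exhaustion program with elevated CAR expression, and 7% of unstimulated
#' CAR-expressing cells are activated without antigen. Cluster structure is
#' driven by CD4/CD8 identity, CCR7/SELL memory state and cell-cycle stage.
#'
#' @param n_donors number of donors (default 3).
#' @param cells_per_condition_per_donor cells per donor per condition
#'   (default 6234, matching ~37,400 product cells over 3 donors x 2
#'   conditions and ~2,104 planted responders in the stimulated arm).
#' @param n_genes total simulated genes including markers (>= 500).
#' @param car_fraction fraction of product cells that are CAR-positive.
#' @param responder_fraction fraction of stimulated CAR+ cells moved to the
#'   activated program.
#' @param exhausted_fraction fraction of responders given the exhaustion
#'   program.
#' @param pre_activated_fraction fraction of unstimulated CAR+ cells already
#'   activated.
#' @param car_umi_mean negative-binomial mean CAR UMIs in CAR+ cells.
#' @param car_umi_mean_exhausted_multiplier CAR UMI mean multiplier for
#'   exhausted cells (> 1 models their elevated CAR expression).
#' @param donor_effect_sd log-scale sd of the per-donor per-gene
#'   multiplicative effect.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); > 0 gives super-Poisson counts.
#' @param library_size_meanlog,library_size_sdlog log-normal per-cell library
#'   size; the default mean (~60,000 UMIs) keeps product cells above the
#'   30,000-UMI QC floor.
#' @param mito_gene_count number of mitochondrial ("MT-") genes.
#' @param mito_fraction_mean,mito_fraction_sd Beta-distributed per-cell
#'   mitochondrial share (defaults put ~7% of cells above the 8% QC cutoff).
#' @param contaminant_fraction non-T (CD3E-negative, GNLY/NKG7-high)
#'   contaminant fraction in leukapheresis samples.
#' @param cycling_s_fraction,cycling_g2m_fraction fraction of cells planted in
#'   S and G2M stages.
#' @param program_fold,activation_fold,exhaustion_fold multiplicative effect
#'   sizes of cluster-identity, activation and exhaustion programs.
#' @param cluster_programs optional named list overriding the default base
#'   cluster programs; each element is
#'   `list(fold = named numeric, proportion = numeric)`.
#' @param seed integer seed; all simulation randomness derives from it.
#' @return object of class `SimConfig`.
#' @export
sim_config <- function(n_donors = 3,
                       cells_per_condition_per_donor = 6234,
                       n_genes = 2000,
                       car_fraction = 0.225,
                       responder_fraction = 0.5,
                       exhausted_fraction = 0.07,
                       pre_activated_fraction = 0.07,
                       car_umi_mean = 5,
                       car_umi_mean_exhausted_multiplier = 2,
                       donor_effect_sd = 0.03,
                       nb_dispersion = 0.1,
                       library_size_meanlog = log(60000),
                       library_size_sdlog = 0.25,
                       mito_gene_count = 10,
                       mito_fraction_mean = 0.05,
                       mito_fraction_sd = 0.02,
                       contaminant_fraction = 0.02,
                       cycling_s_fraction = 0.08,
                       cycling_g2m_fraction = 0.07,
                       program_fold = 4,
                       activation_fold = 6,
                       exhaustion_fold = 12,
                       cluster_programs = NULL,
                       seed = 1L) {
  fracs <- c(car_fraction = car_fraction,
             responder_fraction = responder_fraction,
             exhausted_fraction = exhausted_fraction,
             pre_activated_fraction = pre_activated_fraction,
             contaminant_fraction = contaminant_fraction,
             mito_fraction_mean = mito_fraction_mean)
  if (any(fracs < 0 | fracs > 1)) {
    stop_config("fractions must lie in [0, 1]: ",
                paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", "))
  }
  if (n_genes < 500) stop_config("n_genes must be >= 500")
  if (nb_dispersion <= 0) stop_config("nb_dispersion must be > 0")
  if (car_umi_mean_exhausted_multiplier <= 1) {
    stop_config("car_umi_mean_exhausted_multiplier must be > 1")
  }
  if (cycling_s_fraction + cycling_g2m_fraction >= 1) {
    stop_config("cycling fractions must sum to < 1")
  }
  cfg <- structure(
    list(n_donors = as.integer(n_donors),
         cells_per_condition_per_donor = as.integer(cells_per_condition_per_donor),
         n_genes = as.integer(n_genes),
         car_fraction = car_fraction,
         responder_fraction = responder_fraction,
         exhausted_fraction = exhausted_fraction,
         pre_activated_fraction = pre_activated_fraction,
         car_umi_mean = car_umi_mean,
         car_umi_mean_exhausted_multiplier = car_umi_mean_exhausted_multiplier,
         donor_effect_sd = donor_effect_sd,
         nb_dispersion = nb_dispersion,
         library_size_meanlog = library_size_meanlog,
         library_size_sdlog = library_size_sdlog,
         mito_gene_count = as.integer(mito_gene_count),
         mito_fraction_mean = mito_fraction_mean,
         mito_fraction_sd = mito_fraction_sd,
         contaminant_fraction = contaminant_fraction,
         cycling_s_fraction = cycling_s_fraction,
         cycling_g2m_fraction = cycling_g2m_fraction,
         program_fold = program_fold,
         activation_fold = activation_fold,
         exhaustion_fold = exhaustion_fold,
         cluster_programs = cluster_programs,
         seed = as.integer(seed)),
    class = "SimConfig")
  cfg
}

#' @exportS3Method base::print
print.SimConfig <- function(x, ...) {
  cat("SimConfig:", x$n_donors, "donors x",
      x$cells_per_condition_per_donor, "cells/condition;",
      x$n_genes, "genes; CAR+", x$car_fraction,
      "| responders", x$responder_fraction,
      "| exhausted", x$exhausted_fraction, "\n")
  invisible(x)
}

# Gene universe: named marker genes with fixed baseline weights, per-cluster
# synthetic program genes, mitochondrial genes, and log-normal filler genes.
# Weights are relative expression levels before per-cell library scaling;
# inducible program genes start low so fold inductions stay separable.
build_universe <- function(cfg) {
  markers <- c(
    CD4 = 3, CD8A = 3, CD8B = 3, CCR7 = 3, SELL = 5, GZMA = 1,
    CD3D = 5, CD3E = 5, CD3G = 5, B2M = 8,
    NKG7 = 1, GNLY = 0.25, NCAM1 = 0.25)
  inducible <- setNames(rep(0.25, length(c(ACTIVATION_UP, EXHAUSTION_UP))),
                        c(ACTIVATION_UP, EXHAUSTION_UP))
  inducible <- inducible[setdiff(names(inducible), names(markers))]
  cc <- setNames(rep(1, length(c(S_GENES, G2M_GENES))), c(S_GENES, G2M_GENES))
  prg_names <- function(tag) sprintf("%sPRG%02d", tag, 1:30)
  prg <- setNames(rep(1, 150),
                  c(prg_names("CMCD4"), prg_names("EMCD4"), prg_names("CMCD8"),
                    prg_names("EFFCD8"), prg_names("ACT")))
  prg[grep("^ACTPRG", names(prg))] <- 0.25
  fixed <- c(markers, inducible, cc, prg)
  mito <- setNames(rep(2, cfg$mito_gene_count),
                   sprintf("MT-SIM%02d", seq_len(cfg$mito_gene_count)))
  n_fill <- cfg$n_genes - length(fixed) - length(mito)
  if (n_fill < 0) stop_config("n_genes too small for the fixed marker set")
  fill <- setNames(rlnorm(n_fill, meanlog = 0, sdlog = 1.25),
                   sprintf("GENE%05d", seq_len(n_fill)))
  weights <- c(fixed, mito, fill)
  list(symbols = names(weights),
       weights = unname(weights),
       mito = names(mito))
}

# Default base (non-activated) cluster programs: multiplicative folds applied
# to universe weights, plus a dedicated 30-gene synthetic program per cluster.
default_cluster_programs <- function(cfg) {
  f <- cfg$program_fold
  mk <- function(tag, extra) {
    fold <- c(extra, setNames(rep(f, 30), sprintf("%sPRG%02d", tag, 1:30)))
    fold
  }
  list(
    cm_cd4 = list(
      fold = mk("CMCD4", c(CD4 = f, CCR7 = f, SELL = f, CD8A = .05, CD8B = .05)),
      proportion = 0.30),
    em_cd4 = list(
      fold = mk("EMCD4", c(CD4 = f, CCR7 = .3, SELL = .4, GZMA = f,
                           CD8A = .05, CD8B = .05)),
      proportion = 0.25),
    cm_cd8 = list(
      fold = mk("CMCD8", c(CD8A = f, CD8B = f, CCR7 = f, SELL = f, CD4 = .05)),
      proportion = 0.25),
    eff_cd8 = list(
      fold = mk("EFFCD8", c(CD8A = f, CD8B = f, NKG7 = f, GZMB = f,
                            CCR7 = .2, SELL = .2, CD4 = .05)),
      proportion = 0.20))
}

activation_fold_vector <- function(cfg) {
  c(setNames(rep(cfg$activation_fold, length(ACTIVATION_UP) + 30),
             c(ACTIVATION_UP, sprintf("ACTPRG%02d", 1:30))),
    setNames(rep(1 / cfg$activation_fold, length(ACTIVATION_DOWN)),
             ACTIVATION_DOWN))
}

exhaustion_fold_vector <- function(cfg) {
  setNames(rep(cfg$exhaustion_fold, length(EXHAUSTION_UP)), EXHAUSTION_UP)
}

contaminant_fold_vector <- function() {
  c(CD3D = 0, CD3E = 0, CD3G = 0, CD4 = 0.05, CD8A = 0.05, CD8B = 0.05,
    GNLY = 60, NKG7 = 15, NCAM1 = 60)
}

# Apply a named fold vector to a weight vector indexed by symbol.
apply_fold <- function(weights, symbols, fold) {
  if (length(fold) == 0) return(weights)
  idx <- match(names(fold), symbols)
  if (anyNA(idx)) {
    stop_config("program gene(s) not in the simulated universe: ",
                paste(names(fold)[is.na(idx)], collapse = ", "))
  }
  weights[idx] <- weights[idx] * unname(fold)
  weights
}

# Draw NB counts for one homogeneous cell group. `base` is the relative mean
# vector over non-mito genes; each cell scales it to its own library size and
# mitochondrial share.
draw_group_counts <- function(base, mito_w, lib, mito_f, size) {
  g <- length(base); nm <- length(mito_w); nc <- length(lib)
  base_n <- base / sum(base)
  mito_n <- mito_w / sum(mito_w)
  mu_main <- outer(base_n, lib * (1 - mito_f))
  mu_mito <- outer(mito_n, lib * mito_f)
  main <- matrix(rnbinom(g * nc, mu = mu_main, size = size), g, nc)
  mito <- matrix(rnbinom(nm * nc, mu = mu_mito, size = size), nm, nc)
  rbind(main, mito)
}

# Shared engine behind simulate_product() and simulate_leukapheresis().
simulate_engine <- function(cfg, conditions, leukapheresis, seed_offset) {
  with_seed(cfg$seed + seed_offset, {
    uni <- build_universe(cfg)
    symbols <- uni$symbols
    mito_idx <- match(uni$mito, symbols)
    main_idx <- setdiff(seq_along(symbols), mito_idx)
    programs <- cfg$cluster_programs %||% default_cluster_programs(cfg)
    props <- vapply(programs, function(p) p$proportion, numeric(1))
    if (abs(sum(props) - 1) > 1e-8) stop_config("cluster proportions must sum to 1")
    act_fold <- activation_fold_vector(cfg)
    exh_fold <- exhaustion_fold_vector(cfg)
    # validate program genes against the universe up front
    for (p in programs) apply_fold(uni$weights, symbols, p$fold)
    apply_fold(uni$weights, symbols, act_fold)
    apply_fold(uni$weights, symbols, exh_fold)

    # per-donor per-gene multiplicative effect, shared across conditions
    donor_fx <- matrix(rlnorm(cfg$n_donors * length(symbols),
                              meanlog = 0, sdlog = cfg$donor_effect_sd),
                       nrow = cfg$n_donors)

    n <- cfg$cells_per_condition_per_donor
    size <- 1 / cfg$nb_dispersion
    # Beta parameters for the per-cell mitochondrial share
    mv <- cfg$mito_fraction_sd^2
    mm <- cfg$mito_fraction_mean
    ab <- mm * (1 - mm) / mv - 1
    mito_a <- mm * ab; mito_b <- (1 - mm) * ab

    blocks <- list(); truths <- list(); block_i <- 0
    for (d in seq_len(cfg$n_donors)) {
      for (cond in conditions) {
        # --- plant per-cell labels -------------------------------------
        cluster <- character(n)
        car <- responder <- exhausted <- contaminant <- logical(n)
        if (leukapheresis) {
          n_cont <- alloc_binary(n, cfg$contaminant_fraction)
          contaminant[sample.int(n, n_cont)] <- TRUE
        } else {
          n_car <- alloc_binary(n, cfg$car_fraction)
          car[sample.int(n, n_car)] <- TRUE
          car_idx <- which(car)
          resp_frac <- if (cond == "stimulated") cfg$responder_fraction
                       else cfg$pre_activated_fraction
          n_resp <- alloc_binary(n_car, resp_frac)
          resp_idx <- car_idx[sample.int(n_car, n_resp)]
          responder[resp_idx] <- TRUE
          if (cond == "stimulated") {
            n_exh <- alloc_binary(n_resp, cfg$exhausted_fraction)
            exhausted[resp_idx[sample.int(max(n_resp, 1), n_exh)]] <- TRUE
          }
        }
        # base-cluster assignment for everything not activated/contaminant
        free <- which(!responder & !contaminant)
        n_per_cluster <- alloc_counts(length(free), props)
        # largest-remainder can undershoot by ties; pad the first cluster
        n_per_cluster[1] <- n_per_cluster[1] + (length(free) - sum(n_per_cluster))
        assign <- sample(rep(names(programs), n_per_cluster))
        cluster[free] <- assign
        cluster[responder] <- "activated"
        cluster[contaminant] <- "nk_like"
        stage <- sample(c("G1", "S", "G2M"), n, replace = TRUE,
                        prob = c(1 - cfg$cycling_s_fraction - cfg$cycling_g2m_fraction,
                                 cfg$cycling_s_fraction, cfg$cycling_g2m_fraction))
        lib <- rlnorm(n, cfg$library_size_meanlog, cfg$library_size_sdlog)
        mito_f <- stats::rbeta(n, mito_a, mito_b)

        # --- draw counts by homogeneous group --------------------------
        counts <- matrix(0L, length(symbols), n)
        key <- paste(cluster, exhausted, stage)
        for (k in unique(key)) {
          cells <- which(key == k)
          cl <- cluster[cells[1]]
          w <- uni$weights * donor_fx[d, ]
          if (cl %in% names(programs)) {
            w <- apply_fold(w, symbols, programs[[cl]]$fold)
          } else if (cl == "activated") {
            w <- apply_fold(w, symbols, act_fold)
          } else if (cl == "nk_like") {
            w <- apply_fold(w, symbols, contaminant_fold_vector())
          }
          if (exhausted[cells[1]]) w <- apply_fold(w, symbols, exh_fold)
          st <- stage[cells[1]]
          if (st == "S") {
            w <- apply_fold(w, symbols,
                            setNames(rep(cfg$program_fold, length(S_GENES)), S_GENES))
          } else if (st == "G2M") {
            w <- apply_fold(w, symbols,
                            setNames(rep(cfg$program_fold, length(G2M_GENES)), G2M_GENES))
          }
          counts[c(main_idx, mito_idx), cells] <-
            draw_group_counts(w[main_idx], w[mito_idx],
                              lib[cells], mito_f[cells], size)
        }
        # --- CAR pseudo-feature ----------------------------------------
        car_umis <- integer(n)
        if (any(car)) {
          mu <- ifelse(exhausted[car], cfg$car_umi_mean *
                         cfg$car_umi_mean_exhausted_multiplier, cfg$car_umi_mean)
          car_umis[car] <- rnbinom(sum(car), mu = mu, size = size)
        }
        counts <- rbind(counts, car_umis)

        block_i <- block_i + 1
        sample_id <- sprintf("donor%d_%s", d, cond)
        barcodes <- sprintf("%s_cell%05d", sample_id, seq_len(n))
        blocks[[block_i]] <- as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
        truths[[block_i]] <- data.frame(
          barcode = barcodes,
          donor = sprintf("donor%d", d),
          condition = cond,
          sample_id = sample_id,
          true_cluster = cluster,
          car_positive = car,
          responder = responder,
          exhausted = exhausted,
          contaminant = contaminant,
          cellcycle_stage = stage,
          stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, truths)
    counts <- do.call(cbind, blocks)
    # draw_group_counts lays rows out main-then-mito, but the indexed
    # assignment restores universe order; the CAR feature row is appended.
    gene_syms <- c(uni$symbols, CAR_FEATURE_ID)
    gene_ids <- c(sprintf("SIMG%05d", seq_along(uni$symbols)), CAR_FEATURE_ID)
    meta <- truth[, c("donor", "condition", "sample_id")]
    rownames(meta) <- truth$barcode
    m <- CountMatrix(counts, gene_ids = gene_ids, gene_names = gene_syms,
                     barcodes = truth$barcode, cell_meta = meta)
    rownames(truth) <- truth$barcode
    class(truth) <- c("GroundTruth", "data.frame")
    list(matrix = m, truth = truth)
  })
}

#' Simulate CAR-T product samples
#'
#' Generates unstimulated and antigen-stimulated product samples for each
#' donor under the configured generative model: log-normal cluster baselines
#' with program fold-shifts, per-donor multiplicative effects, log-normal
#' library sizes, negative-binomial counts, a controlled mitochondrial share,
#' and a CAR pseudo-feature row whose UMI mean is elevated in exhausted cells.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg [sim_config()] object.
#' @param conditions subset of `c("unstimulated", "stimulated")` to generate.
#' @return list with elements `matrix` ([CountMatrix()]) and `truth`
#'   (`GroundTruth` data.frame of planted per-cell labels).
#' @export
simulate_product <- function(cfg, conditions = c("unstimulated", "stimulated")) {
  stopifnot(inherits(cfg, "SimConfig"))
  conditions <- match.arg(conditions, several.ok = TRUE)
  simulate_engine(cfg, conditions, leukapheresis = FALSE, seed_offset = 0L)
}

#' Simulate leukapheresis samples
#'
#' Same generative model as [simulate_product()] but with no CAR-positive
#' cells (the CAR pseudo-feature row is all zero), no activated program, and a
#' small CD3E-negative, GNLY/NKG7-high contaminant population resembling NK
#' cells.
#'
#' @param cfg [sim_config()] object.
#' @return list with elements `matrix` and `truth` as in [simulate_product()].
#' @export
simulate_leukapheresis <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  simulate_engine(cfg, "leukapheresis", leukapheresis = TRUE, seed_offset = 7L)
}

#' Write a simulation to disk
#'
#' Emits a 10X-style directory via [write_10x_mtx()] plus `ground_truth.tsv`.
#'
#' @param sim result of [simulate_product()] or [simulate_leukapheresis()].
#' @param directory output directory.
#' @return `directory`, invisibly.
#' @export
write_simulation <- function(sim, directory) {
  write_10x_mtx(sim$matrix, directory)
  write.table(sim$truth, file.path(directory, "ground_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(directory)
}
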