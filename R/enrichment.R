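# Over-representation testing (hypergeometric upper tail), the up/down
# pathway ratio statistic, and pre-ranked GSEA with the classic (unweighted)
# running-sum enrichment statistic.

#' Hypergeometric upper-tail p-value
#'
#' P(X >= x) when drawing `k` genes from a universe of `N` of which `m` are
#' marked: `sum_{i=x}^{min(k, m)} C(m, i) C(N-m, k-i) / C(N, k)`. Computed
#' via the log-gamma-based distribution function, numerically stable for
#' genome-scale inputs.
#'
#' @param x observed overlap (0 <= x <= min(m, k)).
#' @param N universe size (total expressed genes).
#' @param m genes in the term.
#' @param k up- or down-regulated genes.
#' @return upper-tail probability; exactly 1 when x = 0.
#' @export
hypergeom_upper_pval <- function(x, N, m, k) {
  if (any(c(x, N, m, k) < 0) || m > N || k > N || x > min(m, k)) {
    stop_config("invalid hypergeometric input: need 0 <= x <= min(m, k), m <= N, k <= N")
  }
  phyper(x - 1, m, N - m, k, lower.tail = FALSE)
}

#' Over-representation of gene-set terms
#'
#' For each term, the hypergeometric upper-tail p-value of its overlap with
#' the upregulated list (and the downregulated list when provided), BH
#' correction across terms, and — for significant terms — the log2 ratio of
#' upregulated to downregulated overlap.
#'
#' Ratio edge cases (not addressed by the formula's source): a zero
#' denominator with positive numerator yields `+Inf` (reported, plotted at a
#' cap elsewhere); zero over zero is `NA` (undefined).
#'
#' @param up,down character vectors of gene symbols (down may be empty).
#' @param terms list of [GeneSet()] terms.
#' @param universe character vector of all expressed genes; term genes
#'   outside it are silently restricted (restriction count reported in the
#'   `n_restricted` column).
#' @param max_fdr significance cutoff on the BH-adjusted up p-value
#'   (default 0.05).
#' @return data.frame of class `EnrichmentResult`: term, N, m, k_up, x_up,
#'   p_up, q_up, k_down, x_down, p_down, q_down, significant,
#'   updown_log2_ratio, n_restricted.
#' @export
enrich_terms <- function(up, down = character(), terms, universe,
                         max_fdr = 0.05) {
  if (length(terms) == 0) stop_config("no terms given")
  if (!all(up %in% universe)) stop_config("up genes outside the universe")
  if (!all(down %in% universe)) stop_config("down genes outside the universe")
  N <- length(unique(universe))
  rows <- lapply(terms, function(tm) {
    genes <- unique(tm$genes)
    restricted <- setdiff(genes, universe)
    genes <- intersect(genes, universe)
    m <- length(genes)
    x_up <- length(intersect(genes, up))
    x_dn <- length(intersect(genes, down))
    data.frame(term = tm$name, N = N, m = m,
               k_up = length(up), x_up = x_up,
               p_up = if (m > 0) hypergeom_upper_pval(x_up, N, m, length(up)) else 1,
               k_down = length(down), x_down = x_dn,
               p_down = if (m > 0 && length(down) > 0) {
                 hypergeom_upper_pval(x_dn, N, m, length(down))
               } else NA_real_,
               n_restricted = length(restricted),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_up <- bh_adjust(res$p_up)
  res$q_down <- if (all(is.na(res$p_down))) NA_real_ else bh_adjust(res$p_down)
  res$significant <- res$q_up < max_fdr
  ratio <- rep(NA_real_, nrow(res))
  sig <- which(res$significant)
  for (i in sig) {
    if (res$x_up[i] == 0 && res$x_down[i] == 0) {
      ratio[i] <- NA_real_
    } else if (res$x_down[i] == 0) {
      ratio[i] <- Inf
    } else {
      ratio[i] <- log2(res$x_up[i] / res$x_down[i])
    }
  }
  res$updown_log2_ratio <- ratio
  class(res) <- c("EnrichmentResult", "data.frame")
  res
}

#' Rank genes for pre-ranked GSEA
#'
#' Ranking score `(1 / q) * sign(log2FC)` from a differential-expression
#' table, ordered descending (most upregulated first). q-values are clipped
#' below at 1e-300 to avoid infinities; a zero log2 fold change scores 0 and
#' falls mid-list.
#'
#' @param results `DEResult` data.frame (from [welch_ttest_by_gene()]).
#' @return data.frame (gene_id, gene_name, score) in ranking order.
#' @export
rank_genes_for_gsea <- function(results) {
  q <- pmax(results$q_value, 1e-300)
  score <- (1 / q) * sign(results$log2_fold_change)
  ord <- order(-score)
  data.frame(gene_id = results$gene_id[ord],
             gene_name = results$gene_name[ord],
             score = score[ord],
             stringsAsFactors = FALSE)
}

# Classic (unweighted) running-sum enrichment score for one set of member
# positions within a ranking of length n_total. Returns the signed maximum
# deviation and the position at which it is attained.
classic_es <- function(member, n_total) {
  n_hit <- length(member)
  n_miss <- n_total - n_hit
  step <- rep(-1 / n_miss, n_total)
  step[member] <- 1 / n_hit
  rs <- cumsum(step)
  i <- which.max(abs(rs))
  list(es = rs[i], at = i, running = rs)
}

#' Pre-ranked gene set enrichment analysis (classic statistic)
#'
#' Walks the ranked gene list accumulating `+1/n_hits` at set members and
#' `-1/(n_total - n_hits)` otherwise; the enrichment score (ES) is the signed
#' maximum deviation of this running sum. The null distribution comes from
#' `n_perm` random same-size gene sets (gene-tag permutation, seeded); the
#' nominal p-value is the fraction of same-sign null ES at least as extreme,
#' NES is ES divided by the mean |null ES| of the same sign, and the FDR q
#' follows the standard GSEA procedure over the collection of sets. Sets with
#' fewer than `min_size` or more than `max_size` members in the ranking are
#' skipped with a reason.
#'
#' @param ranked data.frame from [rank_genes_for_gsea()] (or a character
#'   vector of gene names in ranking order). Matching is by `gene_name`.
#' @param gene_sets list of [GeneSet()] (a single GeneSet is accepted).
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @param min_size,max_size set-size window (defaults 15 and 500).
#' @return data.frame of class `GseaResult`: gene_set, size, es, nes,
#'   nominal_p, fdr_q, n_perm, skipped, reason; attribute `leading_edge` is a
#'   named list of leading-edge gene vectors.
#' @export
gsea_preranked <- function(ranked, gene_sets, n_perm = 1000, seed = 0L,
                           min_size = 15, max_size = 500) {
  if (inherits(gene_sets, "GeneSet")) gene_sets <- list(gene_sets)
  genes <- if (is.data.frame(ranked)) ranked$gene_name else as.character(ranked)
  n_total <- length(genes)

  prep <- lapply(gene_sets, function(gs) {
    member <- which(genes %in% gs$genes)
    size <- length(member)
    skip <- size < min_size || size > max_size || size == n_total
    list(name = gs$name, member = member, size = size, skipped = skip,
         reason = if (!skip) "" else if (size < min_size) "set too small"
                  else if (size > max_size) "set too large"
                  else "set spans the whole ranking")
  })
  active <- Filter(function(p) !p$skipped, prep)

  null_es <- list()
  obs <- list()
  if (length(active)) {
    sizes <- unique(vapply(active, function(p) p$size, numeric(1)))
    null_by_size <- with_seed(seed, {
      setNames(lapply(sizes, function(s) {
        vapply(seq_len(n_perm), function(i) {
          classic_es(sample.int(n_total, s), n_total)$es
        }, numeric(1))
      }), as.character(sizes))
    })
    for (p in active) {
      res <- classic_es(p$member, n_total)
      null <- null_by_size[[as.character(p$size)]]
      same <- null[sign(null) == sign(res$es) | res$es == 0]
      nominal_p <- if (length(same) == 0) 1 / n_perm else {
        (sum(abs(same) >= abs(res$es)) + 1) / (length(same) + 1)
      }
      denom <- mean(abs(same))
      nes <- if (is.finite(denom) && denom > 0) res$es / denom else 0
      null_nes <- null / ifelse(rep(denom, length(null)) > 0, denom, 1)
      le <- if (res$es >= 0) {
        genes[intersect(p$member, seq_len(res$at))]
      } else {
        genes[p$member[p$member >= res$at]]
      }
      obs[[p$name]] <- list(es = res$es, nes = nes, p = nominal_p,
                            size = p$size, leading_edge = le)
      null_es[[p$name]] <- null_nes
    }
  }
  # GSEA-style FDR over the collection: compare each observed NES with the
  # pooled null NES of matching sign.
  all_null <- unlist(null_es, use.names = FALSE)
  all_obs <- vapply(obs, function(o) o$nes, numeric(1))
  fdr_for <- function(nes) {
    if (nes == 0) return(1)
    if (nes > 0) {
      num <- mean(all_null >= nes)
      den <- mean(all_obs >= nes)
    } else {
      num <- mean(all_null <= nes)
      den <- mean(all_obs <= nes)
    }
    if (den == 0) return(1)
    min(1, num / den)
  }
  rows <- lapply(prep, function(p) {
    if (p$skipped) {
      data.frame(gene_set = p$name, size = p$size, es = NA_real_,
                 nes = NA_real_, nominal_p = NA_real_, fdr_q = NA_real_,
                 n_perm = n_perm, skipped = TRUE, reason = p$reason,
                 stringsAsFactors = FALSE)
    } else {
      o <- obs[[p$name]]
      data.frame(gene_set = p$name, size = o$size, es = o$es, nes = o$nes,
                 nominal_p = o$p, fdr_q = fdr_for(o$nes), n_perm = n_perm,
                 skipped = FALSE, reason = "", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "leading_edge") <- lapply(obs, function(o) o$leading_edge)
  class(out) <- c("GseaResult", "data.frame")
  out
}
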