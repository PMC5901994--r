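#' Minimum p-value per gene
#'
#' Collapses gene-tSNP rows to one row per gene carrying the smallest
#' p-value; applied separately to discovery and replication result sets.
#'
#' @param results data.frame with columns `gene_id` and `p_value`.
#' @return data.frame with one row per gene: `gene_id`, `p_value`,
#'   `n_tsnps` (rows collapsed).
#' @export
min_p_per_gene <- function(results) {
  if (!all(c("gene_id", "p_value") %in% names(results)))
    stop("results must have columns gene_id, p_value")
  sp <- split(results$p_value, as.character(results$gene_id))
  data.frame(gene_id = names(sp),
             p_value = vapply(sp, min, numeric(1)),
             n_tsnps = vapply(sp, length, integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Discovery-to-replication rate curve with hypergeometric null band
#'
#' Treating one cohort as discovery and the other as replication over a
#' shared gene universe of size N, the curve walks the sorted unique
#' discovery p-values from largest to smallest; at each cutoff the n genes
#' with discovery p <= cutoff are "hits", k of which replicate (replication
#' p < `rep_alpha`), giving rate k/n. K is the total number of replicating
#' genes in the universe. Under the null that hits are drawn without regard
#' to replication status, k is hypergeometric(N, K, n) with mean n K/N, so
#' the band is K/N +/- 2 sd(k/n). The curve stops once n < `min_n`.
#'
#' @param disc per-gene discovery p-values: data.frame `gene_id`, `p_value`.
#' @param rep per-gene replication p-values, same gene universe.
#' @param rep_alpha replication significance threshold (default 0.01).
#' @param min_n smallest hit-set size reported (default 10).
#' @return data.frame of class `replication_curve`: `cutoff`, `n`, `k`,
#'   `rate`, `k_over_K`, `null_mean`, `band_lo`, `band_hi`; attributes `K`
#'   and `N`.
#' @export
replication_curve <- function(disc, rep, rep_alpha = 0.01, min_n = 10L) {
  if (!setequal(disc$gene_id, rep$gene_id))
    stop("discovery and replication gene universes differ")
  if (anyDuplicated(disc$gene_id) || anyDuplicated(rep$gene_id))
    stop("one row per gene required (use min_p_per_gene first)")
  N <- nrow(disc)
  pd <- disc$p_value
  pr <- rep$p_value[match(disc$gene_id, rep$gene_id)]
  replicated <- pr < rep_alpha
  K <- sum(replicated)
  cutoffs <- sort(unique(pd), decreasing = TRUE)
  rows <- lapply(cutoffs, function(ct) {
    sel <- pd <= ct
    n <- sum(sel)
    if (n < min_n) return(NULL)
    k <- sum(sel & replicated)
    var_k <- n * (K / N) * (1 - K / N) * (N - n) / max(1, N - 1)
    sd_rate <- sqrt(var_k) / n
    data.frame(cutoff = ct, n = n, k = k, rate = k / n,
               k_over_K = if (K > 0) k / K else NA_real_,
               null_mean = K / N,
               band_lo = K / N - 2 * sd_rate,
               band_hi = K / N + 2 * sd_rate)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(cutoff = numeric(0), n = integer(0),
                                      k = integer(0), rate = numeric(0),
                                      k_over_K = numeric(0),
                                      null_mean = numeric(0),
                                      band_lo = numeric(0),
                                      band_hi = numeric(0))
  attr(out, "K") <- K
  attr(out, "N") <- N
  class(out) <- c("replication_curve", class(out))
  out
}

#' Mean tSNP counts in replicated vs non-replicated gene sets
#'
#' Checks whether replicated genes simply carry more tSNPs (more chances at
#' a small minimum p) than genes that failed to replicate.
#'
#' @param replicated,not_replicated disjoint character vectors of gene ids.
#' @param tsnp_counts named numeric vector of tSNP counts per gene.
#' @return Named vector with `replicated` and `not_replicated` mean counts
#'   (NA for an empty set).
#' @export
tsnp_count_balance <- function(replicated, not_replicated, tsnp_counts) {
  if (length(intersect(replicated, not_replicated)))
    stop("gene sets must be disjoint")
  get <- function(g) if (length(g)) mean(tsnp_counts[g]) else NA_real_
  c(replicated = get(replicated), not_replicated = get(not_replicated))
}
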