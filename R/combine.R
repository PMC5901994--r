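#' Fisher's combined probability test for two p-values
#'
#' X = -2 (ln p1 + ln p2) referred to a chi-square distribution with 4
#' degrees of freedom; equals the closed form p1 p2 (1 - ln(p1 p2)).
#' Vectorized and symmetric in its arguments.
#'
#' @param p1,p2 p-values in (0, 1].
#' @return Combined p-value(s) in (0, 1].
#' @export
fisher_combine <- function(p1, p2) {
  if (any(p1 <= 0 | p1 > 1) || any(p2 <= 0 | p2 > 1))
    stop("p-values must lie in (0, 1]")
  pchisq(-2 * (log(p1) + log(p2)), df = 4, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted p-values: q_(i) = min over j >= i of p_(j) * m / j,
#' capped at 1 and mapped back to the input order.
#'
#' @param pvals vector of p-values in (0, 1].
#' @return q-values, same order as the input.
#' @export
bh_qvalues <- function(pvals) {
  m <- length(pvals)
  if (m == 0L) return(numeric(0))
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must lie in (0, 1]")
  o <- order(pvals)
  q <- pmin(1, rev(cummin(rev(pvals[o] * m / seq_len(m)))))
  q[order(o)]
}

#' Call reQTLs at a per-trait FDR
#'
#' Combines the two arms' p-values per (gene, tSNP, trait) row with Fisher's
#' method, summarizes each gene within a trait (by default by its minimum
#' combined p across tSNPs), applies Benjamini-Hochberg within each trait,
#' and reports the rows passing the FDR threshold. The headline table keeps
#' one row per reQTL-gene-trait: the most significant tSNP; the full pair
#' table with per-pair combined p-values is returned alongside.
#'
#' @param results data.frame with columns `gene_id`, `trait`, `tsnp_id`,
#'   `p_ase`, `p_gene` (extra annotation columns such as `chrom`,
#'   `tsnp_pos`, `reqtl_id`, `alleles`, `reqtl_pos` are carried through).
#' @param fdr FDR threshold within trait (default 0.10).
#' @param per_gene if TRUE (default) BH runs over per-gene minimum combined
#'   p-values within trait; if FALSE, over all gene-tSNP pairs.
#' @return List with `headline` (significant rows, most significant tSNP per
#'   gene-trait) and `pairs` (all rows with `p_combined` and `q_value`).
#' @export
call_reqtls <- function(results, fdr = 0.10, per_gene = TRUE) {
  req <- c("gene_id", "trait", "tsnp_id", "p_ase", "p_gene")
  if (!all(req %in% names(results)))
    stop("results must have columns: ", paste(req, collapse = ", "))
  key <- paste(results$gene_id, results$tsnp_id, results$trait, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (gene_id, tsnp_id, trait) rows")
  if (fdr <= 0 || fdr >= 1) stop("fdr must lie in (0, 1)")
  res <- as.data.frame(results)
  res$p_combined <- fisher_combine(res$p_ase, res$p_gene)
  res$q_value <- NA_real_
  for (tr in unique(res$trait)) {
    ix <- which(res$trait == tr)
    if (per_gene) {
      pmin_gene <- tapply(res$p_combined[ix], res$gene_id[ix], min)
      qg <- bh_qvalues(as.numeric(pmin_gene))
      names(qg) <- names(pmin_gene)
      res$q_value[ix] <- qg[as.character(res$gene_id[ix])]
    } else {
      res$q_value[ix] <- bh_qvalues(res$p_combined[ix])
    }
  }
  sig <- res[res$q_value <= fdr, , drop = FALSE]
  if (nrow(sig)) {
    # most significant tSNP per gene-trait
    gk <- paste(sig$gene_id, sig$trait, sep = "\r")
    best <- unlist(lapply(split(seq_len(nrow(sig)), gk), function(ii)
      ii[which.min(sig$p_combined[ii])]))
    headline <- sig[sort(as.integer(best)), , drop = FALSE]
    headline <- headline[order(headline$trait, headline$q_value), , drop = FALSE]
  } else {
    headline <- sig
  }
  rownames(headline) <- NULL
  list(headline = headline, pairs = res)
}
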