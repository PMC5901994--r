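#' Allele-specific motif disruption delta score
#'
#' `delta = -log10(p_alt) - (-log10(p_ref))` from per-allele motif-scan
#' p-values. An allele with no reported hit (scanner threshold 0.01) is
#' substituted with p = 0.01, which makes the score conservative: the true
#' p for the missing allele is at least 0.01, so the magnitude of delta is
#' never overstated. Positive delta means stronger predicted binding on the
#' alternate allele.
#'
#' @param p_ref,p_alt per-allele scan p-values in (0, 1]; NA means no hit.
#' @param fallback substitute p-value for a missing allele (default 0.01).
#' @return Numeric delta score(s).
#' @export
delta_score <- function(p_ref, p_alt, fallback = 0.01) {
  if (any(is.na(p_ref) & is.na(p_alt)))
    stop("both alleles missing: nothing to score")
  chk <- c(p_ref[!is.na(p_ref)], p_alt[!is.na(p_alt)])
  if (any(chk <= 0 | chk > 1)) stop("p-values must lie in (0, 1]")
  p_ref[is.na(p_ref)] <- fallback
  p_alt[is.na(p_alt)] <- fallback
  -log10(p_alt) + log10(p_ref)
}

#' Score a table of per-allele motif hits
#'
#' Keeps variant-motif records where at least one allele passes the scan
#' reporting threshold (default 1e-4) and computes the delta score for each
#' with the 0.01 fallback for the other allele when missing.
#'
#' @param hits data.frame with columns `variant_id`, `motif_id`, `p_ref`,
#'   `p_alt` (NA = allele not reported by the scanner).
#' @param scan_threshold reporting threshold at least one allele must meet.
#' @param fallback substitute p for a missing allele.
#' @return The scored subset with an added `delta` column.
#' @export
score_motif_hits <- function(hits, scan_threshold = 1e-4, fallback = 0.01) {
  req <- c("variant_id", "motif_id", "p_ref", "p_alt")
  if (!all(req %in% names(hits)))
    stop("hits must have columns: ", paste(req, collapse = ", "))
  pr <- hits$p_ref; pa <- hits$p_alt
  best <- pmin(ifelse(is.na(pr), Inf, pr), ifelse(is.na(pa), Inf, pa))
  keep <- is.finite(best) & best <= scan_threshold
  out <- hits[keep, , drop = FALSE]
  if (nrow(out))
    out$delta <- delta_score(out$p_ref, out$p_alt, fallback = fallback)
  else out$delta <- numeric(0)
  rownames(out) <- NULL
  out
}
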