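#' Quality-control configuration for allelic count data
#'
#' Thresholds for the transcribed-SNP (tSNP) filters and the per-test
#' eligibility filters. Defaults are the values used throughout the package:
#' observations need at least 30 reads, a tSNP must be heterozygous in at
#' least 20 surviving samples and show no near mono-allelic sample
#' (|0.5 - alt/total| > 0.4), mapping-bias screening keeps tSNPs with
#' simulated coverage in [193, 202] and simulated allele ratio within 5% of
#' 0.5, and a GxE test requires >= 15 homozygous and >= 15 heterozygous
#' samples at the regulatory SNP with no dichotomous-environment cell below
#' 5 samples.
#'
#' @param min_reads_per_obs minimum total reads per sample x tSNP observation.
#' @param min_het_samples minimum surviving heterozygous samples per tSNP.
#' @param monoallelic_dev allelic-ratio deviation from 0.5 beyond which a
#'   sample counts as near mono-allelic.
#' @param sim_cov_min,sim_cov_max inclusive bounds on total simulated
#'   coverage in the mapping-bias screen.
#' @param sim_ratio_dev maximum |simulated allele ratio - 0.5| (exclusive).
#' @param min_hom minimum homozygous samples (both homozygote classes
#'   combined) at the candidate regulatory SNP.
#' @param min_het_eqtl minimum heterozygous samples at the regulatory SNP.
#' @param min_group minimum samples per heterozygosity x level cell for
#'   dichotomous environments.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_reads_per_obs = 30L, min_het_samples = 20L,
                      monoallelic_dev = 0.4, sim_cov_min = 193L,
                      sim_cov_max = 202L, sim_ratio_dev = 0.05,
                      min_hom = 15L, min_het_eqtl = 15L, min_group = 5L) {
  cfg <- list(min_reads_per_obs = as.integer(min_reads_per_obs),
              min_het_samples = as.integer(min_het_samples),
              monoallelic_dev = monoallelic_dev,
              sim_cov_min = as.integer(sim_cov_min),
              sim_cov_max = as.integer(sim_cov_max),
              sim_ratio_dev = sim_ratio_dev,
              min_hom = as.integer(min_hom),
              min_het_eqtl = as.integer(min_het_eqtl),
              min_group = as.integer(min_group))
  num <- unlist(cfg)
  if (any(num < 0)) stop("all qc_config thresholds must be >= 0")
  structure(cfg, class = "qc_config")
}

#' Screen tSNPs for reference-mapping bias
#'
#' Keeps tSNPs whose simulated-read statistics show no evidence of allelic
#' mapping bias: total simulated coverage within the configured window and
#' simulated allele ratio within `sim_ratio_dev` of 0.5 (strict inequality;
#' a deviation of exactly 5% is removed).
#'
#' @param stats data.frame with columns `tsnp_id`, `sim_total`,
#'   `sim_allele_ratio` (one row per tSNP).
#' @param cfg a [qc_config()].
#' @return Character vector of retained tSNP ids.
#' @export
mapping_bias_filter <- function(stats, cfg = qc_config()) {
  req <- c("tsnp_id", "sim_total", "sim_allele_ratio")
  if (!all(req %in% names(stats)))
    stop("stats must have columns: ", paste(req, collapse = ", "))
  dup <- unique(stats$tsnp_id[duplicated(stats$tsnp_id)])
  if (length(dup))
    stop("duplicate tsnp_id in mapping-bias stats: ",
         paste(head(dup, 5), collapse = ", "))
  if (any(stats$sim_total < 0) ||
      any(stats$sim_allele_ratio < 0 | stats$sim_allele_ratio > 1))
    stop("sim_total must be >= 0 and sim_allele_ratio in [0, 1]")
  keep <- stats$sim_total >= cfg$sim_cov_min &
    stats$sim_total <= cfg$sim_cov_max &
    abs(stats$sim_allele_ratio - 0.5) < cfg$sim_ratio_dev
  as.character(stats$tsnp_id[keep])
}

#' Filter allelic count observations and tSNPs
#'
#' Applies, in order: (1) drop observations with fewer than
#' `min_reads_per_obs` total reads; (2) drop tSNPs heterozygous in fewer
#' than `min_het_samples` surviving samples; (3) drop tSNPs where any
#' surviving sample shows near mono-allelic expression,
#' |0.5 - alt/total| > `monoallelic_dev`. Only heterozygous observations are
#' informative for ASE, so non-heterozygous records are removed up front.
#'
#' @param records data.frame of allelic counts with columns `sample_id`,
#'   `tsnp_id`, `ref_count`, `alt_count` (and optionally `chrom`, `pos`).
#' @param het_map data.frame with columns `sample_id`, `tsnp_id`, `het`
#'   (logical: sample heterozygous at the tSNP); must cover every record.
#' @param cfg a [qc_config()].
#' @return List with `records` (filtered data.frame), `tsnps` (retained tSNP
#'   ids) and `log` (named removal counts per step).
#' @export
count_filters <- function(records, het_map, cfg = qc_config()) {
  req <- c("sample_id", "tsnp_id", "ref_count", "alt_count")
  if (!all(req %in% names(records)))
    stop("records must have columns: ", paste(req, collapse = ", "))
  if (any(records$ref_count < 0) || any(records$alt_count < 0))
    stop("negative read counts")
  key <- function(s, t) paste(s, t, sep = "\r")
  if (anyDuplicated(key(records$sample_id, records$tsnp_id)))
    stop("duplicated (sample_id, tsnp_id) records")
  hk <- key(het_map$sample_id, het_map$tsnp_id)
  idx <- match(key(records$sample_id, records$tsnp_id), hk)
  if (anyNA(idx))
    stop("het_map does not cover every record")
  het <- as.logical(het_map$het[idx])

  log <- c(input = nrow(records))
  rec <- records[het, , drop = FALSE]
  log["non_het_removed"] <- log[["input"]] - nrow(rec)

  total <- rec$ref_count + rec$alt_count
  keep1 <- total >= cfg$min_reads_per_obs
  log["low_coverage_removed"] <- sum(!keep1)
  rec <- rec[keep1, , drop = FALSE]

  nhet <- table(rec$tsnp_id)
  ok2 <- names(nhet)[nhet >= cfg$min_het_samples]
  keep2 <- rec$tsnp_id %in% ok2
  log["few_het_tsnps_removed"] <-
    length(unique(rec$tsnp_id)) - length(ok2)
  rec <- rec[keep2, , drop = FALSE]

  tot <- rec$ref_count + rec$alt_count
  dev <- abs(0.5 - rec$alt_count / tot)
  bad3 <- unique(rec$tsnp_id[dev > cfg$monoallelic_dev])
  log["monoallelic_tsnps_removed"] <- length(bad3)
  rec <- rec[!(rec$tsnp_id %in% bad3), , drop = FALSE]

  log["retained_records"] <- nrow(rec)
  log["retained_tsnps"] <- length(unique(rec$tsnp_id))
  list(records = rec, tsnps = unique(as.character(rec$tsnp_id)), log = log)
}

#' Decide whether a regulatory-SNP x environment pair is testable
#'
#' A candidate reQTL-trait pair is eligible when, after removing samples
#' with a missing environment value, there are at least `min_hom` homozygous
#' samples (both homozygote classes combined; the ASE model only
#' distinguishes heterozygous from homozygous at the regulatory SNP) and at
#' least `min_het_eqtl` heterozygous samples, and, for dichotomous
#' environments, every heterozygosity-class x environment-level cell holds
#' at least `min_group` samples.
#'
#' @param geno_class per-sample genotype class: `"hom-ref"`, `"het"`,
#'   `"hom-alt"`, or dosages 0/1/2.
#' @param env per-sample environment values (NA allowed).
#' @param kind `"continuous"` or `"dichotomous"`.
#' @param cfg a [qc_config()].
#' @return List with `eligible` (logical) and `reason` (character, `"ok"`
#'   when eligible).
#' @export
test_eligibility <- function(geno_class, env, kind = c("continuous", "dichotomous"),
                             cfg = qc_config()) {
  kind <- match.arg(kind)
  if (length(geno_class) != length(env))
    stop("geno_class and env must be aligned")
  if (all(is.na(env))) stop("environment has zero non-missing values")
  if (is.numeric(geno_class)) {
    g <- round(geno_class)
    if (any(!g %in% c(0, 1, 2), na.rm = TRUE)) stop("dosages must round to 0/1/2")
    geno_class <- c("hom-ref", "het", "hom-alt")[g + 1L]
  }
  if (!all(geno_class %in% c("hom-ref", "het", "hom-alt"), na.rm = TRUE))
    stop("genotype classes must be hom-ref/het/hom-alt")
  ok <- !is.na(env) & !is.na(geno_class)
  gc <- geno_class[ok]; ev <- env[ok]
  n_het <- sum(gc == "het")
  n_hom <- sum(gc != "het")
  if (n_hom < cfg$min_hom)
    return(list(eligible = FALSE, reason = sprintf("hom<%d", cfg$min_hom)))
  if (n_het < cfg$min_het_eqtl)
    return(list(eligible = FALSE, reason = sprintf("het<%d", cfg$min_het_eqtl)))
  if (kind == "dichotomous") {
    if (!all(ev %in% c(0, 1))) stop("dichotomous environment must be 0/1")
    cells <- table(factor(gc == "het", levels = c(FALSE, TRUE)),
                   factor(ev, levels = c(0, 1)))
    if (any(cells < cfg$min_group))
      return(list(eligible = FALSE,
                  reason = sprintf("group<%d", cfg$min_group)))
  }
  list(eligible = TRUE, reason = "ok")
}
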