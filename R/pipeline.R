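#' Run the end-to-end reQTL discovery pipeline
#'
#' QC of allelic counts, trait preparation, empirical-Bayes prior learning,
#' the ASE and gene-level GxE arms for every eligible (gene, trait) unit,
#' Fisher combination and per-trait FDR control, and tab-separated reports.
#' Units that fail (ineligibility, model errors) are logged with a reason
#' and the run continues. Re-running with identical inputs reproduces the
#' outputs exactly: the pipeline itself draws no random numbers.
#'
#' @param config a list or a path to a JSON file with elements:
#'   `counts`, `genotypes` (VCF), `traits`, `covariates`, `tsnp_map`,
#'   `candidates` (file paths); `trait_kinds` (named list,
#'   "continuous"/"dichotomous"); optional `mapping_bias` (TSV of simulated
#'   coverage stats), `qc` (threshold overrides for [qc_config()]),
#'   `fdr` (default 0.10), `nodes` (quadrature nodes, default 20),
#'   `arms` (subset of c("ase","gene")), `out_dir` (when set, reports are
#'   written there).
#' @return List: `results` ([call_reqtls()] output or the raw rows when only
#'   one arm ran), `rows` (per gene-tSNP-trait fits), `qc_log`, `prior`,
#'   `run_log` (skipped/failed units with reasons).
#' @export
run_discovery <- function(config) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  for (f in c("counts", "genotypes", "traits", "covariates", "tsnp_map",
              "candidates")) {
    if (is.null(config[[f]])) stop("config is missing '", f, "'")
    if (!file.exists(config[[f]])) stop("input file not found: ", config[[f]])
  }
  fdr <- config$fdr %||% 0.10
  if (fdr <= 0 || fdr >= 1) stop("fdr must lie in (0, 1)")
  nodes <- config$nodes %||% 20L
  arms <- config$arms %||% c("ase", "gene")
  cfg_qc <- do.call(qc_config, as.list(config$qc %||% list()))

  counts <- read_ase_counts(config$counts)
  traits <- read_traits(config$traits)
  covs <- read_traits(config$covariates)
  geno <- read_genotypes_vcf(config$genotypes)
  tsnp_map <- data.table::fread(config$tsnp_map, sep = "\t",
                                data.table = FALSE)
  candidates <- data.table::fread(config$candidates, sep = "\t",
                                  data.table = FALSE)
  kinds <- unlist(config$trait_kinds)
  if (is.null(kinds)) stop("config needs trait_kinds")
  expr_tab <- NULL
  if ("gene" %in% arms) {
    if (is.null(config$expression)) stop("config is missing 'expression'")
    expr_tab <- data.table::fread(config$expression, sep = "\t",
                                  data.table = FALSE)
  }
  run_log <- list(units = list())
  note <- function(unit, status, reason) {
    run_log$units[[length(run_log$units) + 1L]] <<-
      list(unit = unit, status = status, reason = reason)
  }

  ## --- QC -------------------------------------------------------------
  if (!is.null(config$mapping_bias)) {
    mb <- data.table::fread(config$mapping_bias, sep = "\t",
                            data.table = FALSE)
    keep <- mapping_bias_filter(mb, cfg_qc)
    n0 <- nrow(counts)
    counts <- counts[counts$tsnp_id %in% keep, , drop = FALSE]
    note("mapping_bias", "filter",
         sprintf("%d of %d records retained", nrow(counts), n0))
  }
  samples <- rownames(traits)
  known <- counts$tsnp_id %in% rownames(geno) &
    counts$sample_id %in% colnames(geno)
  counts <- counts[known, , drop = FALSE]
  dos <- geno[cbind(match(counts$tsnp_id, rownames(geno)),
                    match(counts$sample_id, colnames(geno)))]
  het_map <- data.frame(sample_id = counts$sample_id,
                        tsnp_id = counts$tsnp_id,
                        het = round(dos) == 1)
  het_map$het[is.na(het_map$het)] <- FALSE
  qc <- count_filters(counts, het_map, cfg_qc)

  ## --- phenotypes ------------------------------------------------------
  if (!all(c("age", "sex") %in% names(traits)))
    stop("trait table must include 'age' and 'sex' columns for residualization")
  proc <- prepare_traits(traits[, names(kinds), drop = FALSE], kinds,
                         age = traits$age, sex = traits$sex)

  ## --- empirical-Bayes prior -------------------------------------------
  prior <- ig_prior()
  if ("ase" %in% arms) {
    tsnps <- qc$tsnps
    vhat <- vapply(tsnps, function(ts) {
      rr <- qc$records[qc$records$tsnp_id == ts, ]
      ase_variance_ml(rr$alt_count, rr$alt_count + rr$ref_count,
                      nodes = nodes)[["v"]]
    }, numeric(1))
    if (sum(vhat > 0) >= 50L) {
      prior <- estimate_ig_prior(vhat)
      note("prior", "estimated", sprintf("a=%.3g b=%.3g", prior$a, prior$b))
    } else {
      note("prior", "default",
           sprintf("only %d tSNP variance estimates (<50); keeping IG(%.3g, %.3g)",
                   sum(vhat > 0), prior$a, prior$b))
    }
  }

  pc_cols <- intersect(c("pc1", "pc2"), names(covs))
  peer_cols <- intersect(c("peer1", "peer2"), names(covs))

  ## --- per (trait, gene) units -----------------------------------------
  rows <- list()
  for (tr in names(kinds)) {
    e_all <- setNames(proc[[tr]], samples)
    for (ci in seq_len(nrow(candidates))) {
      gene <- candidates$gene_id[ci]
      reqtl <- candidates$reqtl_id[ci]
      unit <- paste(gene, tr, sep = ":")
      if (!reqtl %in% rownames(geno)) {
        note(unit, "skipped", "reQTL not in genotypes"); next
      }
      g_all <- setNames(round(geno[reqtl, samples]), samples)
      elig <- tryCatch(
        test_eligibility(g_all, e_all, kind = kinds[[tr]], cfg = cfg_qc),
        error = function(e) list(eligible = FALSE, reason = conditionMessage(e)))
      if (!elig$eligible) { note(unit, "ineligible", elig$reason); next }

      p_gene <- NA_real_; gene_beta <- NA_real_
      if ("gene" %in% arms) {
        gf <- tryCatch({
          expr <- expression_row(expr_tab, gene, samples)
          Z <- build_gene_covariates(covs, traits, samples, tr,
                                     pc_cols, peer_cols)
          okm <- complete.cases(cbind(expr, Z, e_all, g_all))
          fit_gene_interaction(inverse_normal_transform(expr[okm]),
                               Z[okm, , drop = FALSE],
                               e_all[okm], g_all[okm])
        }, error = function(e) e)
        if (inherits(gf, "error")) {
          note(unit, "gene_arm_failed", conditionMessage(gf))
        } else {
          p_gene <- gf$p_gene; gene_beta <- gf$beta
        }
      }

      gene_tsnps <- intersect(tsnp_map$tsnp_id[tsnp_map$gene_id == gene],
                              qc$tsnps)
      if ("ase" %in% arms && length(gene_tsnps) == 0L) {
        note(unit, "skipped", "no surviving tSNPs"); next
      }
      if (!"ase" %in% arms) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gene, trait = tr, reqtl_id = reqtl, tsnp_id = NA,
          p_ase = NA_real_, p_gene = p_gene, beta_seh = NA_real_,
          beta_gene = gene_beta, v_s = NA_real_)
        next
      }
      for (ts in gene_tsnps) {
        rr <- qc$records[qc$records$tsnp_id == ts, ]
        keep <- !is.na(e_all[rr$sample_id]) & !is.na(g_all[rr$sample_id])
        rr <- rr[keep, , drop = FALSE]
        af <- tryCatch({
          X <- if (length(pc_cols))
            as.matrix(covs[rr$sample_id, pc_cols, drop = FALSE]) else NULL
          des <- ase_design(n = rr$ref_count + rr$alt_count,
                            y = rr$alt_count,
                            e = e_all[rr$sample_id],
                            h = as.numeric(g_all[rr$sample_id] == 1),
                            covariates = X)
          ase_gxe_test(des, prior, nodes = nodes)
        }, error = function(e) e)
        if (inherits(af, "error")) {
          note(paste(unit, ts, sep = ":"), "ase_arm_failed",
               conditionMessage(af))
          next
        }
        if (!af$full$converged) {
          note(paste(unit, ts, sep = ":"), "ase_arm_excluded",
               "optimizer did not converge")
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gene, trait = tr, reqtl_id = reqtl, tsnp_id = ts,
          p_ase = af$p_value, p_gene = p_gene,
          beta_seh = unname(af$full$coefficients["beta_seh"]),
          beta_gene = gene_beta, v_s = af$full$v_s)
      }
    }
  }
  rows <- if (length(rows)) do.call(rbind, rows) else NULL

  results <- NULL
  if (!is.null(rows) && all(c("ase", "gene") %in% arms)) {
    ok <- !is.na(rows$p_ase) & !is.na(rows$p_gene)
    if (any(ok)) results <- call_reqtls(rows[ok, , drop = FALSE], fdr = fdr)
  }

  out <- list(results = results, rows = rows, qc_log = qc$log,
              prior = prior, run_log = run_log)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$out_dir, f)
    if (!is.null(results)) {
      data.table::fwrite(results$headline, p("headline.tsv"), sep = "\t")
      data.table::fwrite(results$pairs, p("pairs.tsv"), sep = "\t")
    }
    if (!is.null(rows)) data.table::fwrite(rows, p("fits.tsv"), sep = "\t")
    write_qc_report(qc$log, p("qc_report.json"))
    jsonlite::write_json(run_log, p("run_log.json"), auto_unbox = TRUE)
  }
  out
}

# expression matrix access: the file has gene_id in the first column and one
# column per sample
expression_row <- function(expr_tab, gene, samples) {
  i <- match(gene, expr_tab[[1]])
  if (is.na(i)) stop("gene not in expression matrix: ", gene)
  v <- as.numeric(expr_tab[i, samples])
  names(v) <- samples
  v
}

build_gene_covariates <- function(covs, traits, samples, trait_name,
                                  pc_cols, peer_cols) {
  Z <- matrix(1, length(samples), 1, dimnames = list(samples, "intercept"))
  if ("batch" %in% names(covs)) {
    b <- factor(covs[samples, "batch"])
    if (nlevels(b) > 1L) {
      Zb <- stats::model.matrix(~b)[, -1, drop = FALSE]
      colnames(Zb) <- paste0("batch", levels(b)[-1])
      Z <- cbind(Z, Zb)
    }
  }
  for (cc in c(pc_cols, peer_cols))
    Z <- cbind(Z, setNames(data.frame(covs[samples, cc]), cc))
  if (trait_name != "age") Z <- cbind(Z, age = traits[samples, "age"])
  if (trait_name != "sex") Z <- cbind(Z, sex = traits[samples, "sex"])
  as.matrix(Z)
}
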