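## Readers and writers for the tab-separated interchange formats. All tables
## are TSV with a header row; coordinates are 1-based inclusive; alleles are
## reported ref/alt.

#' Read an allelic count table
#'
#' Expected columns: sample(_id), tsnp(_id), chrom, pos, ref_count,
#' alt_count.
#'
#' @param path TSV file.
#' @return data.frame with canonical column names.
#' @export
read_ase_counts <- function(path) {
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  nm <- names(dt)
  nm[nm == "sample"] <- "sample_id"
  nm[nm == "tsnp"] <- "tsnp_id"
  names(dt) <- nm
  req <- c("sample_id", "tsnp_id", "ref_count", "alt_count")
  if (!all(req %in% nm))
    stop("count table must have columns: ", paste(req, collapse = ", "))
  dt
}

#' Read a sample-by-trait table
#'
#' First column holds sample ids; remaining columns are traits (missing
#' values allowed).
#'
#' @param path TSV file.
#' @return data.frame with rownames set to sample ids.
#' @export
read_traits <- function(path) {
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  rownames(dt) <- dt[[1]]
  dt[, -1, drop = FALSE]
}

#' Read genotype dosages from a VCF
#'
#' Uses VariantAnnotation to parse the file and converts GT calls (or DS
#' dosages when GT is absent) into a variants x samples dosage matrix.
#'
#' @param path VCF file (plain or bgzipped).
#' @return Numeric matrix, rownames = variant ids, colnames = sample ids;
#'   entries 0/1/2 (dosages possibly fractional when read from DS).
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_genotypes_vcf requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  gen <- VariantAnnotation::geno(vcf)
  if ("GT" %in% names(gen)) {
    gt <- gen$GT
    dos <- apply(gt, c(1, 2), function(x) {
      if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_real_)
      sum(as.numeric(strsplit(x, "[/|]")[[1]]))
    })
  } else if ("DS" %in% names(gen)) {
    dos <- gen$DS
    mode(dos) <- "numeric"
  } else stop("VCF has neither GT nor DS genotype fields")
  rn <- rownames(dos)
  dos <- matrix(as.numeric(dos), nrow = nrow(dos),
                dimnames = list(rn, colnames(gen[[1]])))
  dos
}

#' Write a study's genotypes as a minimal VCF
#'
#' Emits a VCFv4.2 file with GT calls for the regulatory SNP and tSNP of
#' each simulated locus pair (unphased dosage coding; phase lives in the
#' simulation truth, not the VCF).
#'
#' @param geno a `sim_genotypes` object.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_genotypes_vcf <- function(geno, path) {
  n <- length(geno$sample_id); L <- ncol(geno$g_reqtl)
  gt_of <- function(d) c("0/0", "0/1", "1/1")[d + 1L]
  rows <- character(0)
  for (j in seq_len(L)) {
    rows <- c(rows,
      paste(c("chr1", 2000L + j, sprintf("rq%04d", j), "A", "G", ".",
              "PASS", ".", "GT", gt_of(geno$g_reqtl[, j])), collapse = "\t"),
      paste(c("chr1", 1000L + j, sprintf("ts%04d", j), "C", "T", ".",
              "PASS", ".", "GT", gt_of(geno$g_tsnp[, j])), collapse = "\t"))
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr1>",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", geno$sample_id), collapse = "\t"))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write a simulated study to a directory of plain-text files
#'
#' Produces counts.tsv, expression.tsv, traits.tsv, covariates.tsv,
#' genotypes.vcf, tsnp_map.tsv, candidates.tsv and truth.json - the inputs
#' [run_discovery()] consumes.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @param trait_name name for the simulated environment trait.
#' @return Invisibly, a named list of the file paths.
#' @export
write_study <- function(study, dir, trait_name = "env1") {
  stopifnot(inherits(study, "sim_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  data.table::fwrite(study$ase$records, p("counts.tsv"), sep = "\t")
  expr <- data.frame(gene_id = rownames(study$expression$expr),
                     study$expression$expr, check.names = FALSE)
  data.table::fwrite(expr, p("expression.tsv"), sep = "\t")
  geno <- study$genotypes
  set.seed(study$config$seed + 4L)
  n <- study$config$n_samples
  traits <- data.frame(sample_id = geno$sample_id,
                       trait = study$env,
                       age = round(runif(n, 40, 75)),
                       sex = rbinom(n, 1, 0.5))
  names(traits)[2] <- trait_name
  data.table::fwrite(traits, p("traits.tsv"), sep = "\t")
  data.table::fwrite(study$expression$covariates, p("covariates.tsv"),
                     sep = "\t")
  write_genotypes_vcf(geno, p("genotypes.vcf"))
  L <- study$config$n_tsnps
  data.table::fwrite(data.frame(tsnp_id = sprintf("ts%04d", seq_len(L)),
                                gene_id = sprintf("gene%04d", seq_len(L))),
                     p("tsnp_map.tsv"), sep = "\t")
  data.table::fwrite(data.frame(gene_id = sprintf("gene%04d", seq_len(L)),
                                reqtl_id = sprintf("rq%04d", seq_len(L))),
                     p("candidates.tsv"), sep = "\t")
  truth <- list(effects = study$config$effects,
                v_s = vapply(study$ase$truth$per_tsnp,
                             function(t) t$v_s %||% NA_real_, numeric(1)),
                seed = study$config$seed)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(counts = p("counts.tsv"), expression = p("expression.tsv"),
                 traits = p("traits.tsv"), covariates = p("covariates.tsv"),
                 genotypes = p("genotypes.vcf"),
                 tsnp_map = p("tsnp_map.tsv"),
                 candidates = p("candidates.tsv"),
                 truth = p("truth.json")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a QC report as JSON
#'
#' @param log named vector of per-step counts (from [count_filters()]).
#' @param path output JSON file.
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(log, path) {
  jsonlite::write_json(as.list(log), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
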