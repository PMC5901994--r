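## Synthetic data with recorded truth. The generator emulates the stated
## world of the analysis: HWE genotypes at a regulatory SNP and a transcribed
## SNP with configurable phase correlation, a continuous (standard normal,
## i.e. post-inverse-normal scale) or dichotomous Bernoulli(0.5) environment,
## negative-binomial read depths, allelic counts from the binomial-logistic
## random-effect model with per-tSNP variances drawn from the inverse-gamma
## prior, and gene expression from the linear interaction model with batch /
## PC / PEER-like confounders.

#' Simulation configuration
#'
#' Defaults describe the cohort the analysis was designed for: 267 samples,
#' MAF 0.3 at both loci, sequencing depth around 60 reads per observation
#' (negative binomial, dispersion 0.2), random-effect variances from
#' IG(1.80, 0.0024), and all GxE effects zero (a null world) unless set.
#'
#' @param n_samples number of samples.
#' @param n_tsnps number of (regulatory SNP, tSNP) locus pairs; each pair is
#'   treated as one gene.
#' @param maf_reqtl,maf_tsnp alternate-allele frequencies in (0, 1).
#' @param ld_r2 squared haplotype correlation between the two loci (positive
#'   phase); 1 with equal MAFs makes the loci identical.
#' @param env_kind `"continuous"` or `"dichotomous"`.
#' @param depth_mean,depth_dispersion negative-binomial read-depth model
#'   (mean >= 30 keeps records above the coverage filter).
#' @param prior [ig_prior()] from which per-tSNP variances v_s are drawn.
#' @param v_s optional fixed random-effect variance overriding the prior
#'   draw (useful for recovery tests).
#' @param effects named list of generating effects: `gamma_se`, `gamma_sh`,
#'   `beta_seh`, `mu_s` (ASE arm), `gamma_je`, `gamma_jg`, `beta_j` (gene
#'   arm). Unnamed entries default to 0.
#' @param confounders list: `n_batch`, `batch_sd`, `pc_sd`, `peer_sd` -
#'   number of sequencing batches and effect scales of batch, genotype-PC
#'   and PEER-like covariates in the expression model.
#' @param noise_sd residual standard deviation of the expression model.
#' @param seed integer seed; mandatory, every draw is reproducible from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_samples = 267L, n_tsnps = 1L,
                       maf_reqtl = 0.3, maf_tsnp = 0.3, ld_r2 = 0.8,
                       env_kind = c("continuous", "dichotomous"),
                       depth_mean = 60, depth_dispersion = 0.2,
                       prior = ig_prior(1.80, 0.0024), v_s = NULL,
                       effects = list(),
                       confounders = list(n_batch = 2L, batch_sd = 0.5,
                                          pc_sd = 0.5, peer_sd = 0.5),
                       noise_sd = 1, seed) {
  if (missing(seed)) stop("seed is mandatory")
  env_kind <- match.arg(env_kind)
  if (maf_reqtl <= 0 || maf_reqtl >= 1 || maf_tsnp <= 0 || maf_tsnp >= 1)
    stop("allele frequencies must lie in (0, 1)")
  if (ld_r2 < 0 || ld_r2 > 1) stop("ld_r2 must lie in [0, 1]")
  eff0 <- list(gamma_se = 0, gamma_sh = 0, beta_seh = 0, mu_s = 0,
               gamma_je = 0, gamma_jg = 0, beta_j = 0)
  effects <- modifyList(eff0, effects)
  conf0 <- list(n_batch = 2L, batch_sd = 0.5, pc_sd = 0.5, peer_sd = 0.5)
  confounders <- modifyList(conf0, confounders)
  structure(list(n_samples = as.integer(n_samples),
                 n_tsnps = as.integer(n_tsnps),
                 maf_reqtl = maf_reqtl, maf_tsnp = maf_tsnp, ld_r2 = ld_r2,
                 env_kind = env_kind, depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 prior = prior, v_s = v_s, effects = effects,
                 confounders = confounders, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate phased genotypes at (regulatory SNP, tSNP) pairs
#'
#' Haplotypes are drawn from the two-locus haplotype distribution with the
#' configured allele frequencies and positive-phase disequilibrium
#' D = sqrt(ld_r2 * p1 q1 p2 q2), so genotypes at each locus are in HWE and
#' the haplotype correlation is approximately sqrt(ld_r2).
#'
#' @param cfg a [sim_config()].
#' @return List of class `sim_genotypes`: `g_reqtl`, `g_tsnp` (samples x
#'   locus-pairs dosage matrices), `het_reqtl`, `het_tsnp` (logical),
#'   `phase` (+1 when the alternate alleles share a haplotype, -1 when they
#'   oppose, NA unless double heterozygous), and `sample_id`.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  p1 <- cfg$maf_reqtl; p2 <- cfg$maf_tsnp
  q1 <- 1 - p1; q2 <- 1 - p2
  D <- sqrt(cfg$ld_r2 * p1 * q1 * p2 * q2)
  f <- c(`11` = p1 * p2 + D, `10` = p1 * q2 - D,
         `01` = q1 * p2 - D, `00` = q1 * q2 + D)
  if (any(f < -1e-12)) {
    dmax <- min(p1 * q2, q1 * p2)
    stop(sprintf(
      "ld_r2 = %.3f infeasible for MAFs (%.2f, %.2f); maximum feasible ld_r2 = %.4f",
      cfg$ld_r2, p1, p2, dmax^2 / (p1 * q1 * p2 * q2)))
  }
  f <- pmax(f, 0); f <- f / sum(f)
  n <- cfg$n_samples; L <- cfg$n_tsnps
  draw_hap <- function(k) {
    idx <- sample.int(4L, k, replace = TRUE, prob = f)
    # haplotype = (reqtl allele, tsnp allele)
    cbind(a1 = c(1, 1, 0, 0)[idx], a2 = c(1, 0, 1, 0)[idx])
  }
  g_reqtl <- matrix(0L, n, L); g_tsnp <- matrix(0L, n, L)
  phase <- matrix(NA_real_, n, L)
  hap_store <- vector("list", L)
  for (j in seq_len(L)) {
    h1 <- draw_hap(n); h2 <- draw_hap(n)
    g_reqtl[, j] <- h1[, 1] + h2[, 1]
    g_tsnp[, j] <- h1[, 2] + h2[, 2]
    dh <- g_reqtl[, j] == 1L & g_tsnp[, j] == 1L
    # +1 when the haplotype carrying the alternate regulatory allele also
    # carries the alternate tSNP allele
    ph <- ifelse(h1[, 1] == 1L, ifelse(h1[, 2] == 1L, 1, -1),
                 ifelse(h2[, 2] == 1L, 1, -1))
    phase[dh, j] <- ph[dh]
    hap_store[[j]] <- list(h1 = h1, h2 = h2)
  }
  structure(list(g_reqtl = g_reqtl, g_tsnp = g_tsnp,
                 het_reqtl = g_reqtl == 1L, het_tsnp = g_tsnp == 1L,
                 phase = phase, haplotypes = hap_store,
                 sample_id = sprintf("S%03d", seq_len(n))),
            class = "sim_genotypes")
}

#' Simulate an environment trait
#'
#' Continuous environments are standard normal (the scale a trait has after
#' inverse-normal transformation); dichotomous environments are
#' Bernoulli(0.5).
#'
#' @param n number of samples.
#' @param kind `"continuous"` or `"dichotomous"`.
#' @return Numeric vector of length `n`.
#' @export
simulate_env <- function(n, kind = c("continuous", "dichotomous")) {
  kind <- match.arg(kind)
  if (kind == "continuous") rnorm(n) else rbinom(n, 1, 0.5)
}

#' Simulate allelic count records from the ASE model
#'
#' For each sample heterozygous at a tSNP: depth n from a negative binomial,
#' latent random effect eps ~ N(0, v_s) with v_s drawn once per tSNP from
#' the inverse-gamma prior (or fixed via `cfg$v_s`), and alternate count
#' y ~ Binomial(n, sigma(d * eta + eps)) where
#' eta = e gamma_se + h gamma_sh + e h beta_seh + mu_s and d is the phase
#' sign (+1/-1) for double heterozygotes and a random sign otherwise (allele
#' labels at the tSNP carry no information about the regulatory allele when
#' the sample is homozygous there).
#'
#' @param geno a [simulate_genotypes()] result.
#' @param env per-sample environment vector.
#' @param cfg the [sim_config()].
#' @return List: `records` (data.frame sample_id, tsnp_id, chrom, pos,
#'   ref_count, alt_count), `truth` (per-tSNP v_s, per-observation eps and
#'   sign, effects).
#' @export
simulate_ase_counts <- function(geno, env, cfg) {
  stopifnot(inherits(geno, "sim_genotypes"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  ef <- cfg$effects
  L <- ncol(geno$g_tsnp)
  recs <- vector("list", L)
  truth <- vector("list", L)
  for (j in seq_len(L)) {
    het <- which(geno$het_tsnp[, j])
    v_s <- if (is.null(cfg$v_s)) 1 / rgamma(1, cfg$prior$a, rate = cfg$prior$b)
           else cfg$v_s
    if (!length(het)) { truth[[j]] <- list(v_s = v_s); next }
    nn <- rnbinom(length(het), mu = cfg$depth_mean,
                  size = 1 / cfg$depth_dispersion)
    e <- env[het]
    h <- as.numeric(geno$het_reqtl[het, j])
    eta <- e * ef$gamma_se + h * ef$gamma_sh + e * h * ef$beta_seh + ef$mu_s
    d <- geno$phase[het, j]
    d[is.na(d)] <- sample(c(-1, 1), sum(is.na(d)), replace = TRUE)
    eps <- rnorm(length(het), 0, sqrt(v_s))
    y <- rbinom(length(het), nn, plogis(d * eta + eps))
    recs[[j]] <- data.frame(sample_id = geno$sample_id[het],
                            tsnp_id = sprintf("ts%04d", j),
                            chrom = "chr1", pos = 1000L + j,
                            ref_count = nn - y, alt_count = y,
                            stringsAsFactors = FALSE)
    truth[[j]] <- list(v_s = v_s, eps = eps, sign = d, eta = eta,
                       samples = geno$sample_id[het])
  }
  list(records = do.call(rbind, recs),
       truth = list(per_tsnp = truth, effects = ef))
}

#' Simulate gene expression from the linear interaction model
#'
#' y_j = Z alpha_j + e gamma_je + g gamma_jg + (g*e) beta_j + noise, with Z
#' containing an intercept, sequencing-batch dummies, two genotype-PC-like
#' and two PEER-like standard-normal covariates whose effects are drawn at
#' the configured scales.
#'
#' @param geno a [simulate_genotypes()] result; `g_reqtl` supplies g.
#' @param env per-sample environment vector.
#' @param cfg the [sim_config()].
#' @return List: `expr` (genes x samples matrix), `Z` (shared covariate
#'   matrix including batch dummies), `covariates` (data.frame of batch,
#'   PCs, PEER factors), `truth` (alpha, effects, noise_sd).
#' @export
simulate_expression <- function(geno, env, cfg) {
  stopifnot(inherits(geno, "sim_genotypes"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  n <- cfg$n_samples; L <- ncol(geno$g_reqtl)
  cf <- cfg$confounders; ef <- cfg$effects
  batch <- sample.int(cf$n_batch, n, replace = TRUE)
  pcs <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("pc1", "pc2")))
  peer <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("peer1", "peer2")))
  Zb <- if (cf$n_batch > 1L)
    stats::model.matrix(~ factor(batch, levels = seq_len(cf$n_batch)))[, -1, drop = FALSE]
  else matrix(0, n, 0)
  if (ncol(Zb)) colnames(Zb) <- paste0("batch", 2:cf$n_batch)
  Z <- cbind(intercept = 1, Zb, pcs, peer)
  expr <- matrix(NA_real_, L, n,
                 dimnames = list(sprintf("gene%04d", seq_len(L)),
                                 geno$sample_id))
  alpha <- matrix(NA_real_, L, ncol(Z), dimnames = list(NULL, colnames(Z)))
  for (j in seq_len(L)) {
    a <- c(0, rnorm(ncol(Zb), 0, cf$batch_sd), rnorm(2, 0, cf$pc_sd),
           rnorm(2, 0, cf$peer_sd))
    g <- geno$g_reqtl[, j]
    expr[j, ] <- drop(Z %*% a) + env * ef$gamma_je + g * ef$gamma_jg +
      g * env * ef$beta_j + rnorm(n, 0, cfg$noise_sd)
    alpha[j, ] <- a
  }
  list(expr = expr, Z = Z,
       covariates = data.frame(sample_id = geno$sample_id, batch = batch,
                               pcs, peer, stringsAsFactors = FALSE),
       truth = list(alpha = alpha, effects = ef, noise_sd = cfg$noise_sd))
}

#' Simulate a complete study with recorded truth
#'
#' Genotypes, one environment trait, allelic counts and expression for
#' `n_tsnps` gene/locus pairs, bundled with every generating parameter.
#'
#' @param cfg a [sim_config()].
#' @return List of class `sim_study`: `genotypes`, `env`, `ase` (records +
#'   truth), `expression`, `config`.
#' @export
simulate_study <- function(cfg) {
  geno <- simulate_genotypes(cfg)
  set.seed(cfg$seed + 3L)
  env <- simulate_env(cfg$n_samples, cfg$env_kind)
  ase <- simulate_ase_counts(geno, env, cfg)
  expr <- simulate_expression(geno, env, cfg)
  structure(list(genotypes = geno, env = env, ase = ase,
                 expression = expr, config = cfg),
            class = "sim_study")
}

#' Simulate one ready-made ASE design
#'
#' Directly builds an [ase_design()] with a fixed number of double
#' heterozygous (h = 1) and regulatory-homozygous (h = 0) observations,
#' bypassing the genotype layer; the per-observation generative model is the
#' same as in [simulate_ase_counts()]. Used for calibration and recovery
#' studies where the double-heterozygote count is the controlled quantity.
#'
#' @param n_double observations with h = 1.
#' @param n_hom observations with h = 0.
#' @param depth_mean,depth_dispersion negative-binomial depth model.
#' @param effects list with gamma_se, gamma_sh, beta_seh, mu_s (default 0).
#' @param v_s random-effect variance; if NULL drawn from `prior`.
#' @param prior [ig_prior()] used when `v_s` is NULL.
#' @param env_kind environment type.
#' @return An [ase_design()] with attribute `truth`.
#' @export
simulate_ase_design <- function(n_double = 150L, n_hom = 150L,
                                depth_mean = 60, depth_dispersion = 0.2,
                                effects = list(), v_s = NULL,
                                prior = ig_prior(1.80, 0.0024),
                                env_kind = "continuous") {
  ef <- modifyList(list(gamma_se = 0, gamma_sh = 0, beta_seh = 0, mu_s = 0),
                   effects)
  n_obs <- n_double + n_hom
  h <- c(rep(1, n_double), rep(0, n_hom))
  e <- simulate_env(n_obs, env_kind)
  if (is.null(v_s)) v_s <- 1 / rgamma(1, prior$a, rate = prior$b)
  nn <- rnbinom(n_obs, mu = depth_mean, size = 1 / depth_dispersion)
  nn <- pmax(nn, 1L)
  eta <- e * ef$gamma_se + h * ef$gamma_sh + e * h * ef$beta_seh + ef$mu_s
  d <- sample(c(-1, 1), n_obs, replace = TRUE)
  eps <- rnorm(n_obs, 0, sqrt(v_s))
  y <- rbinom(n_obs, nn, plogis(d * eta + eps))
  des <- ase_design(n = nn, y = y, e = e, h = h)
  attr(des, "truth") <- list(effects = ef, v_s = v_s, sign = d, eps = eps)
  des
}

#' Calibration / power study of the full test stack
#'
#' Repeatedly simulates one gene's data at the configured effect sizes,
#' runs the ASE likelihood-ratio test, the gene-level interaction test and
#' Fisher's combination, and tabulates rejection rates.
#'
#' @param cfg a [sim_config()]; its `effects` define the cell (all zero =
#'   null calibration).
#' @param n_reps number of replicates.
#' @param alphas significance levels for the rejection-rate table.
#' @param n_double,n_hom ASE design sizes per replicate.
#' @param arms which arms to run: subset of `c("ase", "gene")`.
#' @return List: `pvals` (data.frame with p_ase / p_gene / p_combined per
#'   replicate, NA for arms not run) and `rates` (rejection rates at each
#'   alpha).
#' @export
calibration_study <- function(cfg, n_reps = 200L, alphas = c(0.05, 0.01),
                              n_double = 150L, n_hom = 150L,
                              arms = c("ase", "gene")) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  p_ase <- p_gene <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    if ("ase" %in% arms) {
      des <- simulate_ase_design(n_double, n_hom,
                                 depth_mean = cfg$depth_mean,
                                 depth_dispersion = cfg$depth_dispersion,
                                 effects = cfg$effects, v_s = cfg$v_s,
                                 prior = cfg$prior, env_kind = cfg$env_kind)
      p_ase[r] <- tryCatch(ase_gxe_test(des, cfg$prior)$p_value,
                           error = function(e) NA_real_)
    }
    if ("gene" %in% arms) {
      n <- cfg$n_samples
      e <- simulate_env(n, cfg$env_kind)
      g <- rbinom(n, 2, cfg$maf_reqtl)
      Z <- cbind(intercept = rep(1, n))
      y <- e * cfg$effects$gamma_je + g * cfg$effects$gamma_jg +
        g * e * cfg$effects$beta_j + rnorm(n, 0, cfg$noise_sd)
      p_gene[r] <- tryCatch(fit_gene_interaction(y, Z, e, g)$p_gene,
                            error = function(e) NA_real_)
    }
  }
  p_comb <- if (all(c("ase", "gene") %in% arms))
    fisher_combine(pmax(p_ase, 1e-300), pmax(p_gene, 1e-300))
  else rep(NA_real_, n_reps)
  pv <- data.frame(p_ase = p_ase, p_gene = p_gene, p_combined = p_comb)
  rates <- sapply(alphas, function(a)
    c(ase = mean(p_ase < a, na.rm = TRUE),
      gene = mean(p_gene < a, na.rm = TRUE),
      combined = mean(p_comb < a, na.rm = TRUE)))
  colnames(rates) <- paste0("alpha", alphas)
  list(pvals = pv, rates = rates)
}
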