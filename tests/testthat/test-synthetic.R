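test_that("simulate_genotypes honors HWE, LD and determinism", {
  cfg <- sim_config(n_samples = 10000, maf_reqtl = 0.5, maf_tsnp = 0.5,
                    ld_r2 = 0.5, seed = 101)
  g <- simulate_genotypes(cfg)
  expect_lt(abs(mean(g$het_tsnp) - 0.5), 0.015)   # 2pq at p = 0.5
  expect_lt(abs(mean(g$g_reqtl) / 2 - 0.5), 0.02) # allele frequency
  # perfect LD at equal MAFs: identical genotypes
  cfg1 <- sim_config(n_samples = 500, maf_reqtl = 0.3, maf_tsnp = 0.3,
                     ld_r2 = 1, seed = 102)
  g1 <- simulate_genotypes(cfg1)
  expect_identical(g1$g_reqtl, g1$g_tsnp)
  expect_true(all(g1$phase == 1, na.rm = TRUE))
  # determinism
  expect_identical(simulate_genotypes(cfg1)$g_reqtl, g1$g_reqtl)
  # infeasible LD errors with the feasible bound
  expect_error(simulate_genotypes(
    sim_config(maf_reqtl = 0.05, maf_tsnp = 0.5, ld_r2 = 0.9, seed = 1)),
    "maximum feasible")
  # haplotype correlation tracks sqrt(ld_r2)
  cfg2 <- sim_config(n_samples = 20000, maf_reqtl = 0.3, maf_tsnp = 0.4,
                     ld_r2 = 0.49, seed = 103)
  g2 <- simulate_genotypes(cfg2)
  h <- g2$haplotypes[[1]]
  rr <- cor(c(h$h1[, 1], h$h2[, 1]), c(h$h1[, 2], h$h2[, 2]))
  expect_lt(abs(rr - 0.7), 0.02)
})

test_that("simulate_ase_counts obeys the generative model", {
  # symmetric null: pooled alt fraction ~ 0.5
  cfg <- sim_config(n_samples = 4000, n_tsnps = 5, depth_mean = 60,
                    v_s = 1e-4, seed = 111)
  g <- simulate_genotypes(cfg)
  env <- simulate_env(cfg$n_samples, "continuous")
  sim <- simulate_ase_counts(g, env, cfg)
  frac <- with(sim$records, sum(alt_count) / sum(alt_count + ref_count))
  expect_lt(abs(frac - 0.5), 0.01)
  # gamma_sh = 1: folded imbalance larger in reQTL hets than homs
  cfg2 <- sim_config(n_samples = 2000, effects = list(gamma_sh = 1),
                     v_s = 1e-4, seed = 112)
  g2 <- simulate_genotypes(cfg2)
  sim2 <- simulate_ase_counts(g2, simulate_env(2000, "continuous"), cfg2)
  r <- sim2$records
  tot <- r$ref_count + r$alt_count
  imb <- abs(0.5 - r$alt_count / pmax(tot, 1))
  is_het <- g2$het_reqtl[match(r$sample_id, g2$sample_id), 1]
  tt <- t.test(imb[is_het & tot > 0], imb[!is_het & tot > 0],
               alternative = "greater")
  expect_lt(tt$p.value, 0.01)
  # determinism and truth recording
  sim2b <- simulate_ase_counts(g2, simulate_env(2000, "continuous"), cfg2)
  expect_identical(sim2$records, sim2b$records)
  expect_true(is.finite(sim2$truth$per_tsnp[[1]]$v_s))
})

test_that("default-config simulated data survive QC for > 90% of tSNPs", {
  cfg <- sim_config(n_samples = 267, n_tsnps = 30, seed = 113)
  g <- simulate_genotypes(cfg)
  sim <- simulate_ase_counts(g, simulate_env(267, "continuous"), cfg)
  hm <- data.frame(sample_id = sim$records$sample_id,
                   tsnp_id = sim$records$tsnp_id, het = TRUE)
  qc <- count_filters(sim$records, hm)
  expect_gte(length(qc$tsnps) / 30, 0.9)
})

test_that("simulate_expression recovers coefficients without noise", {
  cfg <- sim_config(n_samples = 200, n_tsnps = 3, noise_sd = 1e-8,
                    effects = list(gamma_je = 0.4, gamma_jg = -0.3,
                                   beta_j = 0.7),
                    seed = 121)
  g <- simulate_genotypes(cfg)
  env <- simulate_env(200, "continuous")
  ex <- simulate_expression(g, env, cfg)
  for (j in 1:3) {
    fit <- fit_gene_interaction(ex$expr[j, ], ex$Z, env, g$g_reqtl[, j])
    expect_equal(fit$beta, 0.7, tolerance = 1e-6)
    expect_equal(fit$gamma_je, 0.4, tolerance = 1e-6)
    expect_equal(fit$gamma_jg, -0.3, tolerance = 1e-6)
  }
  # null: genotype slope CI covers 0 in most seeds
  cover <- vapply(1:40, function(s) {
    cfgn <- sim_config(n_samples = 150, seed = 1000 + s)
    gn <- simulate_genotypes(cfgn)
    en <- simulate_env(150, "continuous")
    exn <- simulate_expression(gn, en, cfgn)
    sm <- summary(lm(exn$expr[1, ] ~ gn$g_reqtl[, 1]))$coefficients
    abs(sm[2, 1]) < 1.96 * sm[2, 2]
  }, logical(1))
  expect_gte(mean(cover), 0.85)
})

test_that("gene-arm power at the cohort's size", {
  # beta_j = 1, n = 267, MAF 0.3: reject at alpha = 0.05 in most replicates
  rej <- vapply(1:40, function(s) {
    cfg <- sim_config(n_samples = 267, maf_reqtl = 0.3,
                      effects = list(beta_j = 1), seed = 2000 + s)
    g <- simulate_genotypes(cfg)
    env <- simulate_env(267, "continuous")
    ex <- simulate_expression(g, env, cfg)
    fit_gene_interaction(ex$expr[1, ], ex$Z, env, g$g_reqtl[, 1])$p_gene < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.5)
})

test_that("calibration_study tabulates rates and monotone power", {
  cfg0 <- sim_config(seed = 131, v_s = 0.003)
  cal0 <- calibration_study(cfg0, n_reps = 40, n_double = 60, n_hom = 60,
                            arms = "gene")
  expect_true(all(cal0$rates["gene", ] <= 0.2))
  # ASE arm: rejection rate grows with |beta_seh|
  rates <- vapply(c(0, 2), function(b) {
    cfg <- sim_config(seed = 132, v_s = 0.003,
                      effects = list(beta_seh = b, mu_s = -3))
    cal <- calibration_study(cfg, n_reps = 25, n_double = 80, n_hom = 40,
                             arms = "ase")
    cal$rates["ase", 1]
  }, numeric(1))
  expect_gte(rates[2], rates[1])
})

test_that("planted ASE interaction ranks near the top of a null panel", {
  # scaled-down panel power check: 1 planted tSNP (beta_seh = 2, generative
  # regime mu_s = -3) among 15 nulls; planted p should rank in the top 2
  hits <- vapply(1:4, function(s) {
    set.seed(6000 + s)
    p_null <- vapply(1:15, function(j) {
      des <- simulate_ase_design(60, 40, effects = list(mu_s = -0.5))
      ase_gxe_test(des)$p_value
    }, numeric(1))
    des1 <- simulate_ase_design(60, 40,
                                effects = list(beta_seh = 2, mu_s = -3))
    p1 <- ase_gxe_test(des1)$p_value
    rank(c(p1, p_null))[1] <= 2
  }, logical(1))
  expect_gte(mean(hits), 0.75)
})
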