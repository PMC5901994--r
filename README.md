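# reqtl

Tools for mapping **environmental-response eQTLs (reQTLs)** — regulatory
variants whose effect on gene expression depends on an environmental or
clinical context — from RNA-seq cohorts with genotypes, gene-level
expression, allele-specific expression (ASE) and clinical traits.

## Who this is for

Groups with a bulk RNA-seq cohort (hundreds of samples) that already have
imputed genotypes, per-sample allelic read counts at transcribed SNPs
(tSNPs), an expression matrix, and clinical/environment measurements, and
who want to test genotype-by-environment (GxE) interactions on expression
with the extra power and internal control that ASE provides: allelic read
counts compare the two haplotypes *within* a sample, canceling most
between-sample technical variation.

## The model

Two arms are fit per candidate (gene, regulatory SNP, environment) unit and
combined.

**ASE arm.** For sample *i* at tSNP *s* (samples heterozygous at the tSNP),
with total reads *n_is* and alternate reads *y_is*:

```
min(y_is, n_is - y_is) ~ Binomial( n_is,
    sigma( e_is*gamma_se + h_is*gamma_sh + e_is*h_is*beta_seh
           + mu_s + covariates + eps_is ) )
eps_is ~ N(0, v_s),   v_s ~ InvGamma(a, b)
```

where *e* is the (inverse-normalized, residualized) environment, *h* the
indicator that the candidate regulatory SNP is heterozygous, and *sigma*
the logistic function. The random effect *eps* models count overdispersion;
its variance carries an empirical-Bayes inverse-gamma prior whose
hyperparameters are learned across tSNPs (`estimate_ig_prior()`). The
random effect is integrated out by adaptive Gauss-Hermite quadrature, the
parameters are fit by MAP (`fit_ase_model()`), and the GxE term
`beta_seh = 0` is tested with a 1-df likelihood-ratio test (`ase_lrt()`).

**Gene arm.** Ordinary least squares on inverse-normalized expression
*y_j*:

```
y_j = Z*alpha + e*gamma_je + g*gamma_jg + (g .* e)*beta_j + noise
```

with covariates *Z* (batch, genotype PCs, PEER-like factors, age/sex) and a
t-test of `beta_j = 0` (`fit_gene_interaction()`).

**Combination.** `fisher_combine(p_ase, p_gene)` refers
`-2(ln p1 + ln p2)` to a chi-square with 4 df; q-values are
Benjamini-Hochberg within each trait and results are called at 10% FDR
(`call_reqtls()`). Discovery-to-replication comparison across cohorts uses
per-gene minimum p-values and a hypergeometric null band
(`replication_curve()`), and allele-specific transcription-factor motif
disruption is scored with `delta_score()`.

## Worked example

Simulate a small cohort with a planted GxE effect in the gene arm, run the
full pipeline, and look at the calls:

```r
library(reqtl)

cfg <- sim_config(n_samples = 200, n_tsnps = 3,
                  effects = list(beta_j = 0.8), seed = 7)
paths <- write_study(simulate_study(cfg), tempfile("demo"))

res <- run_discovery(list(
  counts = paths$counts, genotypes = paths$genotypes,
  traits = paths$traits, covariates = paths$covariates,
  expression = paths$expression, tsnp_map = paths$tsnp_map,
  candidates = paths$candidates,
  trait_kinds = list(env1 = "continuous"),
  qc = list(min_het_samples = 10)))

res$rows[, c("gene_id", "tsnp_id", "p_ase", "p_gene")]
#>    gene_id tsnp_id     p_ase       p_gene
#> 1 gene0001  ts0001 0.4367488 1.229110e-11
#> 2 gene0002  ts0002 0.7119612 1.168482e-09
#> 3 gene0003  ts0003 0.4129716 1.877550e-17

res$results$headline[, c("gene_id", "trait", "p_combined", "q_value")]
#>    gene_id trait   p_combined      q_value
#> 1 gene0003  env1 3.132387e-16 9.397161e-16
#> 2 gene0001  env1 1.446738e-10 2.170107e-10
#> 3 gene0002  env1 1.822499e-08 1.822499e-08
```

Every gene carries the planted expression-level interaction (`p_gene`
tiny); the ASE arm is null here (`beta_seh = 0` was simulated), so its
p-values are flat — exactly the "gene-level only" signature. `q_value` is
the within-trait BH-adjusted combined p; rows with `q <= 0.10` appear in
the headline table with their most significant tSNP.

Fisher combination of the two arms, on published numbers (ASE p = 4.29e-6,
gene p = 0.125):

```r
fisher_combine(4.29e-6, 1.25e-1)
#> [1] 8.278984e-06
```

## Command line

```sh
inst/cli/reqtl simulate  --config sim.json --out studydir
inst/cli/reqtl discover  --config run.json --out outdir
inst/cli/reqtl replicate --discovery d.tsv --replication r.tsv --out curve.tsv
inst/cli/reqtl delta     --hits fimo_pairs.tsv --out scored.tsv
```

See the methods vignette (`vignettes/reqtl-methods.Rmd`) for the model
assumptions, the synthetic-data generator's stated world, and known
limitations (notably fold-induced attenuation of strong interaction
effects near balanced expression).
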