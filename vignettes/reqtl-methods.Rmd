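---
title: "Methods: joint ASE and gene-level mapping of environmental-response eQTLs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint ASE and gene-level mapping of environmental-response eQTLs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reqtl)
```

## The problem

An eQTL changes a gene's expression; an environmental-response eQTL
(reQTL) changes it *differently depending on context* — age, sex, BMI,
blood pressure, lipid levels, disease status. Detecting such
genotype-by-environment (GxE) interactions in expression is hard because
environmental effects are confounded with batch and other between-sample
technical variation. Allele-specific expression (ASE) sidesteps much of
this: within a sample heterozygous for both a regulatory variant and a
transcribed SNP (tSNP), the two haplotypes share every trans and technical
factor, so a context-dependent *cis* effect shows up as a change in
allelic imbalance with the environment. This package implements the joint
pipeline: QC of allelic counts, trait preparation, an ASE interaction
model, a gene-level interaction model, Fisher combination with per-trait
FDR, cross-cohort replication curves, and motif-disruption scores.

## The ASE arm

For sample $i$ at tSNP $s$, with total count $n_{is}$ and alternate count
$y_{is}$, the folded (minor-allele) count is modeled as

$$\min(y_{is}, n_{is}-y_{is}) \sim \mathrm{Binomial}\!\left[n_{is},\,
\sigma(e_{is}\gamma_{se} + h_{is}\gamma_{sh} + e_{is}h_{is}\beta_{seh} +
\mu_s + x_{is}'\delta + \varepsilon_{is})\right]$$

with $\varepsilon_{is} \sim N(0, v_s)$ a per-observation random effect for
overdispersion, $v_s \sim IG(a,b)$, $h_{is}$ the indicator that the
candidate regulatory SNP is heterozygous, and $\sigma$ the logistic
function. Folding is used because phase between the regulatory SNP and the
tSNP is unknown; only double heterozygotes carry interaction information,
which is why eligibility requires enough of them.

Implementation choices (the inference algorithm is not dictated by the
model statement, so these are this package's own):

* **Likelihood exactly as written.** The binomial pmf is evaluated *at*
  the folded count with an unconstrained logistic mean — not the two-term
  folded mixture over phase. The mixture is mathematically equivalent for
  inference on $|\eta|$ and is not exposed; the printed form is what is
  fit and what the generator simulates.
* **Adaptive Gauss–Hermite quadrature**, 20 nodes, centered and scaled at
  each observation's conditional mode (found by Newton iteration on a
  strictly concave 1-d objective). Tests require agreement with dense
  trapezoid integration to relative error $<10^{-6}$ and stability under
  doubling the node count. Nodes come from the Golub–Welsch
  eigendecomposition — deterministic, no external dependency.
* **MAP estimation.** $(\mu_s, \gamma_{se}, \gamma_{sh}, \beta_{seh},
  \delta, \log v_s)$ maximize the marginal likelihood plus the log
  inverse-gamma prior density of $v_s$, from a deterministic start (zeros;
  $v_s$ at the prior mode $b/(a+1)$), with a BFGS polish pass and a
  central-difference gradient-norm convergence check (threshold $10^{-4}$;
  non-converged fits are flagged and excluded downstream with a log
  entry).
* **LRT on the MAP objective.** $\Lambda = 2(\ell_{full} - \ell_{null})$,
  clipped at 0, referred to $\chi^2_1$. Both fits carry the same prior
  penalty on their own $v_s$, so the penalty largely cancels; calibration
  is established empirically by the 1000-replicate null simulation in the
  acceptance suite rather than asserted asymptotically. If optimization
  noise leaves the null above the full model, the null is refit
  warm-started from the full solution.
* **Empirical Bayes.** Per-tSNP intercept-only maximum-likelihood fits
  give variance estimates $\hat v_s$; $IG(a,b)$ is fit to them by profile
  maximum likelihood ($b = na/\sum 1/\hat v$ for fixed $a$, then a 1-d
  search over $\log a$). On draws from $IG(1.80, 0.0024)$ — the default
  prior — the fit recovers the hyperparameters (acceptance test).

## The gene-level arm

Inverse-normalized expression is modeled by ordinary least squares:
$y_j = Z\alpha_j + e\gamma_{je} + g\gamma_{jg} + (g \odot e)\beta_j +
\psi_j$, with $Z$ holding intercept, sequencing batch, two genotype PCs,
two PEER-like factors, and age and sex except when the tested trait is age
or sex respectively. The interaction p-value is the two-sided t-test of
$\beta_j$ on residual degrees of freedom, which is identical to the 1-df
nested F-test (asserted numerically in the tests). A mixed-model variant
is deliberately not used: the written model has Gaussian iid noise and no
random effect, and OLS is exact under it.

## Trait preparation

Continuous traits are rank inverse-normal transformed with the Blom offset
$(r - 3/8)/(m + 1/4)$ — the common default in eQTL pipelines; the offset
is configurable and ties receive average ranks so the transform is
permutation-invariant — then residualized on age, age$^2$ and sex (age
itself only on sex). Missing values propagate per trait; samples missing a
trait are dropped for that trait only. Dichotomous traits pass through
with 0/1 coding, untransformed. Because every continuous trait is
sex-adjusted globally, using sex as the tested environment leaves a
partial confounding between the global adjustment and the tested term;
this follows the source procedure and is noted rather than "fixed".

## QC and eligibility

Filters run in a fixed order: (1) drop observations with fewer than 30
total reads; (2) drop tSNPs heterozygous in fewer than 20 surviving
samples; (3) drop tSNPs with any surviving sample showing
$|0.5 - y/n| > 0.4$ (near mono-allelic, a genotyping-error signature).
Mapping-bias screening (simulated coverage within [193, 202], simulated
allele ratio within 5% of 0.5) is independent of the count filters, so its
position upstream does not change the result. Eligibility per regulatory
SNP and trait: at least 15 heterozygous and 15 homozygous samples (both
homozygote classes pooled — the ASE model only sees the heterozygosity
indicator) after removing missing-environment samples, and for dichotomous
traits no heterozygosity-by-level cell under 5 samples.

## The synthetic world

The generator's defaults state the world the analysis was designed for:
267 samples, MAF 0.3 at both loci with haplotype correlation
$\sqrt{0.8}$, standard-normal continuous environments (the scale any trait
has after inverse-normal transformation) or Bernoulli(0.5) dichotomous
ones, negative-binomial read depth with mean 60 and dispersion 0.2 (the
source is silent on the depth distribution; mean 60 keeps records above
the 30-read filter so downstream stages are exercised), per-tSNP variances
from $IG(1.80, 0.0024)$, and all effects zero unless a cell states
otherwise. Genotypes are drawn as two-locus haplotypes in HWE with
positive-phase disequilibrium, and the phase of every double heterozygote
is recorded as truth, so allelic counts can be assigned phase-consistently.

Two simulation cells fix the unstated baseline intercept $\mu_s$ once:

* **Null calibration** uses $\mu_s = -0.5$ (folded allelic fraction
  $\approx 0.38$), a moderate, QC-compatible baseline imbalance typical of
  a het eQTL locus. A locus with *exactly* balanced expression
  ($\mu_s = 0$) is the degenerate boundary of the folded model: the folded
  count there is under-dispersed relative to any binomial and the LRT
  turns conservative (type-I error $\approx 0.005$ at $\alpha = 0.05$ in
  our simulations). Real tSNP panels have baseline imbalance spread below
  0.5 — which is what the model's own intercept term exists to absorb.
* **Effect recovery** (planted $\beta_{seh} = 1.5$) uses $\mu_s = -3$.
  The printed model generates the *folded* count, whose support is below
  $n/2$; a generative use of the model is self-consistent only while
  $\sigma(\eta + \varepsilon) < 1/2$. With a standard-normal environment
  and an effect of 1.5, that pins the baseline logit near $-3$
  ($P(\eta > 0) \approx 2\%$). This cell probes the estimator on data
  from its own model.

What a green test does **not** establish: power and unbiasedness for
strong interactions at *moderate* baseline imbalance. When
$\mu_s + \beta_{seh} e$ crosses zero, folding reflects the signal and
attenuates $\hat\beta_{seh}$ toward zero (at $\mu_s = 0$ the sign of
$\beta_{seh}$ is unidentifiable from folded data and $\hat\beta \approx
0$). This fold-induced attenuation is intrinsic to phase-unaware ASE
models of this form — phased haplotype counts, noted as future work in the
source study, remove it. The generator also does not emulate reference
mapping bias, genotyping error, correlated environments, or LD beyond one
tSNP per gene.

## Combination, FDR, replication

Fisher's statistic $-2(\ln p_{ASE} + \ln p_{gene})$ is referred to
$\chi^2_4$; the closed form $p_1 p_2 (1 - \ln p_1 p_2)$ is tested against
it to $10^{-10}$. Independence of the two arms is an assumption inherited
from the method, taken as-is. FDR is Benjamini–Hochberg within each trait.
Because multiple tSNPs per gene yield multiple combined p-values, the
default summarizes each gene by its *minimum* combined p before BH (the
headline table keeps the most significant tSNP per gene–trait pair, and
the full pair list is emitted alongside); per-pair FDR is available via
`per_gene = FALSE`. Both conventions are defensible; the per-gene minimum
matches how hits are reported per gene, but note it is slightly
anti-conservative without a per-gene multiplicity correction.

Replication: per-gene minimum p in each cohort, replication called at
p $< 0.01$, the rate $k/n$ traced over every unique discovery cutoff
(stopping at $n < 10$), against a null band $K/N \pm 2\,\mathrm{sd}(k/n)$
with $k \sim$ Hypergeometric$(N, K, n)$. The band is computed for $k/n$
(not $k$); $k/K$ is emitted alongside since the rate definition in prose
is ambiguous. Both the mean and the variance are verified against
exhaustive enumeration for $N \le 12$.

## Motif delta scores

$\Delta = -\log_{10} p_{alt} + \log_{10} p_{ref}$ from per-allele motif
scans, scored only where one allele passes the scanner's reporting
threshold ($10^{-4}$); an allele with no hit at threshold 0.01 is
substituted with $p = 0.01$, which bounds $|\Delta|$ from below relative
to the truth (the undetected allele's true p exceeds 0.01), i.e. the score
is conservative.

## Numerical details and degenerate inputs

* $v = 0$ reduces the marginal likelihood exactly to the fixed-effect
  binomial likelihood (tested against `glm`).
* Zero-variance environments, designs without double heterozygotes,
  collinear covariates, all-constant traits, p-values outside $(0,1]$, and
  duplicated (gene, tSNP, trait) rows raise immediate errors naming the
  offending unit; pipeline units that error are logged and skipped, never
  silently dropped.
* All tables are TSV with headers; positions 1-based; configs are JSON.
* Everything is deterministic given seeds; the pipeline itself draws no
  random numbers.

## Known limitations

Fold-induced attenuation (above); no trans effects; one environment tested
at a time with no multi-trait model; PEER factors and genotype PCs are
inputs, never computed; the per-gene-minimum FDR convention lacks a
within-gene multiplicity adjustment; replication assumes a shared gene
universe and harmonized trait definitions across cohorts.
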