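Package: reqtl
Title: Mapping Environmental-Response eQTLs from Allele-Specific and
    Gene-Level Expression
Version: 0.1.0
Authors@R:
    person("reqtl", "maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint detection of genotype-by-environment (GxE) interaction
    effects on gene expression from allele-specific read counts and
    gene-level expression. Implements a folded-binomial logistic model with
    a per-observation Gaussian random effect whose variance carries an
    empirical-Bayes inverse-gamma prior (fit by adaptive Gauss-Hermite
    quadrature and tested by likelihood ratio), an ordinary-least-squares
    interaction model for inverse-normalized expression, Fisher's combined
    probability test with per-trait Benjamini-Hochberg FDR control,
    discovery-to-replication rate curves against a hypergeometric null,
    allele-specific transcription-factor motif disruption scores, the
    quality-control and eligibility filters used for allelic count data,
    and a synthetic-data generator with recorded ground truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
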