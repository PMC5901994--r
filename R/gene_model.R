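#' Gene-level GxE interaction fit
#'
#' Ordinary-least-squares fit of the linear interaction model
#' `y = Z alpha + e gamma_je + g gamma_jg + (g * e) beta + noise`
#' for one gene's inverse-normalized expression vector, where `Z` is the
#' fixed covariate design (intercept plus e.g. sequencing batch, genotype
#' PCs, PEER-like factors, and age/sex unless one of them is the tested
#' trait), `e` the environment and `g` the genotype dosage. The interaction
#' p-value is the two-sided t-test of beta = 0 on the residual degrees of
#' freedom.
#'
#' @param y numeric expression vector (inverse-normalized).
#' @param Z covariate matrix including an intercept column; full column rank
#'   required.
#' @param e environment vector (non-constant).
#' @param g genotype dosage vector (at least two distinct values).
#' @return List of class `gene_fit`: `gamma_je`, `gamma_jg`, `beta`,
#'   `se_beta`, `t`, `df`, `p_gene`, `alpha` (covariate effects),
#'   `sigma2` (residual variance).
#' @export
fit_gene_interaction <- function(y, Z, e, g) {
  Z <- as.matrix(Z)
  n <- length(y)
  if (nrow(Z) != n || length(e) != n || length(g) != n)
    stop("y, Z, e, g must be aligned")
  if (anyNA(cbind(y, Z, e, g)))
    stop("missing values: drop incomplete samples before fitting")
  if (length(unique(g)) < 2L) stop("genotype vector is constant")
  if (length(unique(e)) < 2L) stop("environment vector is constant")
  if (n <= ncol(Z) + 3L) stop("too few samples for the design")
  if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  X <- cbind(Z, env = e, geno = g, gxe = g * e)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_idx <- qrX$pivot[seq(qrX$rank + 1L, ncol(X))]
    stop("rank-deficient design; collinear columns: ",
         paste(colnames(X)[drop_idx], collapse = ", "))
  }
  bhat <- qr.coef(qrX, y)
  res <- qr.resid(qrX, y)
  df <- n - ncol(X)
  sigma2 <- sum(res^2) / df
  XtXinv_diag <- diag(chol2inv(qr.R(qrX)))
  # chol2inv(R) gives (X'X)^-1 in pivoted order; map back
  XtXinv_diag <- XtXinv_diag[order(qrX$pivot)]
  se <- sqrt(sigma2 * XtXinv_diag)
  k <- ncol(X)
  tstat <- bhat[k] / se[k]
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  structure(list(gamma_je = unname(bhat[k - 2L]),
                 gamma_jg = unname(bhat[k - 1L]),
                 beta = unname(bhat[k]),
                 se_beta = unname(se[k]),
                 t = unname(tstat), df = df,
                 p_gene = unname(p),
                 alpha = bhat[seq_len(ncol(Z))],
                 sigma2 = sigma2),
            class = "gene_fit")
}

#' @export
print.gene_fit <- function(x, ...) {
  cat("gene-level GxE fit: beta =", signif(x$beta, 4),
      "(se", paste0(signif(x$se_beta, 4), ","),
      "t =", paste0(signif(x$t, 4), ","),
      "df =", paste0(x$df, ")"), "p =", signif(x$p_gene, 4), "\n")
  invisible(x)
}
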