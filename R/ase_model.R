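## ASE arm: folded-binomial logistic model with a per-observation Gaussian
## random effect whose variance v_s carries an inverse-gamma prior IG(a, b).
## For sample i at tSNP s (restricted to samples heterozygous at the tSNP):
##   min(y_is, n_is - y_is) ~ Binomial(n_is, sigma(e*gamma_se + h*gamma_sh +
##                                     e*h*beta_seh + mu_s + covariates + eps)),
##   eps ~ N(0, v_s),  v_s ~ IG(a, b).
## The random effect is integrated out by adaptive Gauss-Hermite quadrature
## and (mu, gamma_se, gamma_sh, beta_seh, covariate effects, log v) are found
## by maximizing the posterior (MAP) objective. The GxE test is a 1-df
## likelihood-ratio test of beta_seh = 0.

#' Fold an allelic count onto the minor allele
#'
#' Returns `min(y, n - y)`, the count of the less-expressed allele, used as
#' the model response when phase between the regulatory SNP and the tSNP is
#' unknown.
#'
#' @param y alternate-allele read count(s).
#' @param n total read count(s).
#' @return Integer vector, elementwise `min(y, n - y)` (always <= n/2).
#' @export
fold_count <- function(y, n) {
  if (any(y < 0) || any(n < 0)) stop("counts must be non-negative")
  if (any(y > n)) stop("y must not exceed n")
  pmin(y, n - y)
}

#' Inverse-gamma prior on the random-effect variance
#'
#' @param a shape (> 0).
#' @param b scale (> 0). Density b^a / Gamma(a) * v^-(a+1) * exp(-b/v).
#' @return List of class `ig_prior`.
#' @export
ig_prior <- function(a = 1.80, b = 0.0024) {
  if (a <= 0 || b <= 0) stop("inverse-gamma parameters must be positive")
  structure(list(a = a, b = b), class = "ig_prior")
}

dinvgamma_log <- function(v, prior) {
  prior$a * log(prior$b) - lgamma(prior$a) -
    (prior$a + 1) * log(v) - prior$b / v
}

# Gauss-Hermite nodes/weights for weight exp(-x^2) via the Golub-Welsch
# eigendecomposition of the Jacobi matrix; deterministic, no dependencies.
gauss_hermite <- function(K) {
  if (K < 1) stop("need at least one quadrature node")
  if (K == 1L) return(list(x = 0, logw = 0.5 * log(pi)))
  off <- sqrt(seq_len(K - 1) / 2)
  J <- diag(0, K)
  J[cbind(seq_len(K - 1), seq_len(K - 1) + 1L)] <- off
  J[cbind(seq_len(K - 1) + 1L, seq_len(K - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord],
       logw = (0.5 * log(pi) + 2 * log(abs(e$vectors[1, ])))[ord])
}

#' Design for one ASE GxE fit
#'
#' Bundles, for the samples heterozygous at one tSNP, the total and
#' alternate read counts, the environment value, the indicator that the
#' candidate regulatory SNP is heterozygous, and optional covariates
#' (e.g. genotype principal components, main effects only).
#'
#' @param n total read counts.
#' @param y alternate-allele read counts.
#' @param e environment values (no NA; drop missing samples first).
#' @param h 0/1 regulatory-SNP heterozygosity indicator.
#' @param covariates optional numeric matrix, one row per observation.
#' @return List of class `ase_design` with folded counts in `m`.
#' @export
ase_design <- function(n, y, e, h, covariates = NULL) {
  len <- length(n)
  if (length(y) != len || length(e) != len || length(h) != len)
    stop("n, y, e, h must be aligned")
  if (anyNA(c(n, y, e, h))) stop("ase_design does not accept missing values")
  if (!all(h %in% c(0, 1))) stop("h must be 0/1")
  m <- fold_count(y, n)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != len) stop("covariates misaligned")
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
  }
  structure(list(n = as.numeric(n), y = as.numeric(y), m = as.numeric(m),
                 e = as.numeric(e), h = as.numeric(h), X = covariates),
            class = "ase_design")
}

ase_linear_predictor <- function(design, mu, gamma_se, gamma_sh, beta_seh,
                                 cov_effects = NULL) {
  eta <- mu + design$e * gamma_se + design$h * gamma_sh +
    design$e * design$h * beta_seh
  if (!is.null(design$X)) {
    if (is.null(cov_effects)) cov_effects <- rep(0, ncol(design$X))
    eta <- eta + drop(design$X %*% cov_effects)
  }
  eta
}

#' Marginal log-likelihood (MAP objective) of the ASE model
#'
#' Sum over observations of the log binomial likelihood of the folded count
#' with the Gaussian random effect integrated out by adaptive Gauss-Hermite
#' quadrature (nodes centered and scaled at each observation's conditional
#' mode), plus, when `prior` is given, the log inverse-gamma prior density
#' of `v`. At `v = 0` it reduces exactly to the fixed-effect binomial
#' log-likelihood.
#'
#' @param design an [ase_design()].
#' @param mu,gamma_se,gamma_sh,beta_seh model coefficients.
#' @param v random-effect variance (>= 0).
#' @param cov_effects covariate coefficients (length = ncol of design
#'   covariates), if any.
#' @param prior optional [ig_prior()]; when supplied its log density of `v`
#'   is added (MAP objective).
#' @param nodes number of quadrature nodes (default 20).
#' @return Scalar log-likelihood / MAP objective.
#' @export
ase_marginal_loglik <- function(design, mu = 0, gamma_se = 0, gamma_sh = 0,
                                beta_seh = 0, v = 0, cov_effects = NULL,
                                prior = NULL, nodes = 20L) {
  if (v < 0) stop("v must be >= 0")
  eta <- ase_linear_predictor(design, mu, gamma_se, gamma_sh, beta_seh,
                              cov_effects)
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  gh <- gauss_hermite(nodes)
  ll <- sum(ase_obs_loglik_cpp(design$m, design$n, eta, v, gh$x, gh$logw))
  if (!is.null(prior)) ll <- ll + dinvgamma_log(max(v, 1e-300), prior)
  ll
}

# objective over packed parameters theta = (mu, gamma_se, gamma_sh,
# [beta_seh], cov effects..., log v); returns the MAP objective
ase_objective <- function(theta, design, prior, interaction, gh) {
  p_cov <- if (is.null(design$X)) 0L else ncol(design$X)
  mu <- theta[1]; gse <- theta[2]; gsh <- theta[3]
  i <- 4L
  b <- 0
  if (interaction) { b <- theta[i]; i <- i + 1L }
  ce <- if (p_cov) theta[i:(i + p_cov - 1L)] else NULL
  lv <- theta[length(theta)]
  v <- exp(lv)
  eta <- ase_linear_predictor(design, mu, gse, gsh, b, ce)
  if (any(!is.finite(eta))) return(-Inf)
  ll <- sum(ase_obs_loglik_cpp(design$m, design$n, eta, v, gh$x, gh$logw))
  if (!is.null(prior)) ll <- ll + dinvgamma_log(v, prior)
  ll
}

num_grad <- function(f, x, eps = 1e-5) {
  vapply(seq_along(x), function(j) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

#' Fit the ASE GxE model
#'
#' Maximizes the MAP objective over the intercept, the environment and
#' heterozygosity main effects, the GxE interaction (optional), covariate
#' effects and log variance, starting from zeros with the variance at the
#' prior mode b/(a + 1). The null model for the LRT is obtained with
#' `include_interaction = FALSE`.
#'
#' @param design an [ase_design()]; must contain at least one
#'   double-heterozygous observation (h = 1).
#' @param prior an [ig_prior()] on the random-effect variance.
#' @param include_interaction fit the GxE term beta_seh (TRUE) or constrain
#'   it to zero (FALSE).
#' @param nodes Gauss-Hermite nodes.
#' @param start optional start vector (packed as mu, gamma_se, gamma_sh,
#'   \[beta_seh\], covariates, log v) to warm-start the optimizer.
#' @return List of class `ase_fit`: coefficients, `v_s`, `objective` (MAP),
#'   `loglik` (data log-likelihood at the optimum, prior excluded),
#'   `converged` flag and `grad_norm`.
#' @export
fit_ase_model <- function(design, prior = ig_prior(), include_interaction = TRUE,
                          nodes = 20L, start = NULL) {
  stopifnot(inherits(design, "ase_design"))
  if (sum(design$h) == 0)
    stop("untestable: no double heterozygotes")
  if (length(unique(design$e)) < 2L)
    stop("degenerate design: environment is constant")
  p_cov <- if (is.null(design$X)) 0L else ncol(design$X)
  np <- 3L + include_interaction + p_cov + 1L
  if (is.null(start)) {
    start <- rep(0, np)
    start[np] <- log(prior$b / (prior$a + 1))
  }
  gh <- gauss_hermite(nodes)
  f <- function(th) ase_objective(th, design, prior, include_interaction, gh)
  opt <- optim(start, f, method = "BFGS",
               control = list(fnscale = -1, maxit = 500, reltol = 1e-12))
  # one polish pass guards against early BFGS termination
  opt2 <- optim(opt$par, f, method = "BFGS",
                control = list(fnscale = -1, maxit = 500, reltol = 1e-12))
  if (opt2$value > opt$value) opt <- opt2
  g <- num_grad(f, opt$par)
  grad_norm <- sqrt(sum(g^2))
  th <- opt$par
  coefs <- c(mu = th[1], gamma_se = th[2], gamma_sh = th[3])
  i <- 4L
  if (include_interaction) { coefs["beta_seh"] <- th[i]; i <- i + 1L }
  if (p_cov) {
    ce <- th[i:(i + p_cov - 1L)]
    names(ce) <- colnames(design$X)
    coefs <- c(coefs, ce)
  }
  v <- exp(th[length(th)])
  ll_data <- ase_marginal_loglik(design,
                                 mu = th[1], gamma_se = th[2],
                                 gamma_sh = th[3],
                                 beta_seh = if (include_interaction) coefs[["beta_seh"]] else 0,
                                 v = v,
                                 cov_effects = if (p_cov) coefs[3L + include_interaction + seq_len(p_cov)] else NULL,
                                 prior = NULL, nodes = nodes)
  structure(list(coefficients = coefs, v_s = v,
                 objective = opt$value, loglik = ll_data,
                 interaction = include_interaction,
                 converged = grad_norm < 1e-4, grad_norm = grad_norm,
                 par = th, design = design, prior = prior, nodes = nodes),
            class = "ase_fit")
}

#' @export
print.ase_fit <- function(x, ...) {
  cat("ASE GxE fit (", if (x$interaction) "full" else "null", " model)\n", sep = "")
  print(round(x$coefficients, 4))
  cat("v_s =", signif(x$v_s, 4), " MAP objective =", round(x$objective, 4),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  invisible(x)
}

#' Likelihood-ratio test of the GxE interaction
#'
#' Lambda = 2 * (objective_full - objective_null), clipped at zero, referred
#' to a chi-square distribution with 1 degree of freedom. Both fits carry
#' the same inverse-gamma penalty on their variance term, so the penalized
#' objectives difference behaves as an ordinary LRT statistic (calibration
#' is verified by null simulation). If the null objective exceeds the full
#' one beyond tolerance the null is refit warm-started from the full
#' solution.
#'
#' @param full fit with the interaction term.
#' @param null fit with `include_interaction = FALSE` on the same design.
#' @param tol tolerance on objective inversion before refitting.
#' @return List: `stat`, `p_value`, and the (possibly refit) `null` fit.
#' @export
ase_lrt <- function(full, null, tol = 1e-6) {
  stopifnot(inherits(full, "ase_fit"), inherits(null, "ase_fit"))
  if (!full$interaction || null$interaction)
    stop("ase_lrt expects (full with interaction, null without)")
  if (full$objective < null$objective - tol) {
    # restart the null from the full solution with beta_seh removed
    st <- full$par[-4L]
    null2 <- fit_ase_model(full$design, full$prior,
                           include_interaction = FALSE,
                           nodes = full$nodes, start = st)
    if (null2$objective > null$objective) null <- null2
    if (full$objective < null$objective - tol)
      stop("full-model objective below null beyond tolerance")
  }
  lambda <- max(0, 2 * (full$objective - null$objective))
  list(stat = lambda,
       p_value = pchisq(lambda, df = 1, lower.tail = FALSE),
       null = null)
}

#' Test one design for a GxE effect in ASE
#'
#' Convenience wrapper: fits full and null models and returns the LRT.
#'
#' @inheritParams fit_ase_model
#' @return List with `full`, `null`, `stat`, `p_value`.
#' @export
ase_gxe_test <- function(design, prior = ig_prior(), nodes = 20L) {
  full <- fit_ase_model(design, prior, include_interaction = TRUE, nodes = nodes)
  null <- fit_ase_model(design, prior, include_interaction = FALSE, nodes = nodes)
  lrt <- ase_lrt(full, null)
  list(full = full, null = lrt$null, stat = lrt$stat, p_value = lrt$p_value)
}

#' Per-tSNP maximum-likelihood variance from an intercept-only model
#'
#' Fits (mu_s, v_s) by maximum likelihood (no prior) for one tSNP's folded
#' counts; the resulting variance estimates across tSNPs feed
#' [estimate_ig_prior()].
#'
#' @param y,n alternate and total counts for one tSNP's observations.
#' @param nodes Gauss-Hermite nodes.
#' @return Named vector with `mu` and `v`.
#' @export
ase_variance_ml <- function(y, n, nodes = 20L) {
  m <- fold_count(y, n)
  gh <- gauss_hermite(nodes)
  f <- function(th) {
    sum(ase_obs_loglik_cpp(m, n, rep(th[1], length(m)), exp(th[2]),
                           gh$x, gh$logw))
  }
  opt <- optim(c(0, log(0.01)), f, method = "BFGS",
               control = list(fnscale = -1, maxit = 500, reltol = 1e-12))
  c(mu = opt$par[1], v = exp(opt$par[2]))
}

#' Empirical-Bayes inverse-gamma hyperparameters
#'
#' Maximum-likelihood fit of IG(a, b) to a sample of per-tSNP variance
#' estimates, by profiling: for fixed shape a the scale is
#' b = n * a / sum(1/v), and the profile likelihood is maximized over log a.
#'
#' @param vhat positive per-tSNP variance estimates (non-positive values are
#'   dropped with a warning); at least 50 must remain.
#' @return An [ig_prior()] with the fitted (a, b).
#' @export
estimate_ig_prior <- function(vhat) {
  bad <- !is.finite(vhat) | vhat <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive variance estimates excluded")
    vhat <- vhat[!bad]
  }
  n <- length(vhat)
  if (n < 50L) stop("need >= 50 positive variance estimates")
  if (length(unique(vhat)) == 1L)
    stop("degenerate variance sample: all values equal")
  s_inv <- sum(1 / vhat)
  s_log <- sum(log(vhat))
  prof <- function(la) {
    a <- exp(la)
    b <- n * a / s_inv
    n * a * log(b) - n * lgamma(a) - (a + 1) * s_log - b * s_inv
  }
  opt <- optimize(prof, c(log(1e-3), log(1e3)), maximum = TRUE, tol = 1e-10)
  a <- exp(opt$maximum)
  ig_prior(a = a, b = n * a / s_inv)
}
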