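#' Rank-based inverse-normal transform
#'
#' Replaces the non-missing values of `x` by standard-normal quantiles of
#' their Blom-offset fractional ranks, `qnorm((r - offset) / (m - 2*offset + 1))`
#' with `m` the number of non-missing values and ties receiving average
#' ranks. With the default offset 3/8 this is the usual Blom transform used
#' in eQTL pipelines; missing values stay missing and ranks are preserved.
#'
#' @param x numeric vector, NA allowed.
#' @param offset rank offset in \[0, 0.5\]; 3/8 (Blom) by default.
#' @return Numeric vector, same length and NA pattern as `x`.
#' @export
inverse_normal_transform <- function(x, offset = 3/8) {
  ok <- !is.na(x)
  m <- sum(ok)
  if (m < 2L || length(unique(x[ok])) < 2L)
    stop("inverse_normal_transform needs >= 2 distinct non-missing values")
  r <- rank(x[ok], ties.method = "average")
  out <- x
  out[ok] <- qnorm((r - offset) / (m - 2 * offset + 1))
  out
}

#' Residualize a trait on age, age squared and sex
#'
#' Returns least-squares residuals of an (already inverse-normalized)
#' continuous trait on intercept + age + age^2 + sex. When the trait itself
#' is age, only intercept + sex are used. Samples with a missing trait value
#' keep NA; covariates must be observed wherever the trait is.
#'
#' @param trait numeric vector (NA allowed).
#' @param age numeric vector of ages.
#' @param sex 0/1 indicator vector.
#' @param trait_is_age set TRUE when `trait` is the age variable itself.
#' @return Numeric vector of residuals with the NA pattern of `trait`.
#' @export
residualize_trait <- function(trait, age, sex, trait_is_age = FALSE) {
  n <- length(trait)
  if (length(age) != n || length(sex) != n)
    stop("trait, age and sex must be aligned")
  ok <- !is.na(trait)
  if (any(is.na(age[ok])) || any(is.na(sex[ok])))
    stop("covariates missing where trait is observed")
  X <- if (trait_is_age) cbind(1, sex = sex[ok])
       else cbind(1, age = age[ok], age2 = age[ok]^2, sex = sex[ok])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("collinear covariate design in residualization")
  out <- rep(NA_real_, n)
  out[ok] <- qr.resid(qrX, trait[ok])
  out
}

#' Prepare a trait table for GxE testing
#'
#' Continuous traits are inverse-normal transformed then residualized on
#' age, age^2 and sex (age itself only on sex). Dichotomous traits pass
#' through unchanged with 0/1 coding.
#'
#' @param traits data.frame, samples in rows, traits in columns.
#' @param kinds named character vector, `"continuous"` or `"dichotomous"`
#'   per trait column.
#' @param age,sex per-sample covariates used for residualization.
#' @return data.frame of processed traits, same shape as `traits`.
#' @export
prepare_traits <- function(traits, kinds, age, sex) {
  if (!all(names(traits) %in% names(kinds)))
    stop("every trait column needs a declared kind")
  out <- traits
  for (nm in names(traits)) {
    if (kinds[[nm]] == "dichotomous") {
      v <- traits[[nm]]
      if (!all(v %in% c(0, 1) | is.na(v)))
        stop("dichotomous trait '", nm, "' must be 0/1/NA")
      next
    }
    z <- inverse_normal_transform(traits[[nm]])
    out[[nm]] <- residualize_trait(z, age, sex,
                                   trait_is_age = identical(nm, "age"))
  }
  out
}
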