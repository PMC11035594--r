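check_design <- function(data, needs_e = TRUE) {
  need <- c("y", "g", if (needs_e) "e")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(paste0("Design is missing column(s): ", paste(miss, collapse = ", ")))
  }
  n0 <- nrow(data)
  data <- data[complete.cases(data), , drop = FALSE]
  if (nrow(data) < n0) {
    inform(paste0("Listwise deletion removed ", n0 - nrow(data), " row(s)."))
  }
  data
}

#' Fit the genome-wide interaction (GWIS) model to individual-level data
#'
#' Ordinary least squares of `y` on the genotype, the exposure, their
#' product and optional covariates:
#' `y ~ g + e + g:e + covariates`. Returns the coefficient estimates
#' `beta0..beta3` with their SEs, the covariance of the main and interaction
#' estimates, and the direct interaction test
#' \eqn{T_{direct} = \hat\beta_3^2 / var(\hat\beta_3)} with a two-sided
#' p-value from chi-square(1). Rows with missing values are dropped
#' listwise with a message.
#'
#' @param data Data frame with columns `y` (trait), `g` (genotype dosage or
#'   standardized dosage), `e` (exposure), plus any covariate columns named
#'   in `covariates`.
#' @param covariates Character vector of covariate column names (optional).
#' @return A list of class `gxe_lm` with elements `coef` (named estimates),
#'   `se`, `cov_beta1_beta3`, `sigma2`, `n`, `test` (a one-row test tibble)
#'   and the underlying `lm` fit.
#' @export
fit_interaction_model <- function(data, covariates = NULL) {
  data <- check_design(data)
  if (var(data$e) == 0) abort("Exposure is constant: design is collinear.")
  if (var(data$g) == 0) abort("Genotype is monomorphic: design is collinear.")
  fml <- stats::reformulate(c("g", "e", "g:e", covariates), response = "y")
  fit <- lm(fml, data = data)
  if (fit$rank < length(coef(fit)) || anyNA(coef(fit))) {
    abort("Rank-deficient interaction design (collinear columns).")
  }
  V <- vcov(fit)
  cf <- coef(fit)
  idx <- c("(Intercept)", "g", "e", "g:e")
  stat <- cf[["g:e"]]^2 / V["g:e", "g:e"]
  structure(list(
    coef = setNames(cf[idx], c("beta0", "beta1", "beta2", "beta3")),
    se = setNames(sqrt(diag(V)[idx]), c("beta0", "beta1", "beta2", "beta3")),
    cov_beta1_beta3 = V["g", "g:e"],
    sigma2 = summary(fit)$sigma^2,
    n = nrow(data),
    test = new_gxe_test(stat, 1L, pchisq(stat, 1, lower.tail = FALSE),
                        "direct"),
    fit = fit
  ), class = "gxe_lm")
}

#' Fit the marginal (GWAS) model to individual-level data
#'
#' Ordinary least squares of `y` on the genotype and optional covariates,
#' omitting the exposure: `y ~ g + covariates`. The genotype coefficient is
#' the marginal effect `alpha`.
#'
#' @inheritParams fit_interaction_model
#' @return A list of class `marginal_lm` with `alpha_hat`, `se_alpha`,
#'   `p_value`, `sigma2`, `n` and the underlying `lm` fit.
#' @export
fit_marginal_model <- function(data, covariates = NULL) {
  data <- check_design(data, needs_e = FALSE)
  if (var(data$g) == 0) abort("Genotype is monomorphic: design is collinear.")
  fml <- stats::reformulate(c("g", covariates), response = "y")
  fit <- lm(fml, data = data)
  if (anyNA(coef(fit))) abort("Rank-deficient marginal design.")
  se <- sqrt(vcov(fit)["g", "g"])
  z <- coef(fit)[["g"]] / se
  structure(list(alpha_hat = coef(fit)[["g"]], se_alpha = se,
                 p_value = 2 * pnorm(-abs(z)),
                 sigma2 = summary(fit)$sigma^2, n = nrow(data), fit = fit),
            class = "marginal_lm")
}

#' Same-sample difference test with exact estimate covariance
#'
#' When the marginal and interaction models are fitted to the very same
#' individuals, the covariance between `alpha_hat` and `beta1_hat` is known
#' exactly from least-squares algebra
#' (\eqn{cov = \sigma^2 e_g'(X'X)^{-1}X'W(W'W)^{-1}e_g} with `X` the
#' marginal and `W` the interaction design), rather than estimated from
#' genome-wide null variants. The resulting
#' \eqn{T_{diff} = (\hat\alpha-\hat\beta_1)^2/var(\hat\alpha-\hat\beta_1)}
#' is asymptotically equivalent to the direct interaction test in this
#' same-sample setting.
#'
#' @inheritParams fit_interaction_model
#' @return A list with the two fitted models (`marginal`, `interaction`),
#'   the exact `cov_alpha_beta1`, and `test` (a one-row `diff` test tibble).
#' @export
same_sample_diff_test <- function(data, covariates = NULL) {
  data <- check_design(data)
  mm <- fit_marginal_model(data, covariates)
  im <- fit_interaction_model(data, covariates)
  X <- stats::model.matrix(mm$fit)
  W <- stats::model.matrix(im$fit)
  s2 <- im$sigma2
  cross <- solve(crossprod(X), crossprod(X, W)) %*%
    solve(crossprod(W))[, "g", drop = FALSE]
  cov_ab <- s2 * cross["g", 1]
  var_alpha <- s2 * solve(crossprod(X))["g", "g"]
  var_beta1 <- im$se["beta1"]^2
  d <- mm$alpha_hat - im$coef[["beta1"]]
  v <- var_alpha + var_beta1 - 2 * cov_ab
  stat <- unname(d^2 / v)
  list(marginal = mm, interaction = im, cov_alpha_beta1 = cov_ab,
       test = new_gxe_test(stat, 1L, pchisq(stat, 1, lower.tail = FALSE),
                           "diff"))
}

#' Empirical correlation between main-effect and interaction statistics
#'
#' Computes the Pearson correlation of the main-effect and interaction
#' z-scores across replicate interaction-model fits. Its large-sample value
#' is \eqn{-\mu_E/\sqrt{\mu_E^2+\sigma_E^2}} (see
#' [main_interaction_corr()]).
#'
#' @param fits Data frame with columns `beta1_hat`, `se_beta1`, `beta3_hat`,
#'   `se_beta3` (one row per replicate), or a list of `gxe_lm` objects.
#' @return Scalar correlation.
#' @export
correlation_main_vs_interaction <- function(fits) {
  if (is.list(fits) && !is.data.frame(fits) &&
      inherits(fits[[1]], "gxe_lm")) {
    fits <- purrr::map_dfr(fits, function(f) {
      tibble::tibble(beta1_hat = f$coef[["beta1"]], se_beta1 = f$se[["beta1"]],
                     beta3_hat = f$coef[["beta3"]], se_beta3 = f$se[["beta3"]])
    })
  }
  cor(fits$beta1_hat / fits$se_beta1, fits$beta3_hat / fits$se_beta3)
}
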