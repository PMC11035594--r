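#' Expected gap between marginal and main genetic effects
#'
#' Closed-form expectation of `alpha - beta1`, the difference between the
#' marginal effect of a variant (model omitting the environment) and its main
#' effect (model including the environment and the GxE product). The gap is
#'
#' \deqn{\alpha - \beta_1 = \frac{\rho\,\sigma_{E1}}{\sigma_{G1}}\beta_2 +
#'   \left(\mu_{E1} + \frac{\rho\,\sigma_{E1}}{\sigma_{G1}}\right)\beta_3,}
#'
#' so it vanishes only when there is neither mediation (`rho = 0`) nor
#' interaction (`beta3 = 0`). Testing `alpha - beta1 = 0` is therefore a test
#' of the combined interaction + mediation contribution.
#'
#' @param beta2 Environment main effect on the trait.
#' @param beta3 GxE interaction effect.
#' @param mu_e1 Mean of the environmental exposure in the GWAS cohort.
#' @param sigma_e1 SD of the exposure in the GWAS cohort.
#' @param sigma_g1 Genotype SD in the GWAS cohort (1 for standardized dosage).
#' @param rho Mediation contribution of the genotype through the exposure
#'   (correlation-scale; 0 means genotype and exposure are independent).
#'
#' @return Numeric, the expected value of `alpha - beta1` (trait units per
#'   allele unit). Vectorized over all arguments.
#' @examples
#' marginal_main_gap(beta2 = 0.1, beta3 = 0.05, mu_e1 = 1) # pure interaction
#' @export
marginal_main_gap <- function(beta2, beta3, mu_e1, sigma_e1 = 1,
                              sigma_g1 = 1, rho = 0) {
  stopifnot(all(sigma_g1 > 0), all(sigma_e1 > 0))
  k <- rho * sigma_e1 / sigma_g1
  k * beta2 + (mu_e1 + k) * beta3
}

#' Expected inverse-variance-weighted slope under sample overlap
#'
#' Expectation of the IVW slope \eqn{\hat\theta} relating marginal (GWAS) to
#' main (GWIS) effects, for valid instruments (no interaction, no mediation),
#' standardized genotypes and unit residual variance:
#'
#' \deqn{E(\hat\theta) = \frac{\sigma_\beta^2 + \frac{n_0}{n_1 n_2}
#'   \left(1 + \mu_{E0}^2/\sigma_{E0}^2\right)}{\sigma_\beta^2 +
#'   \frac{1}{n_2}\left(1 + \mu_{E2}^2/\sigma_{E2}^2\right)}}
#'
#' where \eqn{\sigma_\beta^2} is the mean per-instrument explained trait
#' variance, `n1`/`n2` the GWAS/GWIS sample sizes and `n0` the number of
#' overlapping individuals. The value converges to 1 as `n1, n2` grow at
#' fixed \eqn{\sigma_\beta^2 > 0} and converges slowly when instruments are
#' weak. It is at most 1 whenever `n0 <= min(n1, n2)` and the overlapping
#' samples share the GWIS cohort's exposure distribution
#' (`mu_e0 = mu_e2`, `sigma_e0 = sigma_e2` — the defaults; the overlap is a
#' subset of the GWIS cohort, so this is the regime the bound refers to).
#' Allowing the overlap exposure moments to drift freely from the GWIS ones
#' can push the expression above 1.
#'
#' The derivation assumes standardized genotypes, unit phenotype residual
#' variance and valid instruments; outside that regime the expression still
#' evaluates but the returned attribute `outside_derivation_regime` is set.
#'
#' @param sigma_beta2 Mean per-instrument explained trait variance
#'   \eqn{\sigma_\beta^2 = m^{-1}\sum_j \beta_{1j}^2} (fraction of trait
#'   variance; >= 0).
#' @param n1,n2,n0 GWAS, GWIS and overlap sample sizes (`n0 <= min(n1, n2)`).
#' @param mu_e2,sigma_e2 Exposure mean and SD in the GWIS cohort.
#' @param mu_e0,sigma_e0 Exposure mean and SD among the overlapping samples
#'   (defaults: the GWIS values).
#' @param beta1 Optional vector of per-instrument main effects; when supplied,
#'   `sigma_beta2` is taken as `mean(beta1^2)` (the per-instrument average
#'   form of the same expression).
#'
#' @return Numeric expectation of the slope, vectorized over the parameters.
#' @examples
#' expected_theta(sigma_beta2 = 0.001, n1 = 2e4, n2 = 2e4, n0 = 0,
#'                mu_e2 = 1, sigma_e2 = 1)
#' @export
expected_theta <- function(sigma_beta2, n1, n2, n0 = 0,
                           mu_e2 = 0, sigma_e2 = 1,
                           mu_e0 = mu_e2, sigma_e0 = sigma_e2,
                           beta1 = NULL) {
  if (!is.null(beta1)) sigma_beta2 <- mean(beta1^2)
  stopifnot(all(sigma_beta2 >= 0), all(n1 > 0), all(n2 > 0), all(n0 >= 0),
            all(sigma_e2 > 0), all(sigma_e0 > 0))
  if (any(n0 > pmin(n1, n2))) {
    abort("`n0` (overlap) cannot exceed min(n1, n2).")
  }
  num <- sigma_beta2 + n0 / (n1 * n2) * (1 + mu_e0^2 / sigma_e0^2)
  den <- sigma_beta2 + 1 / n2 * (1 + mu_e2^2 / sigma_e2^2)
  out <- num / den
  attr(out, "outside_derivation_regime") <- any(sigma_beta2 == 0)
  out
}

#' Correlation between main-effect and interaction test statistics
#'
#' In the interaction model the test statistics for the genotype main effect
#' and the GxE product term are negatively correlated through the exposure
#' distribution, with correlation \eqn{-\mu_E / \sqrt{\mu_E^2 + \sigma_E^2}}.
#' The correlation is 0 for a mean-centred exposure and tends to -1 as the
#' exposure mean dominates its SD, which is why interaction tests lose power
#' when the exposure is far from centred.
#'
#' @param mu_e Exposure mean.
#' @param sigma_e Exposure SD (> 0).
#' @return Correlation in (-1, 1), vectorized.
#' @examples
#' main_interaction_corr(1, 1) # -1/sqrt(2)
#' @export
main_interaction_corr <- function(mu_e, sigma_e = 1) {
  stopifnot(all(sigma_e > 0))
  -mu_e / sqrt(mu_e^2 + sigma_e^2)
}
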