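# Vectorized per-variant least squares used by both simulation designs.
# Marginal model y ~ 1 + g, one fit per column of G.
marginal_stats_matrix <- function(G, y) {
  n <- length(y)
  gc <- sweep(G, 2, colMeans(G))
  yc <- y - mean(y)
  sxx <- colSums(gc^2)
  sxy <- colSums(gc * yc)
  syy <- sum(yc^2)
  alpha <- sxy / sxx
  rss <- pmax(syy - alpha * sxy, 0)
  se <- sqrt(rss / (n - 2) / sxx)
  z <- alpha / se
  tibble::tibble(alpha_hat = alpha, se_alpha = se,
                 p_gwas = 2 * pnorm(-abs(z)), n_gwas = n)
}

# Interaction model y ~ 1 + g + e + g:e, one fit per column of G.
gwis_stats_matrix <- function(G, e, y) {
  n <- length(y)
  m <- ncol(G)
  Ge <- G * e
  s1 <- colSums(G);    s2 <- colSums(G^2)
  se_ <- sum(e);       see <- sum(e^2)
  sge <- colSums(Ge);  sg2e <- colSums(G * Ge)
  sge2 <- colSums(Ge * e); sg2e2 <- colSums(Ge^2)
  sy <- sum(y);        syy <- sum(y^2)
  sgy <- colSums(G * y); sey <- sum(e * y)
  sgey <- colSums(Ge * y)
  out <- matrix(NA_real_, m, 8)
  for (j in seq_len(m)) {
    xtx <- matrix(c(n,      s1[j],   se_,     sge[j],
                    s1[j],  s2[j],   sge[j],  sg2e[j],
                    se_,    sge[j],  see,     sge2[j],
                    sge[j], sg2e[j], sge2[j], sg2e2[j]), 4, 4)
    xty <- c(sy, sgy[j], sey, sgey[j])
    b <- tryCatch(solve(xtx, xty), error = function(e) rep(NA_real_, 4))
    if (anyNA(b)) next
    rss <- max(syy - sum(b * xty), 0)
    sig2 <- rss / (n - 4)
    V <- sig2 * solve(xtx)
    out[j, ] <- c(b[2], sqrt(V[2, 2]), b[3], sqrt(V[3, 3]),
                  b[4], sqrt(V[4, 4]), V[2, 4], sig2)
  }
  z3 <- out[, 5] / out[, 6]
  tibble::tibble(beta1_hat = out[, 1], se_beta1 = out[, 2],
                 beta2_hat = out[, 3], se_beta2 = out[, 4],
                 beta3_hat = out[, 5], se_beta3 = out[, 6],
                 p_beta3 = 2 * pnorm(-abs(z3)),
                 cov_beta1_beta3 = out[, 7], n_gwis = n)
}

#' Configuration for simulation design A (many instruments, one GxE variant)
#'
#' Emulates a GWAS/GWIS pair with `m` independent variants: variant 1
#' carries a GxE interaction (`beta3`), variant 2 is a pure null used for
#' type-I error, and the remaining `m - 2` variants are valid instruments
#' for the slope. Genotypes are Binomial(2, p) with p ~ Uniform(0.05, 0.5),
#' scaled by `1/sqrt(2p(1-p))` to unit variance. Main effects are drawn
#' `beta1_j ~ N(0, sigma_beta2)`. Each cohort's exposure is Gaussian with
#' unit SD; overlapping individuals (shared between cohorts) take the GWIS
#' exposure distribution. The trait is
#' `y = sum_j G_j beta1_j + beta2 * e + beta3 * G_1 * e + eps`,
#' `eps ~ N(0, sigma2)`.
#'
#' @param m Number of variants (default 102).
#' @param n1,n2 GWAS and GWIS cohort sizes.
#' @param overlap_fraction Fraction of the smaller cohort shared between the
#'   two cohorts (default 1, fully nested).
#' @param mu_e1,mu_e2 Exposure means in the GWAS-only and GWIS samples.
#' @param sigma_beta2 Mean per-instrument explained trait variance; each
#'   `beta1_j ~ N(0, sigma_beta2)`.
#' @param beta2 Exposure main effect (default 0.1).
#' @param beta3 Interaction effect at variant 1 (default 0.05).
#' @param s Sign scenario for variant 1's main effect relative to the
#'   interaction: 1 same direction, -1 opposite, 0 no main effect.
#' @param sigma2 Residual trait variance (default 1).
#' @return A list of class `sim_config_a`.
#' @export
sim_config_a <- function(m = 102, n1 = 20000, n2 = 20000,
                         overlap_fraction = 1, mu_e1 = 1, mu_e2 = 1,
                         sigma_beta2 = 0.005, beta2 = 0.1, beta3 = 0.05,
                         s = 1, sigma2 = 1) {
  stopifnot(m >= 3, overlap_fraction >= 0, overlap_fraction <= 1,
            sigma_beta2 >= 0, sigma2 > 0, s %in% c(-1, 0, 1))
  structure(as.list(environment()), class = "sim_config_a")
}

#' Simulate design A: individual-level cohorts and summary statistics
#'
#' For each replicate, draws genotypes and cohort-specific exposures, builds
#' the trait, fits the marginal model per variant in the GWAS cohort and the
#' interaction model per variant in the GWIS cohort, and returns the
#' stacked summary statistics with truth labels (`"interaction"` for
#' variant 1, `"null"` otherwise; variant 1 is labelled `"null"` when
#' `beta3 = 0`). The slope is conventionally fitted on variants 3..m
#' (`instrument_ids` attribute); variants 1 and 2 serve as the power and
#' type-I probes.
#'
#' @param config A [sim_config_a()].
#' @param n_reps Number of replicates.
#' @param seed Optional integer seed.
#' @return A tibble with one row per variant per replicate (`rep`,
#'   `variant_id`, `truth`, `eaf`, GWAS and GWIS summary columns).
#'   Attributes: `env` (realized exposure means/SDs per cohort, averaged
#'   over replicates), `config`, `instrument_ids`.
#' @export
simulate_design_a <- function(config = sim_config_a(), n_reps = 1,
                              seed = NULL) {
  stopifnot(inherits(config, "sim_config_a"))
  if (!is.null(seed)) set.seed(seed)
  cf <- config
  n0 <- round(cf$overlap_fraction * min(cf$n1, cf$n2))
  n_tot <- cf$n1 + cf$n2 - n0
  idx_gwas <- seq_len(cf$n1)
  idx_gwis <- seq(cf$n1 - n0 + 1, cf$n1 + cf$n2 - n0)
  reps <- vector("list", n_reps)
  env_acc <- matrix(0, n_reps, 6)
  for (r in seq_len(n_reps)) {
    p <- runif(cf$m, 0.05, 0.5)
    G <- matrix(rbinom(n_tot * cf$m, 2, rep(p, each = n_tot)), n_tot, cf$m)
    G <- sweep(G, 2, sqrt(2 * p * (1 - p)), "/")
    e <- numeric(n_tot)
    n_only1 <- cf$n1 - n0
    if (n_only1 > 0) e[seq_len(n_only1)] <- rnorm(n_only1, cf$mu_e1, 1)
    e[idx_gwis] <- rnorm(length(idx_gwis), cf$mu_e2, 1)
    beta1 <- rnorm(cf$m, 0, sqrt(cf$sigma_beta2))
    beta1[1] <- cf$s * abs(beta1[1])
    y <- as.vector(G %*% beta1) + cf$beta2 * e +
      cf$beta3 * G[, 1] * e + rnorm(n_tot, 0, sqrt(cf$sigma2))
    gw <- marginal_stats_matrix(G[idx_gwas, , drop = FALSE], y[idx_gwas])
    wi <- gwis_stats_matrix(G[idx_gwis, , drop = FALSE], e[idx_gwis],
                            y[idx_gwis])
    e1 <- e[idx_gwas]; e2 <- e[idx_gwis]; e0 <- e[intersect(idx_gwas, idx_gwis)]
    env_acc[r, ] <- c(mean(e1), sd(e1), mean(e2), sd(e2),
                      if (n0 > 0) c(mean(e0), sd(e0)) else c(NA, NA))
    reps[[r]] <- dplyr::bind_cols(
      tibble::tibble(rep = r, variant_id = paste0("v", seq_len(cf$m)),
                     chrom = "1", pos = seq_len(cf$m) * 2e6,
                     eaf = p,
                     truth = c(if (cf$beta3 != 0) "interaction" else "null",
                               rep("null", cf$m - 1))),
      gw, wi)
  }
  out <- dplyr::bind_rows(reps)
  env <- colMeans(env_acc)
  attr(out, "env") <- tibble::tibble(mu_e1 = env[1], sigma_e1 = env[2],
                                     mu_e2 = env[3], sigma_e2 = env[4],
                                     mu_e0 = env[5], sigma_e0 = env[6])
  attr(out, "config") <- cf
  attr(out, "instrument_ids") <- paste0("v", seq(3, cf$m))
  out
}

#' Configuration for simulation design B (20 variants, nested cohorts)
#'
#' Emulates a nested-cohort design with 20 independent Binomial(2, 0.3)
#' variants, standardized by `1/sqrt(2 * 0.3 * 0.7)` without mean
#' correction (the genotype keeps a nonzero mean, which feeds the
#' marginal-main gap). Variant 1 is causal. Three scenarios:
#' `"null"` (no mediation, no interaction), `"mediation"` (the exposure is
#' `0.05 * G + N(env_mean, 0.9975)`, so the genotype explains 0.25% of the
#' exposure variance), and `"both"` (mediation plus an interaction effect
#' of 0.1). The trait is `y = 0.1 * G + gamma * e (+ 0.1 * G * e) +
#' N(0, noise_var)`. The GWIS cohort (`n2`) is always nested in the GWAS
#' cohort (`n1 >= n2`); non-overlapping individuals get an exposure mean
#' `nonoverlap_env_mean_factor` times the GWIS mean.
#'
#' @param scenario One of `"null"`, `"mediation"`, `"both"`.
#' @param gamma Exposure effect on the trait (1 or sqrt(5) in the reference
#'   settings).
#' @param n1,n2 GWAS and GWIS cohort sizes (`n1 >= n2`).
#' @param m Number of variants (default 20).
#' @param maf Minor allele frequency of every variant (default 0.3).
#' @param env_mean Exposure mean in the GWIS cohort (default 1; 0.5 and 2
#'   are the swept presets).
#' @param nonoverlap_env_mean_factor Multiplier on `env_mean` for GWAS-only
#'   individuals (default 1.5).
#' @param mediation_coef Exposure-on-genotype coefficient under mediation
#'   (default 0.05).
#' @param main_effect Causal variant's main effect (default 0.1).
#' @param interaction_effect Interaction effect under `"both"`
#'   (default 0.1).
#' @param noise_var Residual trait variance (default 10).
#' @return A list of class `sim_config_b`.
#' @export
sim_config_b <- function(scenario = c("null", "mediation", "both"),
                         gamma = 1, n1 = 20000, n2 = 20000, m = 20,
                         maf = 0.3, env_mean = 1,
                         nonoverlap_env_mean_factor = 1.5,
                         mediation_coef = 0.05, main_effect = 0.1,
                         interaction_effect = 0.1, noise_var = 10) {
  scenario <- match.arg(scenario)
  stopifnot(n1 >= n2, m >= 2, maf > 0, maf < 1, noise_var > 0)
  structure(as.list(environment()), class = "sim_config_b")
}

#' Simulate design B: mediation and interaction with nested cohorts
#'
#' See [sim_config_b()] for the generative model. Returns stacked summary
#' statistics in the same shape as [simulate_design_a()]; the causal
#' variant's truth label is `"null"`, `"mediation"` or `"both"` according
#' to the scenario, all other variants are `"null"`.
#'
#' @param config A [sim_config_b()].
#' @param n_reps Number of replicates.
#' @param seed Optional integer seed.
#' @return A tibble as in [simulate_design_a()]; attribute
#'   `"instrument_ids"` names all variants (the slope is fitted on the full
#'   set with iterative outlier removal in this design).
#' @export
simulate_design_b <- function(config = sim_config_b(), n_reps = 1,
                              seed = NULL) {
  stopifnot(inherits(config, "sim_config_b"))
  if (!is.null(seed)) set.seed(seed)
  cf <- config
  n1 <- cf$n1; n2 <- cf$n2; m <- cf$m
  idx_gwis <- seq_len(n2)
  scale_g <- sqrt(2 * cf$maf * (1 - cf$maf))
  mediate <- cf$scenario %in% c("mediation", "both")
  interact <- cf$scenario == "both"
  e_sd <- if (mediate) sqrt(0.9975) else 1
  reps <- vector("list", n_reps)
  env_acc <- matrix(0, n_reps, 6)
  for (r in seq_len(n_reps)) {
    G <- matrix(rbinom(n1 * m, 2, cf$maf), n1, m) / scale_g
    mu_e <- c(rep(cf$env_mean, n2),
              rep(cf$env_mean * cf$nonoverlap_env_mean_factor, n1 - n2))
    e <- rnorm(n1, mu_e, e_sd)
    if (mediate) e <- e + cf$mediation_coef * G[, 1]
    y <- cf$main_effect * G[, 1] + cf$gamma * e +
      (if (interact) cf$interaction_effect * G[, 1] * e else 0) +
      rnorm(n1, 0, sqrt(cf$noise_var))
    gw <- marginal_stats_matrix(G, y)
    wi <- gwis_stats_matrix(G[idx_gwis, , drop = FALSE], e[idx_gwis],
                            y[idx_gwis])
    e0 <- e[idx_gwis]
    env_acc[r, ] <- c(mean(e), sd(e), mean(e0), sd(e0), mean(e0), sd(e0))
    truth1 <- if (interact) "both" else if (mediate) "mediation" else "null"
    reps[[r]] <- dplyr::bind_cols(
      tibble::tibble(rep = r, variant_id = paste0("v", seq_len(m)),
                     chrom = "1", pos = seq_len(m) * 2e6,
                     eaf = cf$maf,
                     truth = c(truth1, rep("null", m - 1))),
      gw, wi)
  }
  out <- dplyr::bind_rows(reps)
  env <- colMeans(env_acc)
  attr(out, "env") <- tibble::tibble(mu_e1 = env[1], sigma_e1 = env[2],
                                     mu_e2 = env[3], sigma_e2 = env[4],
                                     mu_e0 = env[5], sigma_e0 = env[6])
  attr(out, "config") <- cf
  attr(out, "instrument_ids") <- paste0("v", seq_len(m))
  out
}

#' Draw summary statistics directly from their asymptotic laws
#'
#' Fast alternative to the individual-level designs: per-variant marginal
#' and main effect estimates are drawn jointly from the bivariate normal
#' implied by the sampling theory on the standardized scale
#' (`var(alpha_hat) = sigma2/n1`,
#' `var(beta1_hat) = sigma2 * (1 + mu_e2^2/sigma_e2^2)/n2`, and the
#' overlap-induced cross-covariance `cov = sigma2 * n0/(n1 n2)` — the
#' influence-function covariance of the two least-squares estimates over
#' the shared individuals, which keeps the implied correlation inside
#' [-1, 1] at any overlap), with the true marginal
#' effect `alpha = beta1 +` [marginal_main_gap()]. Interaction estimates
#' are drawn with `var(beta3_hat) = 1/(n2 sigma_e2^2)` and the
#' main-interaction correlation of [main_interaction_corr()]. Roughly two
#' orders of magnitude faster than the individual-level path and
#' distributionally matched to it.
#'
#' @param truth Data frame with columns `variant_id`, `beta1`, and
#'   optionally `beta2`, `beta3`, `rho` (defaults 0).
#' @param n1,n2,n0 GWAS, GWIS and overlap sample sizes.
#' @param mu_e1,sigma_e1 GWAS-cohort exposure mean and SD.
#' @param mu_e2,sigma_e2,mu_e0,sigma_e0 GWIS-cohort and overlap exposure
#'   moments (overlap defaults to the GWIS values; `mu_e0`/`sigma_e0` are
#'   accepted for interface completeness but the cross-covariance does not
#'   depend on them).
#' @param sigma2 Residual trait variance on the standardized scale
#'   (default 1).
#' @param seed Optional integer seed.
#' @return A harmonized-shape tibble (`alpha_hat`, `se_alpha`, `p_gwas`,
#'   `beta1_hat`, `se_beta1`, `beta3_hat`, `se_beta3`, `p_beta3`, sample
#'   sizes, `truth` labels) ready for [screen_genome()] and friends;
#'   attribute `"overlap_r"` carries the implied estimate correlation.
#' @export
simulate_sumstats_fast <- function(truth, n1, n2, n0 = 0,
                                   mu_e1 = 0, sigma_e1 = 1,
                                   mu_e2 = mu_e1, sigma_e2 = sigma_e1,
                                   mu_e0 = mu_e2, sigma_e0 = sigma_e2,
                                   sigma2 = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n0 <= min(n1, n2))
  m <- nrow(truth)
  col_or <- function(nm, default) {
    if (nm %in% names(truth)) truth[[nm]] else default
  }
  beta1 <- truth$beta1
  beta2 <- col_or("beta2", rep(0, m))
  beta3 <- col_or("beta3", rep(0, m))
  rho <- col_or("rho", rep(0, m))
  alpha <- beta1 + marginal_main_gap(beta2, beta3, mu_e1, sigma_e1, 1, rho)

  va <- sigma2 / n1
  vb <- sigma2 * (1 + mu_e2^2 / sigma_e2^2) / n2
  cab <- sigma2 * n0 / (n1 * n2)
  r_ab <- cab / sqrt(va * vb)
  # conditional draw: alpha_hat | beta1_hat is normal
  b1_hat <- rnorm(m, beta1, sqrt(vb))
  a_mean <- alpha + cab / vb * (b1_hat - beta1)
  a_hat <- rnorm(m, a_mean, sqrt(va - cab^2 / vb))

  v3 <- sigma2 / (n2 * sigma_e2^2)
  r13 <- main_interaction_corr(mu_e2, sigma_e2)
  b3_mean <- beta3 + r13 * sqrt(v3 / vb) * (b1_hat - beta1)
  b3_hat <- rnorm(m, b3_mean, sqrt(v3 * (1 - r13^2)))

  out <- tibble::tibble(
    variant_id = as.character(truth$variant_id),
    chrom = "1", pos = seq_len(m) * 2e6,
    truth = col_or("truth", ifelse(beta3 != 0 | rho != 0,
                                   "interaction", "null")),
    alpha_hat = a_hat, se_alpha = sqrt(va),
    p_gwas = 2 * pnorm(-abs(a_hat / sqrt(va))), n_gwas = n1,
    beta1_hat = b1_hat, se_beta1 = sqrt(vb),
    beta3_hat = b3_hat, se_beta3 = sqrt(v3),
    p_beta3 = 2 * pnorm(-abs(b3_hat / sqrt(v3))), n_gwis = n2)
  attr(out, "overlap_r") <- r_ab
  out
}

#' Type-I error and power of the tests on simulated replicates
#'
#' For each replicate of a design-A/B output: fits the slope on the
#' instrument set (iterative outlier removal), applies the MR-GxE test to
#' every variant, reads the direct test from the interaction model, and
#' runs the two-step procedure (screen at `alpha/m`, then direct test on
#' survivors at `alpha/X` with `X` the realized survivor count). Rejection
#' frequencies are tabulated per test and truth class with exact binomial
#' 95% confidence intervals. The overlap correlation is estimated once by
#' pooling the null variants' marginal/main z-score pairs across
#' replicates, unless supplied.
#'
#' @param sims Output of [simulate_design_a()], [simulate_design_b()] or a
#'   compatible stacked tibble with a `rep` column and truth labels.
#' @param alpha Nominal family-wise level (default 0.05).
#' @param correction `"bonferroni"` (each test corrected for the number of
#'   variants per replicate) or `"none"` (per-variant level `alpha`).
#' @param instrument_ids Variant ids used to fit the slope; defaults to the
#'   `instrument_ids` attribute of `sims`.
#' @param overlap_r Overlap correlation; estimated from pooled null
#'   variants when `NULL`.
#' @param tests Character subset of `c("mr_gxe", "direct", "twostep")`.
#' @return A tibble with columns `test`, `truth`, `n_reps`, `rejections`,
#'   `rate`, `ci_lo`, `ci_hi`; attribute `"overlap_r"` and
#'   `"theta_hat_mean"` record the nuisance estimates.
#' @export
evaluate_error_rates <- function(sims, alpha = 0.05,
                                 correction = c("bonferroni", "none"),
                                 instrument_ids = NULL, overlap_r = NULL,
                                 tests = c("mr_gxe", "direct", "twostep")) {
  correction <- match.arg(correction)
  tests <- match.arg(tests, several.ok = TRUE)
  instrument_ids <- instrument_ids %||% attr(sims, "instrument_ids")
  if (is.null(instrument_ids)) abort("No instrument ids available.")
  if (nrow(sims) == 0) abort("Zero replicates supplied.")

  if (is.null(overlap_r)) {
    nulls <- sims[sims$truth == "null", ]
    z_a <- nulls$alpha_hat / nulls$se_alpha
    z_b <- nulls$beta1_hat / nulls$se_beta1
    keep <- 2 * pnorm(-abs(z_a)) > 0.05 & 2 * pnorm(-abs(z_b)) > 0.05
    overlap_r <- if (sum(keep) >= 50) cor(z_a[keep], z_b[keep]) else 0
  }

  rep_ids <- unique(sims$rep)
  m <- sum(sims$rep == rep_ids[1])
  level <- if (correction == "bonferroni") alpha / m else alpha
  thetas <- numeric(length(rep_ids))
  res <- vector("list", length(rep_ids))
  for (k in seq_along(rep_ids)) {
    d <- sims[sims$rep == rep_ids[k], ]
    fit <- imrp_fit(d[d$variant_id %in% instrument_ids, ],
                    overlap_r = overlap_r)
    thetas[k] <- fit$theta_hat
    p_mr <- test_mr_gxe(d$alpha_hat, d$se_alpha, d$beta1_hat, d$se_beta1,
                        theta_hat = fit$theta_hat,
                        overlap_r = overlap_r)$p_value
    p_dir <- d$p_beta3
    rej <- tibble::tibble(rep = rep_ids[k], variant_id = d$variant_id,
                          truth = d$truth,
                          mr_gxe = p_mr < level, direct = p_dir < level)
    surv <- which(p_mr < level)
    x <- length(surv)
    rej$twostep <- FALSE
    if (x > 0) rej$twostep[surv] <- p_dir[surv] < alpha / x
    res[[k]] <- rej
  }
  long <- dplyr::bind_rows(res) |>
    tidyr::pivot_longer(dplyr::all_of(tests), names_to = "test",
                        values_to = "reject")
  out <- long |>
    dplyr::group_by(.data$test, .data$truth) |>
    dplyr::summarise(n_reps = dplyr::n(),
                     rejections = sum(.data$reject), .groups = "drop") |>
    dplyr::mutate(rate = .data$rejections / .data$n_reps)
  ci <- purrr::map2_dfr(out$rejections, out$n_reps, function(x, n) {
    b <- stats::binom.test(x, n)$conf.int
    tibble::tibble(ci_lo = b[1], ci_hi = b[2])
  })
  out <- dplyr::bind_cols(out, ci)
  attr(out, "overlap_r") <- overlap_r
  attr(out, "theta_hat_mean") <- mean(thetas)
  out
}
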