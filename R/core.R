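#' Correlation between GWAS and GWIS estimates induced by sample overlap
#'
#' When the GWAS and GWIS cohorts share individuals, the marginal and main
#' effect estimates of the same variant are correlated even under the null.
#' The correlation is estimated empirically as the Pearson correlation of
#' the two z-score vectors over variants that are null in both sources
#' (both p-values above `null_p_threshold`), and is clipped to [-1, 1].
#'
#' @param table A harmonized table; needs `alpha_hat`/`se_alpha`,
#'   `beta1_hat`/`se_beta1` and `p_gwas` (a main-effect p is derived from
#'   the z-score when no `p_beta1` column is present).
#' @param null_p_threshold Variants with both p-values above this threshold
#'   form the null set (default 0.05).
#' @param min_null Minimum size of the null set (default 200); fewer null
#'   variants is an error advising a lower floor or an explicit `r`.
#' @return Scalar correlation in [-1, 1].
#' @export
estimate_overlap_correlation <- function(table, null_p_threshold = 0.05,
                                         min_null = 200) {
  z_a <- table$alpha_hat / table$se_alpha
  z_b <- table$beta1_hat / table$se_beta1
  p_a <- if ("p_gwas" %in% names(table)) table$p_gwas else
    2 * pnorm(-abs(z_a))
  p_b <- if ("p_beta1" %in% names(table)) table$p_beta1 else
    2 * pnorm(-abs(z_b))
  keep <- !is.na(p_a) & !is.na(p_b) &
    p_a > null_p_threshold & p_b > null_p_threshold
  if (sum(keep) < min_null) {
    abort(paste0("Only ", sum(keep), " null variants (need >= ", min_null,
                 "); lower `min_null` or supply the overlap correlation ",
                 "directly (r = 0 for disjoint cohorts)."))
  }
  if (sd(z_a[keep]) == 0 || sd(z_b[keep]) == 0) {
    abort("Degenerate z-scores in the null set (zero variance).")
  }
  r <- cor(z_a[keep], z_b[keep])
  max(-1, min(1, r))
}

#' Instrument selection settings
#'
#' @param p_threshold GWAS significance threshold for candidate instruments
#'   (default 5e-8).
#' @param prune_window_bp Pruning window half-width in bp (default 500 kb).
#' @param prune_r2 Maximum allowed LD r-squared between kept instruments
#'   within the window (default 0.1).
#' @param gc_correct Apply genomic-control correction to the GWAS p-values
#'   (chi-square statistics divided by the genomic inflation factor computed
#'   from the full table) before thresholding?
#' @return A list of class `instrument_selection`.
#' @export
instrument_selection <- function(p_threshold = 5e-8, prune_window_bp = 5e5,
                                 prune_r2 = 0.1, gc_correct = TRUE) {
  stopifnot(p_threshold > 0, p_threshold < 1, prune_r2 > 0, prune_r2 < 1,
            prune_window_bp >= 0)
  structure(list(p_threshold = p_threshold,
                 prune_window_bp = prune_window_bp,
                 prune_r2 = prune_r2, gc_correct = isTRUE(gc_correct)),
            class = "instrument_selection")
}

#' Select independent genome-wide significant instruments
#'
#' Candidates are variants passing the GWAS significance threshold (after
#' optional genomic-control correction of the p-values). Candidates are then
#' greedily pruned in order of ascending p-value (ties broken by position): a
#' variant is kept iff its LD r-squared with every already-kept variant
#' within `prune_window_bp` on the same chromosome is below `prune_r2`.
#'
#' @param table A harmonized table with `p_gwas`, `chrom`, `pos`.
#' @param sel An [instrument_selection()].
#' @param ld_ref Either a numeric genotype matrix (samples x variants, with
#'   column names matching `variant_id`) from which r-squared is computed as
#'   the squared Pearson correlation of dosages, or a function
#'   `f(id1, id2) -> r2`, or `NULL` for distance-only pruning (keeps one
#'   variant per window, with a warning).
#' @return Character vector of instrument variant ids.
#' @export
select_instruments <- function(table, sel = instrument_selection(),
                               ld_ref = NULL) {
  p <- table$p_gwas
  if (sel$gc_correct) {
    lam <- genomic_lambda(p_values = p)
    if (lam > 1) p <- pchisq(qchisq(p, df = 1, lower.tail = FALSE) / lam,
                             df = 1, lower.tail = FALSE)
  }
  cand <- table[!is.na(p) & p < sel$p_threshold, ]
  cand$p_adj <- p[!is.na(p) & p < sel$p_threshold]
  if (nrow(cand) == 0) abort("No variants pass the instrument p-threshold.")
  cand <- cand[order(cand$p_adj, cand$pos), ]

  r2_fun <- NULL
  if (is.matrix(ld_ref)) {
    r2_fun <- function(a, b) {
      if (!all(c(a, b) %in% colnames(ld_ref))) return(NA_real_)
      cor(ld_ref[, a], ld_ref[, b])^2
    }
  } else if (is.function(ld_ref)) {
    r2_fun <- ld_ref
  } else if (!is.null(ld_ref)) {
    abort("`ld_ref` must be a genotype matrix, a function, or NULL.")
  }
  if (is.null(r2_fun)) {
    warn("No LD reference supplied; pruning by distance only.")
  }

  kept <- character(0)
  kept_chrom <- character(0)
  kept_pos <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    id <- cand$variant_id[i]
    near <- which(kept_chrom == cand$chrom[i] &
                    abs(kept_pos - cand$pos[i]) <= sel$prune_window_bp)
    ok <- if (length(near) == 0) {
      TRUE
    } else if (is.null(r2_fun)) {
      FALSE # distance-only: one variant per window
    } else {
      r2 <- vapply(kept[near], function(k) r2_fun(id, k), numeric(1))
      all(is.na(r2) | r2 < sel$prune_r2)
    }
    if (ok) {
      kept <- c(kept, id)
      kept_chrom <- c(kept_chrom, cand$chrom[i])
      kept_pos <- c(kept_pos, cand$pos[i])
    }
  }
  kept
}

new_mr_fit <- function(theta_hat, se_theta, instruments, removed, overlap_r,
                       n_iter, trace = numeric(0)) {
  structure(list(theta_hat = theta_hat, se_theta = se_theta,
                 instruments = instruments, removed = removed,
                 overlap_r = overlap_r, n_iter = n_iter, trace = trace),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, ...) {
  cat("MR slope fit (marginal on main effects)\n")
  cat(sprintf("  theta_hat = %.4f (SE %.4f)\n", x$theta_hat, x$se_theta))
  cat(sprintf("  instruments: %d kept, %d removed as interaction/mediation\n",
              length(x$instruments), length(x$removed)))
  cat(sprintf("  overlap r = %.3f, iterations = %d\n", x$overlap_r, x$n_iter))
  invisible(x)
}

#' Inverse-variance-weighted slope of marginal on main effects
#'
#' Fits the slope theta minimizing the weighted least-squares objective
#' \eqn{m^{-1}\sum_j (\hat\alpha_j - \hat\beta_{1j}\theta)^2 /
#' var(\hat\alpha_j)}, whose closed form is
#' \eqn{\hat\theta = \sum_j w_j \hat\alpha_j\hat\beta_{1j} /
#' \sum_j w_j \hat\beta_{1j}^2} with \eqn{w_j = 1/var(\hat\alpha_j)}.
#' The standard error is the sandwich form over instruments,
#' \eqn{\sqrt{\sum_j w_j^2\hat\beta_{1j}^2(\hat\alpha_j -
#' \hat\theta\hat\beta_{1j})^2} / \sum_j w_j\hat\beta_{1j}^2}.
#'
#' @param table Data frame restricted to the instruments, with `alpha_hat`,
#'   `se_alpha`, `beta1_hat`, `se_beta1` and (optionally) `variant_id`.
#' @param overlap_r Overlap-induced correlation between the two estimate
#'   vectors (carried into the fit object for downstream tests).
#' @return An object of class `mr_fit`.
#' @export
fit_ivw_theta <- function(table, overlap_r = 0) {
  stopifnot(nrow(table) >= 1, all(table$se_alpha > 0))
  w <- 1 / table$se_alpha^2
  denom <- sum(w * table$beta1_hat^2)
  if (denom == 0) abort("All main effects are zero: the slope is undefined.")
  theta <- sum(w * table$alpha_hat * table$beta1_hat) / denom
  resid <- table$alpha_hat - theta * table$beta1_hat
  se <- sqrt(sum(w^2 * table$beta1_hat^2 * resid^2)) / denom
  ids <- if ("variant_id" %in% names(table)) table$variant_id else
    as.character(seq_len(nrow(table)))
  new_mr_fit(theta, se, instruments = ids, removed = character(0),
             overlap_r = overlap_r, n_iter = 1L, trace = theta)
}

#' Iterative slope fit with removal of interaction/mediation outliers
#'
#' Alternates between refitting the IVW slope and testing every current
#' instrument for departure from the fitted line with [test_mr_gxe()];
#' instruments with p below the removal threshold are excluded and the loop
#' repeats until the instrument set stabilizes or `max_iter` is reached.
#' This mirrors iterative pleiotropy-aware MR estimation: variants carrying
#' interaction or mediation act like horizontally pleiotropic instruments
#' and are excluded from the slope.
#'
#' By default each instrument is tested at the unadjusted `removal_alpha`
#' (0.05), as in standard iterative pleiotropy estimation. A liberal
#' threshold is deliberate: a strong contaminated instrument drags the
#' slope toward itself and inflates the variance of its own outlier test
#' (masking), so a Bonferroni-corrected removal bar can fail to evict it
#' from small instrument sets; the cost — occasionally dropping a few valid
#' instruments — barely moves the inverse-variance-weighted slope.
#' `bonferroni = TRUE` divides the bar by the current set size for users
#' who want conservative removal on large, clean instrument panels.
#'
#' @inheritParams fit_ivw_theta
#' @param removal_alpha Per-instrument removal level (default 0.05).
#' @param max_iter Maximum number of refit iterations (default 50).
#' @param bonferroni Divide the removal level by the current instrument
#'   count (default `FALSE`).
#' @return An `mr_fit` with the removed variant ids, the per-iteration
#'   slope trace and the iteration count.
#' @export
imrp_fit <- function(table, overlap_r = 0, removal_alpha = 0.05,
                     max_iter = 50L, bonferroni = FALSE) {
  stopifnot(removal_alpha > 0, removal_alpha < 1, max_iter >= 1)
  ids <- if ("variant_id" %in% names(table)) table$variant_id else
    as.character(seq_len(nrow(table)))
  table$variant_id <- ids
  current <- table
  removed <- character(0)
  trace <- numeric(0)
  fit <- NULL
  for (it in seq_len(max_iter)) {
    if (nrow(current) == 0) {
      abort("All instruments were removed; cannot fit the slope.")
    }
    fit <- fit_ivw_theta(current, overlap_r = overlap_r)
    trace <- c(trace, fit$theta_hat)
    p <- test_mr_gxe(current$alpha_hat, current$se_alpha,
                     current$beta1_hat, current$se_beta1,
                     theta_hat = fit$theta_hat,
                     overlap_r = overlap_r)$p_value
    bar <- if (bonferroni) removal_alpha / nrow(current) else removal_alpha
    drop <- p < bar
    if (!any(drop)) {
      return(new_mr_fit(fit$theta_hat, fit$se_theta,
                        instruments = current$variant_id, removed = removed,
                        overlap_r = overlap_r, n_iter = it, trace = trace))
    }
    removed <- c(removed, current$variant_id[drop])
    current <- current[!drop, ]
  }
  new_mr_fit(fit$theta_hat, fit$se_theta, instruments = current$variant_id,
             removed = removed, overlap_r = overlap_r, n_iter = max_iter,
             trace = trace)
}

new_gxe_test <- function(statistic, df, p_value, label) {
  tibble::tibble(statistic = statistic, df = df, p_value = p_value,
                 label = label)
}

residual_variance <- function(se_alpha, se_beta1, theta_hat, overlap_r) {
  v <- se_alpha^2 + theta_hat^2 * se_beta1^2 -
    2 * theta_hat * overlap_r * se_alpha * se_beta1
  if (any(v <= 0)) {
    abort(paste0("Non-positive variance for alpha_hat - theta*beta1_hat; ",
                 "overlap correlation r = ", format(overlap_r),
                 " is too extreme for theta = ", format(theta_hat), "."))
  }
  v
}

#' MR-based test for GxE interaction and mediation
#'
#' Tests whether a variant departs from the fitted marginal-vs-main
#' regression line:
#' \deqn{T = \frac{(\hat\alpha - \hat\theta\hat\beta_1)^2}
#'   {se_\alpha^2 + \hat\theta^2 se_{\beta_1}^2 -
#'    2\hat\theta\, r\, se_\alpha se_{\beta_1}} \sim \chi^2_1,}
#' where `r` is the overlap-induced correlation between the two estimates.
#' Departure indicates GxE interaction and/or mediation through the
#' exposure, the analogue of horizontal pleiotropy in MR. The slope is
#' treated as fixed; `propagate_se_theta = TRUE` adds the delta-method term
#' `beta1_hat^2 * se_theta^2` to the denominator instead.
#'
#' @param alpha_hat,se_alpha Marginal effect estimate and SE (GWAS).
#' @param beta1_hat,se_beta1 Main effect estimate and SE (GWIS).
#' @param theta_hat Fitted slope (e.g. from [imrp_fit()]).
#' @param overlap_r Overlap correlation (0 for disjoint cohorts).
#' @param propagate_se_theta,se_theta Optionally propagate the slope's own
#'   estimation error (off by default).
#' @return A tibble with `statistic`, `df` (= 1), two-sided `p_value` and
#'   `label`; vectorized over the effect arguments.
#' @export
test_mr_gxe <- function(alpha_hat, se_alpha, beta1_hat, se_beta1,
                        theta_hat, overlap_r = 0,
                        propagate_se_theta = FALSE, se_theta = 0) {
  stopifnot(all(se_alpha > 0), all(se_beta1 > 0))
  v <- residual_variance(se_alpha, se_beta1, theta_hat, overlap_r)
  if (propagate_se_theta) v <- v + beta1_hat^2 * se_theta^2
  stat <- (alpha_hat - theta_hat * beta1_hat)^2 / v
  new_gxe_test(stat, 1L, pchisq(stat, df = 1, lower.tail = FALSE), "MR_GxE")
}

#' Difference test between marginal and main effects
#'
#' The slope-1 special case of [test_mr_gxe()]:
#' \eqn{T_{diff} = (\hat\alpha - \hat\beta_1)^2 / var(\hat\alpha -
#' \hat\beta_1)}. When the GWAS and GWIS are run on the same data this is
#' equivalent to the direct interaction test, but it is sensitive to
#' between-study heterogeneity (phenotype transformations, covariate sets,
#' confounding), which is why the screen uses the fitted slope instead.
#'
#' @inheritParams test_mr_gxe
#' @return A tibble as in [test_mr_gxe()] with label `"diff"`.
#' @export
test_diff <- function(alpha_hat, se_alpha, beta1_hat, se_beta1,
                      overlap_r = 0) {
  out <- test_mr_gxe(alpha_hat, se_alpha, beta1_hat, se_beta1,
                     theta_hat = 1, overlap_r = overlap_r)
  out$label <- "diff"
  out
}

#' Interaction effect implied by the marginal-main gap
#'
#' Converts a variant's departure from the fitted line into an interaction
#' effect estimate on the trait scale,
#' \eqn{(\hat\alpha - \hat\theta\hat\beta_1)/\mu_{E1}}, valid when there is
#' no mediation. Its SE is the residual SD divided by `|mu_e1|`; a near-zero
#' exposure mean leaves the interaction unidentifiable from the gap.
#'
#' @inheritParams test_mr_gxe
#' @param mu_e1 Exposure mean in the GWAS cohort (non-zero).
#' @return A tibble with `estimate` and `se`, vectorized.
#' @export
estimate_interaction_effect <- function(alpha_hat, se_alpha, beta1_hat,
                                        se_beta1, theta_hat, mu_e1,
                                        overlap_r = 0) {
  if (any(mu_e1 == 0)) {
    abort(paste0("mu_e1 = 0: the interaction effect is not identifiable ",
                 "from the marginal-main gap."))
  }
  v <- residual_variance(se_alpha, se_beta1, theta_hat, overlap_r)
  tibble::tibble(estimate = (alpha_hat - theta_hat * beta1_hat) / mu_e1,
                 se = sqrt(v) / abs(mu_e1))
}

#' Genomic-control inflation factor
#'
#' Ratio of the median observed 1-df chi-square statistic to the null
#' chi-square(1) median (0.4549364...). Values near 1 indicate a
#' well-calibrated genome-wide test.
#'
#' @param statistics Vector of chi-square(1) statistics, or
#' @param p_values vector of two-sided p-values (converted to chi-square).
#' @return Scalar lambda.
#' @export
genomic_lambda <- function(statistics = NULL, p_values = NULL) {
  if (is.null(statistics)) {
    if (is.null(p_values)) abort("Supply statistics or p_values.")
    statistics <- qchisq(p_values, df = 1, lower.tail = FALSE)
  }
  statistics <- statistics[is.finite(statistics)]
  if (length(statistics) == 0) abort("No finite statistics supplied.")
  median(statistics) / qchisq(0.5, df = 1)
}
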