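#' Genome-wide MR-GxE screen
#'
#' Applies [test_mr_gxe()] at the fitted slope to every variant of a
#' harmonized table, returning the table with screening statistic and
#' p-value columns appended, together with the genomic-control inflation
#' factor of the screen as attribute `"lambda"`.
#'
#' @param table A harmonized table.
#' @param fit An `mr_fit` from [fit_ivw_theta()] or [imrp_fit()] (supplies
#'   the slope and the overlap correlation).
#' @return The input tibble with `mr_gxe_stat` and `mr_gxe_p` columns,
#'   classed `mrgxe_screen`; attribute `"lambda"` carries the genomic
#'   inflation of the screen.
#' @export
screen_genome <- function(table, fit) {
  stopifnot(inherits(fit, "mr_fit"))
  table <- tibble::as_tibble(table)
  if (nrow(table) == 0) {
    out <- dplyr::mutate(table, mr_gxe_stat = numeric(0),
                         mr_gxe_p = numeric(0))
    attr(out, "lambda") <- NA_real_
    return(structure(out, class = c("mrgxe_screen", class(out))))
  }
  res <- test_mr_gxe(table$alpha_hat, table$se_alpha,
                     table$beta1_hat, table$se_beta1,
                     theta_hat = fit$theta_hat, overlap_r = fit$overlap_r)
  out <- dplyr::mutate(table, mr_gxe_stat = res$statistic,
                       mr_gxe_p = res$p_value)
  attr(out, "lambda") <- genomic_lambda(statistics = res$statistic)
  attr(out, "theta_hat") <- fit$theta_hat
  structure(out, class = c("mrgxe_screen", setdiff(class(out),
                                                   "mrgxe_screen")))
}

#' Define independent loci and signals among significant variants
#'
#' Greedy locus assignment: the most significant unassigned variant founds a
#' locus as its lead, and every significant variant within `window_bp` on
#' the same chromosome joins that locus. Within each locus, independent
#' signals are retained in ascending p-value order subject to pairwise LD
#' r-squared below `r2` with every previously retained signal; without an
#' LD reference only the lead is reported as a signal, with a warning.
#'
#' @param screen A screened table from [screen_genome()] (or any table with
#'   `variant_id`, `chrom`, `pos` and `mr_gxe_p`).
#' @param p_threshold Screening significance threshold (default 5e-8).
#' @param window_bp Locus half-width in bp (default 1 Mb).
#' @param r2 Independence threshold on LD r-squared (default 0.1).
#' @param ld_ref Genotype matrix or `f(id1, id2) -> r2`, as in
#'   [select_instruments()].
#' @return A tibble with one row per locus: `lead_variant`, `lead_p`,
#'   `members` (list-column) and `independent_signals` (list-column).
#' @export
define_loci <- function(screen, p_threshold = 5e-8, window_bp = 1e6,
                        r2 = 0.1, ld_ref = NULL) {
  sig <- screen[!is.na(screen$mr_gxe_p) & screen$mr_gxe_p < p_threshold, ]
  if (nrow(sig) == 0) {
    return(tibble::tibble(lead_variant = character(0), lead_p = numeric(0),
                          members = list(), independent_signals = list()))
  }
  r2_fun <- NULL
  if (is.matrix(ld_ref)) {
    r2_fun <- function(a, b) {
      if (!all(c(a, b) %in% colnames(ld_ref))) return(NA_real_)
      cor(ld_ref[, a], ld_ref[, b])^2
    }
  } else if (is.function(ld_ref)) {
    r2_fun <- ld_ref
  } else {
    warn("No LD reference supplied; reporting one signal per locus.")
  }

  sig <- sig[order(sig$mr_gxe_p, sig$pos), ]
  loci <- list()
  while (nrow(sig) > 0) {
    lead <- sig[1, ]
    in_locus <- sig$chrom == lead$chrom &
      abs(sig$pos - lead$pos) <= window_bp
    members <- sig[in_locus, ]
    signals <- members$variant_id[1]
    if (!is.null(r2_fun) && nrow(members) > 1) {
      for (i in seq(2, nrow(members))) {
        id <- members$variant_id[i]
        r2s <- vapply(signals, function(s) r2_fun(id, s), numeric(1))
        if (all(is.na(r2s) | r2s < r2)) signals <- c(signals, id)
      }
    }
    loci[[length(loci) + 1]] <- tibble::tibble(
      lead_variant = lead$variant_id, lead_p = lead$mr_gxe_p,
      members = list(members$variant_id),
      independent_signals = list(signals))
    sig <- sig[!in_locus, ]
  }
  dplyr::bind_rows(loci)
}

#' Step-2 confirmation by the direct interaction test
#'
#' Survivors of the MR-GxE screen are confirmed with the direct interaction
#' test at the Bonferroni threshold `family_alpha / (X * n_exposures)`,
#' where `X` is the realized number of independent signals from the screen
#' (never a hard-coded count). Within each locus the variant with the
#' smallest direct-test p-value among the screen-significant variants is
#' the reported candidate. Because the screen and the confirmation are not
#' independent when run on the same data, results are labelled
#' `"non-independent confirmation"` unless `independent_data = TRUE`
#' (direct test from a separate cohort), in which case they are labelled
#' `"replication"`.
#'
#' @param signals Data frame with one row per independent signal:
#'   `variant_id` plus `direct_p` (direct-test p-value for that signal), and
#'   optionally `locus` (lead id) and `exposure`.
#' @param family_alpha Family-wise level (default 0.05).
#' @param n_exposures Number of exposures in the testing family (default 4).
#' @param n_signals Number of independent signals `X`; defaults to
#'   `nrow(signals)`.
#' @param independent_data Direct test computed in a cohort independent of
#'   the screen?
#' @return A list with `threshold`, `label`, and `confirmed` (the rows of
#'   `signals` passing the threshold; when `locus` and `exposure` columns
#'   are present, the best variant per locus-exposure pair).
#' @export
step2_confirm <- function(signals, family_alpha = 0.05, n_exposures = 4,
                          n_signals = nrow(signals),
                          independent_data = FALSE) {
  stopifnot(n_signals >= 1, n_exposures >= 1)
  threshold <- family_alpha / (n_signals * n_exposures)
  hits <- signals[!is.na(signals$direct_p) & signals$direct_p < threshold, ]
  if (all(c("locus", "exposure") %in% names(hits)) && nrow(hits) > 0) {
    hits <- hits |>
      dplyr::group_by(.data$locus, .data$exposure) |>
      dplyr::slice_min(.data$direct_p, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  list(threshold = threshold,
       label = if (independent_data) "replication"
               else "non-independent confirmation",
       confirmed = hits)
}

#' Combine discovery and replication p-values (Fisher, 4 df)
#'
#' Fisher's combination of two independent direct-test p-values:
#' \eqn{-2(\ln p_1 + \ln p_2) \sim \chi^2_4} under the joint null.
#' The combined p-value is not guaranteed to be below `min(p1, p2)`.
#'
#' @param p_discovery,p_replication P-values in (0, 1]; exact zeros are
#'   clipped to the smallest representable positive double with a warning.
#' @return A test tibble with `statistic`, `df` (= 4), `p_value` and label
#'   `"combined"`; vectorized.
#' @export
combine_replication_p <- function(p_discovery, p_replication) {
  clip <- function(p) {
    if (any(p == 0)) {
      warn("p-value of 0 clipped to .Machine$double.xmin.")
      p[p == 0] <- .Machine$double.xmin
    }
    stopifnot(all(p > 0), all(p <= 1))
    p
  }
  p1 <- clip(p_discovery); p2 <- clip(p_replication)
  stat <- -2 * (log(p1) + log(p2))
  new_gxe_test(stat, 4L, pchisq(stat, df = 4, lower.tail = FALSE),
               "combined")
}

#' Cross-population correlation of marginal effects, split by GxE status
#'
#' Interaction and mediation make marginal effects environment-dependent,
#' so variants carrying them should show weaker cross-population agreement
#' of marginal effect sizes. This compares the Pearson correlation of
#' per-variant effects between two populations for the flagged
#' (interaction/mediation) versus unflagged variant sets and reports the
#' percent drop `100 * (1 - corr_flagged / corr_unflagged)`.
#'
#' @param effects Data frame with `variant_id`, `effect_a`, `effect_b`
#'   (marginal effect sizes of the same variants in populations A and B).
#' @param flagged_ids Character vector of variant ids flagged as carrying
#'   interaction or mediation.
#' @param min_per_group Minimum variants required in each group.
#' @return A tibble with `corr_flagged`, `corr_unflagged`, `percent_drop`
#'   (`NA` when the flagged set is empty or too small).
#' @export
cross_population_effect_correlation <- function(effects, flagged_ids,
                                                min_per_group = 10) {
  flagged <- effects[effects$variant_id %in% flagged_ids, ]
  unflagged <- effects[!effects$variant_id %in% flagged_ids, ]
  safe_cor <- function(d) {
    if (nrow(d) < min_per_group) return(NA_real_)
    if (sd(d$effect_a) == 0 || sd(d$effect_b) == 0) {
      abort("Degenerate effect-size variance in one group.")
    }
    cor(d$effect_a, d$effect_b)
  }
  cf <- safe_cor(flagged)
  cu <- safe_cor(unflagged)
  tibble::tibble(corr_flagged = cf, corr_unflagged = cu,
                 percent_drop = 100 * (1 - cf / cu))
}
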