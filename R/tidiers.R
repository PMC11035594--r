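#' Tidy an MR slope fit
#'
#' @param x An `mr_fit`.
#' @param ... Unused.
#' @return One-row tibble with `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.mr_fit <- function(x, ...) {
  z <- x$theta_hat / x$se_theta
  tibble::tibble(term = "theta", estimate = x$theta_hat,
                 std.error = x$se_theta, statistic = z,
                 p.value = 2 * pnorm(-abs(z)))
}

#' Glance at an MR slope fit
#'
#' @param x An `mr_fit`.
#' @param ... Unused.
#' @return One-row tibble with fit-level summaries.
#' @export
glance.mr_fit <- function(x, ...) {
  tibble::tibble(theta_hat = x$theta_hat, se_theta = x$se_theta,
                 n_instruments = length(x$instruments),
                 n_removed = length(x$removed),
                 overlap_r = x$overlap_r, n_iter = x$n_iter)
}

#' Tidy an individual-level interaction-model fit
#'
#' @param x A `gxe_lm` from [fit_interaction_model()].
#' @param ... Unused.
#' @return Tibble with one row per coefficient (`beta0..beta3`).
#' @export
tidy.gxe_lm <- function(x, ...) {
  z <- x$coef / x$se
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef),
                 std.error = unname(x$se), statistic = unname(z),
                 p.value = unname(2 * pnorm(-abs(z))))
}

#' Glance at an interaction-model fit
#'
#' @param x A `gxe_lm`.
#' @param ... Unused.
#' @return One-row tibble with the direct-test statistic and p-value.
#' @export
glance.gxe_lm <- function(x, ...) {
  tibble::tibble(n = x$n, sigma2 = x$sigma2,
                 direct_stat = x$test$statistic, direct_p = x$test$p_value)
}

#' Tidy an LD-score regression fit
#'
#' @param x An `ldsc_fit`.
#' @param ... Unused.
#' @return Tibble with `h2` and `intercept` rows.
#' @export
tidy.ldsc_fit <- function(x, ...) {
  tibble::tibble(term = c("h2", "intercept"),
                 estimate = c(x$h2, x$intercept),
                 std.error = c(x$se, x$intercept_se))
}

#' QQ plot of a genome-wide MR-GxE screen
#'
#' Expected versus observed -log10 p-values with the genomic inflation
#' factor in the subtitle.
#'
#' @param object A screened table from [screen_genome()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mrgxe_screen <- function(object, ...) {
  p <- sort(object$mr_gxe_p)
  d <- tibble::tibble(expected = -log10(stats::ppoints(length(p))),
                      observed = -log10(p))
  lam <- attr(object, "lambda")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Expected -log10(p)", y = "Observed -log10(p)",
                  title = "MR-GxE screen QQ plot",
                  subtitle = sprintf("genomic inflation lambda = %.3f", lam))
}

#' Scatter plot of marginal versus main effects with the fitted slope
#'
#' The MR-GxE view of the data: instruments should lie on the line through
#' the origin with slope `theta_hat`; variants carrying interaction or
#' mediation depart from it.
#'
#' @param table A harmonized table.
#' @param fit An `mr_fit`.
#' @param highlight Optional character vector of variant ids to colour as
#'   flagged.
#' @return A ggplot object.
#' @export
plot_theta_fit <- function(table, fit, highlight = NULL) {
  d <- tibble::as_tibble(table)
  d$flagged <- d$variant_id %in% (highlight %||% fit$removed)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta1_hat, y = .data$alpha_hat,
                                  colour = .data$flagged)) +
    ggplot2::geom_abline(slope = fit$theta_hat, intercept = 0,
                         linetype = 2) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick"),
                                 name = "interaction/mediation") +
    ggplot2::labs(x = "GWIS main effect", y = "GWAS marginal effect",
                  title = sprintf("IVW slope theta = %.3f (SE %.3f)",
                                  fit$theta_hat, fit$se_theta))
}
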