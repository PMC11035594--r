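#' Per-variant residual effects after removing the fitted slope
#'
#' The residual effect `alpha_hat - theta_hat * beta1_hat` isolates the
#' part of the marginal effect attributable to interaction and mediation.
#' Its standard error uses the same variance expression as the MR-GxE test
#' denominator, so the squared residual z-score reproduces the screening
#' statistic exactly.
#'
#' @param table A harmonized table.
#' @param fit An `mr_fit` (slope and overlap correlation).
#' @return The table with `residual`, `se_residual`, `residual_z` and
#'   `residual_chisq` columns appended.
#' @export
residual_effects <- function(table, fit) {
  stopifnot(inherits(fit, "mr_fit"))
  v <- residual_variance(table$se_alpha, table$se_beta1, fit$theta_hat,
                         fit$overlap_r)
  res <- table$alpha_hat - fit$theta_hat * table$beta1_hat
  dplyr::mutate(tibble::as_tibble(table),
                residual = res, se_residual = sqrt(v),
                residual_z = res / sqrt(v),
                residual_chisq = res^2 / v)
}

#' LD-score regression on residual-effect chi-square statistics
#'
#' Regresses per-variant chi-square statistics on `ld_score * n_eff / M`
#' to estimate the (lower-bound) heritability contributed by interaction
#' and mediation, with a confounding intercept. Weights are
#' `1/max(ld_score, 1)` in a first pass, then updated by the inverse
#' squared fitted values (two-pass heteroskedasticity weighting). The
#' standard error is a leave-one-block-out jackknife over `blocks`
#' contiguous blocks.
#'
#' @param input Data frame with columns `chisq` (or `z`, squared
#'   internally), `ld_score` and `n_eff`.
#' @param M Total number of variants the heritability refers to (defaults
#'   to `nrow(input)`).
#' @param blocks Number of jackknife blocks (default 200, reduced to
#'   `floor(nrow/2)` when the input is small).
#' @param intercept `NULL` to estimate the intercept freely (default) or a
#'   number (typically 1) to constrain it. Constant LD scores make the
#'   slope and a free intercept jointly unidentifiable and raise an error.
#' @return A list of class `ldsc_fit` with `h2`, `se`, `intercept`,
#'   `intercept_se` (NA when constrained), `blocks`, `M`.
#' @export
ldsc_fit <- function(input, M = nrow(input), blocks = 200, intercept = NULL) {
  chisq <- if ("chisq" %in% names(input)) input$chisq else input$z^2
  ell <- input$ld_score
  n <- input$n_eff
  stopifnot(all(ell >= 0), all(n > 0), length(chisq) == length(ell))
  blocks <- max(2L, min(as.integer(blocks), floor(length(chisq) / 2)))
  if (length(chisq) < 2L * blocks) {
    abort("Need at least 2 variants per jackknife block.")
  }
  free_int <- is.null(intercept)
  if (free_int && stats::sd(ell) == 0) {
    abort(paste0("All LD scores are equal: the slope is not identifiable ",
                 "with a free intercept. Fix `intercept` (e.g. 1)."))
  }
  x <- ell * n / M
  w1 <- 1 / pmax(ell, 1)

  fit_once <- function(keep, w) {
    xx <- x[keep]; yy <- chisq[keep]; ww <- w[keep]
    if (free_int) {
      X <- cbind(1, xx)
      b <- solve(crossprod(X * sqrt(ww)), crossprod(X * sqrt(ww),
                                                    yy * sqrt(ww)))
      c(intercept = b[1], h2 = b[2])
    } else {
      b <- sum(ww * xx * (yy - intercept)) / sum(ww * xx^2)
      c(intercept = intercept, h2 = b)
    }
  }
  all_idx <- seq_along(chisq)
  pass1 <- fit_once(all_idx, w1)
  fitted <- pmax(pass1["intercept"] + pass1["h2"] * x, 0.1)
  w2 <- w1 / fitted^2
  full <- fit_once(all_idx, w2)

  block_id <- cut(all_idx, breaks = blocks, labels = FALSE)
  jk <- vapply(seq_len(blocks),
               function(b) fit_once(all_idx[block_id != b], w2),
               numeric(2))
  jk_se <- sqrt((blocks - 1) / blocks *
                  rowSums((jk - rowMeans(jk))^2))
  structure(list(h2 = unname(full["h2"]), se = unname(jk_se[2]),
                 intercept = unname(full["intercept"]),
                 intercept_se = if (free_int) unname(jk_se[1]) else NA_real_,
                 blocks = blocks, M = M),
            class = "ldsc_fit")
}

#' @export
print.ldsc_fit <- function(x, ...) {
  cat(sprintf("LD-score regression: h2 = %.4f (SE %.4f), intercept = %.3f\n",
              x$h2, x$se, x$intercept))
  invisible(x)
}

#' Synthetic residual chi-square fixture for LD-score regression
#'
#' Generates per-variant residual z-scores under the LD-score regression
#' model: `z ~ N(0, sqrt(a + n_eff * h2 * ld_score / M))` with confounding
#' intercept `a`. With `ld_score = 1` every variant is in LD only with
#' itself (a "unit-LD" panel of independent variants).
#'
#' @param m Number of variants simulated.
#' @param h2 Planted heritability.
#' @param n_eff Effective sample size (scalar or vector).
#' @param M Total variant count the heritability is spread over
#'   (default `m`).
#' @param ld_score LD scores (scalar or vector; default 1).
#' @param intercept Confounding intercept `a` (default 1, no confounding).
#' @param seed Optional integer seed.
#' @return A tibble with `variant_id`, `z`, `chisq`, `ld_score`, `n_eff`.
#' @export
simulate_ldsc_input <- function(m, h2, n_eff, M = m, ld_score = 1,
                                intercept = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ell <- rep_len(ld_score, m)
  n <- rep_len(n_eff, m)
  v <- intercept + n * h2 * ell / M
  z <- rnorm(m, 0, sqrt(v))
  tibble::tibble(variant_id = paste0("v", seq_len(m)), z = z, chisq = z^2,
                 ld_score = ell, n_eff = n)
}
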