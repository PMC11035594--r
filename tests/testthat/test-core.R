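test_that("IVW closed form equals the numeric minimizer of the objective", {
  # single instrument: slope is the effect ratio
  one <- make_harmonized_tbl(0.2, 0.05, 0.1, 0.05)
  expect_equal(fit_ivw_theta(one)$theta_hat, 2.0)

  set.seed(21)
  for (i in 1:10) {
    m <- sample(3:40, 1)
    tbl <- make_harmonized_tbl(rnorm(m, 0, 0.05), runif(m, 0.005, 0.05),
                               rnorm(m, 0.05, 0.05), runif(m, 0.005, 0.05))
    fit <- fit_ivw_theta(tbl)
    oracle <- ivw_numeric_oracle(tbl$alpha_hat, tbl$se_alpha, tbl$beta1_hat)
    expect_equal(fit$theta_hat, oracle, tolerance = 1e-10)
  }
  # all-zero main effects leave the slope undefined
  degen <- make_harmonized_tbl(c(0.1, 0.2), c(0.01, 0.01), c(0, 0),
                               c(0.01, 0.01))
  expect_error(fit_ivw_theta(degen), "undefined")
})

test_that("MR-GxE statistic, d.f. and two-sided p follow the chi-square(1) form", {
  # on-the-line variant: statistic 0, p 1
  t0 <- test_mr_gxe(0.05, 0.01, 0.05, 0.01, theta_hat = 1)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  # hand-computed case: (0.05-0.01)^2 / (2e-4) = 8
  t1 <- test_mr_gxe(0.05, 0.01, 0.01, 0.01, theta_hat = 1, overlap_r = 0)
  expect_equal(t1$statistic, 8)
  expect_equal(t1$df, 1L)
  expect_equal(t1$p_value, pchisq(8, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(t1$p_value, 0.004678, tolerance = 1e-3)
  # overlap shrinks the variance: statistic increases with r at theta 1
  tr0 <- test_diff(0.05, 0.01, 0.02, 0.01, overlap_r = 0)
  tr5 <- test_diff(0.05, 0.01, 0.02, 0.01, overlap_r = 0.5)
  expect_gt(tr5$statistic, tr0$statistic)
  # extreme r makes the variance non-positive
  expect_error(test_mr_gxe(0.05, 0.01, 0.02, 0.01, theta_hat = 1,
                           overlap_r = 1), "overlap correlation")
  # diff test is the slope-1 special case of the MR-GxE test
  td <- test_diff(0.07, 0.012, 0.03, 0.009, overlap_r = 0.3)
  tm <- test_mr_gxe(0.07, 0.012, 0.03, 0.009, theta_hat = 1,
                    overlap_r = 0.3)
  expect_equal(td$statistic, tm$statistic)
})

test_that("iterative fit removes a planted interaction instrument", {
  set.seed(8)
  m <- 101
  beta1 <- rnorm(m, 0, sqrt(0.01))
  se_a <- rep(1 / sqrt(2e4), m)
  se_b <- rep(sqrt(2 / 2e4), m)
  alpha <- beta1 + rnorm(m, 0, se_a)
  b1_hat <- beta1 + rnorm(m, 0, se_b)
  alpha[1] <- alpha[1] + 0.12 # contaminated instrument departs from line
  tbl <- make_harmonized_tbl(alpha, se_a, b1_hat, se_b)
  fit <- imrp_fit(tbl)
  expect_true("v1" %in% fit$removed)
  expect_false("v1" %in% fit$instruments)
  expect_equal(fit$theta_hat, 1, tolerance = 3 * fit$se_theta + 0.05)
  # the liberal default may shed a few valid instruments, never many
  expect_lt(length(fit$removed), 12)
  # under conservative removal, only the contaminant is evicted and the
  # slope trajectory moves monotonically toward the fit on the
  # a-priori-clean subset
  fit_b <- imrp_fit(tbl, bonferroni = TRUE)
  expect_equal(fit_b$removed, "v1")
  oracle <- fit_ivw_theta(tbl[-1, ])$theta_hat
  gaps <- abs(fit_b$trace - oracle)
  expect_true(all(diff(gaps) <= 1e-12))
  # and a clean input converges immediately with nothing removed
  clean <- imrp_fit(tbl[-1, ], bonferroni = TRUE)
  expect_equal(clean$n_iter, 1L)
  expect_length(clean$removed, 0)
})

test_that("interaction effect from the gap scales as 1/mu_e1", {
  est1 <- estimate_interaction_effect(0.06, 0.01, 0.01, 0.01,
                                      theta_hat = 1, mu_e1 = 1)
  expect_equal(est1$estimate, 0.05)
  est2 <- estimate_interaction_effect(0.06, 0.01, 0.01, 0.01,
                                      theta_hat = 1, mu_e1 = 2)
  expect_equal(est2$estimate, est1$estimate / 2)
  expect_equal(est2$se, est1$se / 2)
  expect_error(estimate_interaction_effect(0.06, 0.01, 0.01, 0.01, 1,
                                           mu_e1 = 0), "identifiable")
})

test_that("genomic inflation factor is calibrated and scale-equivariant", {
  set.seed(31)
  lam <- genomic_lambda(p_values = runif(1e5))
  expect_equal(lam, 1, tolerance = 0.02)
  med <- qchisq(0.5, 1)
  expect_equal(genomic_lambda(statistics = rep(med, 11)), 1)
  stats <- rchisq(1001, 1)
  expect_equal(genomic_lambda(statistics = 2 * stats),
               2 * genomic_lambda(statistics = stats))
})

test_that("overlap correlation is recovered from null variants", {
  # fully shared samples: theoretical correlation of the estimate pair
  set.seed(52)
  m <- 2000
  n <- 5e4
  va <- 1 / n; vb <- 2 / n; cab <- 2 / n * 0.7 # induced covariance
  r_true <- cab / sqrt(va * vb)
  z <- matrix(rnorm(2 * m), m)
  a <- sqrt(va) * z[, 1]
  b <- cab / sqrt(va) * z[, 1] + sqrt(vb - cab^2 / va) * z[, 2]
  tbl <- make_harmonized_tbl(a, sqrt(va), b, sqrt(vb))
  r_hat <- estimate_overlap_correlation(tbl)
  expect_equal(r_hat, r_true, tolerance = 0.05)

  # disjoint cohorts: near-zero correlation
  tbl0 <- make_harmonized_tbl(rnorm(m, 0, sqrt(va)), sqrt(va),
                              rnorm(m, 0, sqrt(vb)), sqrt(vb))
  expect_lt(abs(estimate_overlap_correlation(tbl0)), 0.06)

  # degenerate constant z-scores error out
  tblc <- make_harmonized_tbl(rep(0.001, 300), rep(0.01, 300),
                              rnorm(300, 0, 0.01), rep(0.01, 300))
  expect_error(estimate_overlap_correlation(tblc), "[Dd]egenerate")
  # too few nulls is an actionable error
  expect_error(estimate_overlap_correlation(tbl[1:50, ]), "null variants")
})

test_that("instrument selection prunes by p-value, window and LD threshold", {
  tbl <- make_harmonized_tbl(c(0.10, 0.09, 0.08, 0.001),
                             rep(0.005, 4), rep(0.05, 4), rep(0.01, 4))
  tbl$pos <- c(1e6, 1.1e6, 1.7e6, 3e6)
  tbl$p_gwas <- c(1e-10, 1e-9, 1e-9, 0.5)
  geno <- matrix(rnorm(400), 100, 4)
  geno[, 2] <- geno[, 1] + rnorm(100, 0, 0.5)  # r2 ~ 0.8 with v1
  colnames(geno) <- tbl$variant_id
  sel <- instrument_selection(gc_correct = FALSE)
  kept <- select_instruments(tbl, sel, ld_ref = geno)
  expect_true("v1" %in% kept)
  expect_false("v2" %in% kept) # within 500 kb of v1 at high r2
  expect_true("v3" %in% kept)  # within window but low r2
  expect_false("v4" %in% kept) # fails p threshold
  # two variants 600 kb apart are both kept regardless of r2
  tbl2 <- tbl[1:2, ]
  tbl2$pos <- c(1e6, 1.6e6)
  geno2 <- geno[, 1:2]
  geno2[, 2] <- geno2[, 1] # perfect LD, but outside the window
  colnames(geno2) <- tbl2$variant_id
  expect_setequal(select_instruments(tbl2, sel, ld_ref = geno2),
                  c("v1", "v2"))
  # single candidate trivially kept; none at all errors
  expect_equal(suppressWarnings(select_instruments(tbl[1, ], sel)), "v1")
  expect_error(select_instruments(tbl[4, ], sel), "No variants")
})
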