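# Shared fixtures: small in-code summary-statistics tables and oracles.

make_gwas_tbl <- function(n = 5, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    variant_id = paste0("rs", seq_len(n)),
    chrom = "1", pos = seq_len(n) * 1e6,
    effect_allele = rep(c("A", "C", "G", "T", "A"), length.out = n),
    other_allele = rep(c("G", "T", "A", "C", "C"), length.out = n),
    eaf = runif(n, 0.1, 0.45),
    alpha_hat = rnorm(n, 0, 0.02), se_alpha = runif(n, 0.005, 0.02),
    p_value = runif(n, 0.01, 0.99), n_eff = 2e5)
}

make_gwis_tbl <- function(gwas = make_gwas_tbl()) {
  n <- nrow(gwas)
  set.seed(n + 7)
  tibble::tibble(
    variant_id = gwas$variant_id, chrom = gwas$chrom, pos = gwas$pos,
    effect_allele = gwas$effect_allele, other_allele = gwas$other_allele,
    eaf = gwas$eaf + rnorm(n, 0, 0.005),
    n_eff = 5e4,
    beta1_hat = rnorm(n, 0, 0.02), se_beta1 = runif(n, 0.005, 0.02),
    beta2_hat = rnorm(n, 0, 0.01), se_beta2 = runif(n, 0.005, 0.02),
    beta3_hat = rnorm(n, 0, 0.01), se_beta3 = runif(n, 0.005, 0.02),
    p_beta3 = runif(n, 0.01, 0.99))
}

write_sumstats_file <- function(tbl, path, sep = "\t") {
  cols <- lapply(tbl, function(x) {
    if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
  })
  m <- do.call(cbind, cols)
  lines <- c(paste(names(tbl), collapse = sep),
             apply(m, 1, paste, collapse = sep))
  writeLines(lines, path)
  path
}

# Harmonized-shape table straight from effect vectors (bypasses file QC).
make_harmonized_tbl <- function(alpha_hat, se_alpha, beta1_hat, se_beta1,
                                beta3_hat = 0, se_beta3 = 0.01,
                                n_gwas = 2e5, n_gwis = 5e4) {
  m <- length(alpha_hat)
  tibble::tibble(
    variant_id = paste0("v", seq_len(m)), chrom = "1", pos = seq_len(m) * 2e6,
    alpha_hat = alpha_hat, se_alpha = se_alpha,
    p_gwas = 2 * pnorm(-abs(alpha_hat / se_alpha)), n_gwas = n_gwas,
    beta1_hat = beta1_hat, se_beta1 = se_beta1,
    beta3_hat = rep_len(beta3_hat, m), se_beta3 = rep_len(se_beta3, m),
    p_beta3 = 2 * pnorm(-abs(rep_len(beta3_hat, m) / rep_len(se_beta3, m))),
    n_gwis = n_gwis)
}

# Independent normal-equations OLS oracle (no lm), returns coef, se, vcov.
ols_oracle <- function(X, y) {
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% b
  s2 <- sum(resid^2) / (length(y) - ncol(X))
  V <- s2 * solve(XtX)
  list(coef = drop(b), se = sqrt(diag(V)), vcov = V, sigma2 = s2)
}

# Numeric minimizer oracle for the IVW objective. The objective is exactly
# quadratic in theta, so evaluating it at three points and taking the vertex
# of the interpolating parabola recovers the minimizer to machine precision,
# independently of the closed-form weight algebra.
ivw_numeric_oracle <- function(alpha_hat, se_alpha, beta1_hat) {
  obj <- function(th) mean((alpha_hat - beta1_hat * th)^2 / se_alpha^2)
  f <- vapply(c(-1, 0, 1), obj, numeric(1))
  vertex <- (f[1] - f[3]) / (2 * (f[1] - 2 * f[2] + f[3]))
  coarse <- optimize(obj, interval = c(-100, 100), tol = 1e-10)$minimum
  stopifnot(abs(vertex - coarse) < 1e-4) # cross-check the two routes
  vertex
}
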