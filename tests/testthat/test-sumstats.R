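test_that("well-formed tables round-trip; invariant violations are dropped and logged", {
  g <- make_gwas_tbl(3)
  f <- write_sumstats_file(g, withr::local_tempfile(fileext = ".tsv"))
  rec <- read_sumstats(f, "gwas")
  expect_equal(nrow(rec), 3)
  expect_equal(sum(attr(rec, "qc_log")$n), 0)
  expect_equal(rec$alpha_hat, g$alpha_hat)

  g$se_alpha[2] <- 0
  f2 <- write_sumstats_file(g, withr::local_tempfile(fileext = ".tsv"))
  rec2 <- suppressMessages(read_sumstats(f2, "gwas"))
  expect_equal(nrow(rec2), 2)
  log <- attr(rec2, "qc_log")
  expect_equal(log$n[log$reason == "nonpositive_se"], 1L)
})

test_that("tab- and whitespace-delimited dialects parse identically", {
  g <- make_gwas_tbl(5)
  f_tab <- write_sumstats_file(g, withr::local_tempfile(fileext = ".tsv"))
  f_ws <- write_sumstats_file(g, withr::local_tempfile(fileext = ".txt"),
                              sep = "  ")
  a <- read_sumstats(f_tab, "gwas")
  b <- read_sumstats(f_ws, "gwas")
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("missing mandatory columns and empty files are explicit errors", {
  g <- make_gwas_tbl(3)
  g$se_alpha <- NULL
  f <- write_sumstats_file(g, withr::local_tempfile(fileext = ".tsv"))
  expect_error(read_sumstats(f, "gwas"), "se_alpha")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_error(read_sumstats(empty, "gwas"), "[Ee]mpty")
})

test_that("column mapping renames file columns to canonical names", {
  g <- make_gwas_tbl(3)
  names(g)[names(g) == "alpha_hat"] <- "BETA"
  names(g)[names(g) == "variant_id"] <- "SNP"
  f <- write_sumstats_file(g, withr::local_tempfile(fileext = ".tsv"))
  rec <- read_sumstats(f, "gwas",
                       column_map = c(alpha_hat = "BETA", variant_id = "SNP"))
  expect_true(all(c("alpha_hat", "variant_id") %in% names(rec)))
})

qc_loose <- qc_config(min_n_primary = 0, min_n_secondary = 0)

test_that("swapped alleles are sign-flipped onto the GWAS effect allele", {
  g <- make_gwas_tbl(1)
  g$effect_allele <- "A"; g$other_allele <- "G"; g$alpha_hat <- 0.2
  w <- make_gwis_tbl(g)
  w$effect_allele <- "G"; w$other_allele <- "A"
  w$beta1_hat <- 0.1; w$beta3_hat <- 0.02; w$eaf <- 0.3
  h <- harmonize(g, w, qc_loose)
  expect_equal(h$beta1_hat, -0.1)
  expect_equal(h$beta3_hat, -0.02)
  expect_equal(h$eaf_gwis, 0.7)
  expect_true(h$flipped)
})

test_that("palindromic variants are removed and irreconcilable alleles dropped", {
  g <- make_gwas_tbl(3)
  g$effect_allele <- c("A", "A", "A")
  g$other_allele <- c("T", "G", "G")
  w <- make_gwis_tbl(g)
  w$effect_allele <- c("A", "A", "A")
  w$other_allele <- c("T", "G", "C") # third cannot be reconciled
  h <- suppressMessages(harmonize(g, w, qc_loose))
  expect_equal(h$variant_id, "rs2")
  log <- attr(h, "qc_log")
  expect_equal(log$n[log$reason == "palindromic"], 1L)
  expect_equal(log$n[log$reason == "allele_mismatch"], 1L)
})

test_that("identity harmonization keeps all rows with zero flips", {
  g <- make_gwas_tbl(4)
  g <- g[g$effect_allele != "A" | g$other_allele != "T", ]
  w <- make_gwis_tbl(g)
  h <- harmonize(g, w, qc_loose)
  expect_equal(nrow(h), nrow(g))
  expect_false(any(h$flipped))
})

test_that("MAF-difference filter uses minor-allele frequencies at the 0.15 rule", {
  g <- make_gwas_tbl(2)
  g$effect_allele <- "A"; g$other_allele <- "G"
  g$eaf <- c(0.10, 0.10)
  w <- make_gwis_tbl(g)
  w$effect_allele <- "A"; w$other_allele <- "G"
  w$eaf <- c(0.30, 0.24) # diffs 0.20 (drop) and 0.14 (keep)
  h <- suppressMessages(harmonize(g, w, qc_loose))
  expect_equal(h$variant_id, "rs2")
  # strand-robust: the same variant reported on the major allele passes too
  w$eaf <- c(0.70, 0.76) # minor allele frequencies 0.30 and 0.24 again
  h2 <- suppressMessages(harmonize(g, w, qc_loose))
  expect_equal(h2$variant_id, "rs2")
})

test_that("positional fallback joins by coordinates under the 0.01 MAF rule", {
  g <- make_gwas_tbl(2)
  g$effect_allele <- "A"; g$other_allele <- "G"
  g$eaf <- c(0.20, 0.20)
  w <- make_gwis_tbl(g)
  w$variant_id <- c("chr1:alt1", "chr1:alt2") # ids differ -> positional
  w$effect_allele <- "A"; w$other_allele <- "G"
  w$eaf <- c(0.205, 0.25) # first within 0.01, second not
  h <- suppressMessages(harmonize(g, w, qc_loose))
  expect_equal(h$variant_id, "rs1")
  expect_true(h$positional_match)
})

test_that("effective-sample-size floors drop underpowered rows", {
  g <- make_gwas_tbl(2)
  g$n_eff <- c(2e5, 5e4) # second below the 100K GWAS floor
  w <- make_gwis_tbl(g)
  h <- suppressMessages(harmonize(g, w, qc_config()))
  expect_equal(h$variant_id, "rs1")
})

test_that("harmonization is idempotent and sign-flip is an involution", {
  g <- make_gwas_tbl(6, seed = 3)
  w <- make_gwis_tbl(g)
  flip <- c(2, 5)
  w$effect_allele[flip] <- g$other_allele[flip]
  w$other_allele[flip] <- g$effect_allele[flip]
  w$eaf[flip] <- 1 - w$eaf[flip]
  h1 <- suppressMessages(harmonize(g, w, qc_loose))

  # rebuild the two sources from the harmonized output and re-harmonize
  g2 <- dplyr::transmute(h1, variant_id, chrom, pos, effect_allele,
                         other_allele, eaf = eaf_gwas, alpha_hat, se_alpha,
                         p_value = p_gwas, n_eff = n_gwas)
  w2 <- dplyr::transmute(h1, variant_id, chrom, pos, effect_allele,
                         other_allele, eaf = eaf_gwis, n_eff = n_gwis,
                         beta1_hat, se_beta1, beta2_hat, se_beta2,
                         beta3_hat, se_beta3, p_beta3)
  h2 <- suppressMessages(harmonize(g2, w2, qc_loose))
  expect_setequal(h2$variant_id, h1$variant_id)
  expect_equal(h2$beta1_hat[order(h2$variant_id)],
               h1$beta1_hat[order(h1$variant_id)])

  # flipping both input allele orders returns identical aligned effects
  g3 <- g
  g3$effect_allele <- g$other_allele; g3$other_allele <- g$effect_allele
  g3$eaf <- 1 - g$eaf; g3$alpha_hat <- -g$alpha_hat
  w3 <- w
  w3$effect_allele <- w$other_allele; w3$other_allele <- w$effect_allele
  w3$eaf <- 1 - w$eaf
  w3$beta1_hat <- -w$beta1_hat; w3$beta3_hat <- -w$beta3_hat
  h3 <- suppressMessages(harmonize(g3, w3, qc_loose))
  m <- match(h1$variant_id, h3$variant_id)
  # both sources re-expressed on the opposite allele: aligned effects negate
  # together, so the relative configuration is unchanged
  expect_equal(-h3$alpha_hat[m], h1$alpha_hat, tolerance = 1e-12)
  expect_equal(-h3$beta1_hat[m], h1$beta1_hat, tolerance = 1e-12)
})

test_that("drop reasons account exactly for the input-output row difference", {
  g <- make_gwas_tbl(8, seed = 9)
  g$effect_allele <- c("A", "A", "C", "G", "A", "C", "T", "G")
  g$other_allele <- c("T", "G", "G", "A", "C", "T", "C", "T")
  w <- make_gwis_tbl(g)
  w$eaf[4] <- 0.49; g$eaf[4] <- 0.05 # large MAF difference
  h <- suppressMessages(harmonize(g, w, qc_loose))
  log <- attr(h, "qc_log")
  expect_equal(nrow(g) - nrow(h), sum(log$n))
})

test_that("exposure-locus exclusion removes closed windows around hits", {
  tbl <- make_harmonized_tbl(alpha_hat = rep(0.01, 4),
                             se_alpha = rep(0.01, 4),
                             beta1_hat = rep(0.01, 4),
                             se_beta1 = rep(0.01, 4))
  tbl$pos <- c(4.6e6, 6.1e6, 5e6, 20e6)
  hits <- tibble::tibble(chrom = "1", pos = 5e6)
  out <- suppressMessages(exclude_environment_loci(tbl, hits,
                                                   window_bp = 1e6))
  expect_setequal(out$pos, c(6.1e6, 20e6))

  expect_warning(unchanged <- exclude_environment_loci(tbl, hits[0, ]),
                 "unchanged")
  expect_equal(nrow(unchanged), nrow(tbl))

  # overlapping hit windows act as a union of intervals (brute-force check)
  hits2 <- tibble::tibble(chrom = "1", pos = c(5e6, 5.8e6))
  out2 <- suppressMessages(exclude_environment_loci(tbl, hits2,
                                                    window_bp = 1e6))
  member <- vapply(tbl$pos, function(p) any(abs(p - hits2$pos) <= 1e6),
                   logical(1))
  expect_setequal(out2$pos, tbl$pos[!member])
})

test_that("standardization follows z/sqrt(n) and is scale-invariant", {
  tbl <- make_harmonized_tbl(alpha_hat = 0.05, se_alpha = 0.01,
                             beta1_hat = 0.03, se_beta1 = 0.01,
                             n_gwas = 1e4, n_gwis = 1e4)
  out <- standardize_effects(tbl)
  expect_equal(out$alpha_std, (0.05 / 0.01) / sqrt(1e4))
  expect_equal(out$se_alpha_std, 0.01)
  # zero effect stays zero on any n
  tbl0 <- make_harmonized_tbl(0, 0.01, 0, 0.01, n_gwas = 123456)
  expect_equal(standardize_effects(tbl0)$alpha_std, 0)
  # multiplying effect and SE by 3 leaves the standardized effect unchanged
  set.seed(4)
  tblr <- make_harmonized_tbl(rnorm(20, 0, 0.05), runif(20, 0.01, 0.05),
                              rnorm(20, 0, 0.05), runif(20, 0.01, 0.05))
  scaled <- dplyr::mutate(tblr, alpha_hat = alpha_hat * 3,
                          se_alpha = se_alpha * 3)
  expect_equal(standardize_effects(scaled)$alpha_std,
               standardize_effects(tblr)$alpha_std)
})
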