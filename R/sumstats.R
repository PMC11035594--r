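canonical_cols <- list(
  gwas = c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
           "eaf", "alpha_hat", "se_alpha", "p_value", "n_eff"),
  gwis = c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
           "eaf", "n_eff", "beta1_hat", "se_beta1", "beta2_hat", "se_beta2",
           "beta3_hat", "se_beta3", "p_beta3")
)

optional_cols <- list(gwas = character(), gwis = c("cov_beta1_beta3", "p_beta1"))

#' QC configuration for harmonizing GWAS and GWIS summary statistics
#'
#' Bundles the thresholds applied by [harmonize()] and
#' [exclude_environment_loci()]. Defaults follow common practice for
#' consortium-scale lipid analyses: variants whose minor allele frequency
#' differs by more than 0.15 between sources are dropped, positional
#' (id-less) matches must agree within 0.01, palindromic (A/T, C/G) variants
#' are removed, and per-source effective-sample-size floors of 100K (GWAS)
#' and 30K (GWIS) apply. Loci associated with the exposure itself at
#' p < 5e-7 are excluded within a 1 Mb window to limit mediation leakage.
#'
#' @param maf_diff_max Maximum allowed minor-allele-frequency difference for
#'   id-matched variants (fraction).
#' @param maf_diff_positional_max Maximum MAF difference for positional
#'   (chrom/pos) matches; must not exceed `maf_diff_max`.
#' @param min_n_primary Minimum effective sample size in the GWAS source.
#' @param min_n_secondary Minimum effective sample size in the GWIS source.
#' @param drop_palindromic Drop A/T and C/G variants (strand-ambiguous)?
#' @param exclusion_window_bp Half-width (bp) of the window removed around
#'   each exposure-associated locus; closed interval.
#' @param exclusion_p P-value threshold defining an exposure-associated hit.
#' @param standardization Effect standardization rule used by
#'   [standardize_effects()]: `"z_over_sqrt_n"` (default) or
#'   `"z_over_sqrt_n_plus_z2"`; the two differ negligibly for |z| well below
#'   sqrt(n).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(maf_diff_max = 0.15,
                      maf_diff_positional_max = 0.01,
                      min_n_primary = 1e5,
                      min_n_secondary = 3e4,
                      drop_palindromic = TRUE,
                      exclusion_window_bp = 1e6,
                      exclusion_p = 5e-7,
                      standardization = c("z_over_sqrt_n",
                                          "z_over_sqrt_n_plus_z2")) {
  standardization <- match.arg(standardization)
  stopifnot(maf_diff_positional_max > 0,
            maf_diff_positional_max <= maf_diff_max,
            maf_diff_max < 0.5,
            min_n_primary >= 0, min_n_secondary >= 0,
            exclusion_window_bp >= 0, exclusion_p > 0, exclusion_p < 1)
  structure(list(maf_diff_max = maf_diff_max,
                 maf_diff_positional_max = maf_diff_positional_max,
                 min_n_primary = min_n_primary,
                 min_n_secondary = min_n_secondary,
                 drop_palindromic = isTRUE(drop_palindromic),
                 exclusion_window_bp = exclusion_window_bp,
                 exclusion_p = exclusion_p,
                 standardization = standardization),
            class = "qc_config")
}

qc_log <- function(x) attr(x, "qc_log") %||%
  tibble::tibble(reason = character(), n = integer())

set_qc_log <- function(x, log) {
  attr(x, "qc_log") <- log
  x
}

add_reason <- function(log, reason, n) {
  if (n > 0) log <- dplyr::bind_rows(log, tibble::tibble(reason = reason,
                                                         n = as.integer(n)))
  log
}

#' Read a GWAS or GWIS summary-statistics table
#'
#' Reads a delimited text file (tab- or whitespace-separated, with a header)
#' into a validated tibble with canonical column names. Rows violating basic
#' type invariants (non-positive SEs, allele frequencies outside (0,1),
#' p-values outside (0,1], alleles containing characters other than
#' A/C/G/T) are dropped; the per-reason drop counts are attached as the
#' `"qc_log"` attribute and reported with a message.
#'
#' @param path Path to the summary-statistics file.
#' @param role `"gwas"` (marginal model: effect `alpha_hat`) or `"gwis"`
#'   (interaction model: `beta1_hat`, `beta2_hat`, `beta3_hat`).
#' @param column_map Optional named character vector mapping canonical names
#'   (names) to the file's column names (values), e.g.
#'   `c(variant_id = "SNP", alpha_hat = "BETA")`. Unmapped canonical names
#'   are looked up verbatim.
#' @return A tibble of validated records with canonical columns; attribute
#'   `"qc_log"` holds the drop log.
#' @export
read_sumstats <- function(path, role = c("gwas", "gwis"), column_map = NULL) {
  role <- match.arg(role)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(trimws(first))) {
    abort(paste0("Empty summary-statistics file: ", path))
  }
  raw <- if (grepl("\t", first)) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_table(path, show_col_types = FALSE, progress = FALSE)
  }
  if (nrow(raw) == 0L) abort(paste0("No data rows in: ", path))

  want <- canonical_cols[[role]]
  opt <- optional_cols[[role]]
  map <- setNames(c(want, opt), c(want, opt))
  if (!is.null(column_map)) map[names(column_map)] <- unname(column_map)
  missing_cols <- setdiff(unname(map[want]), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing mandatory column(s) in ", path, ": ",
                 paste(missing_cols, collapse = ", ")))
  }
  present <- c(want, intersect(opt, names(map)[unname(map) %in% names(raw)]))
  out <- tibble::as_tibble(raw[, unname(map[present]), drop = FALSE])
  names(out) <- present
  out$chrom <- as.character(out$chrom)
  out$variant_id <- as.character(out$variant_id)
  validate_records(out, role)
}

validate_records <- function(tbl, role) {
  log <- tibble::tibble(reason = character(), n = integer())
  ok_allele <- function(a) !is.na(a) & grepl("^[ACGT]+$", toupper(a))
  keep <- ok_allele(tbl$effect_allele) & ok_allele(tbl$other_allele)
  log <- add_reason(log, "invalid_allele", sum(!keep))
  tbl <- tbl[keep, ]

  se_cols <- grep("^se_", names(tbl), value = TRUE)
  keep <- rep(TRUE, nrow(tbl))
  for (sc in se_cols) keep <- keep & !is.na(tbl[[sc]]) & tbl[[sc]] > 0
  log <- add_reason(log, "nonpositive_se", sum(!keep))
  tbl <- tbl[keep, ]

  keep <- is.na(tbl$eaf) | (tbl$eaf > 0 & tbl$eaf < 1)
  log <- add_reason(log, "eaf_out_of_range", sum(!keep))
  tbl <- tbl[keep, ]

  p_col <- if (role == "gwas") "p_value" else "p_beta3"
  keep <- !is.na(tbl[[p_col]]) & tbl[[p_col]] > 0 & tbl[[p_col]] <= 1
  log <- add_reason(log, "p_out_of_range", sum(!keep))
  tbl <- tbl[keep, ]

  keep <- !is.na(tbl$pos) & !is.na(tbl$n_eff) & tbl$n_eff > 0
  log <- add_reason(log, "missing_fields", sum(!keep))
  tbl <- tbl[keep, ]

  if (sum(log$n) > 0) {
    inform(paste0("read_sumstats: dropped ", sum(log$n), " row(s) [",
                  paste(log$reason, log$n, sep = "=", collapse = ", "), "]"))
  }
  set_qc_log(tbl, log)
}

is_palindromic <- function(a1, a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize GWAS and GWIS summary statistics into one analysis table
#'
#' Joins the two sources on `variant_id` (with a chrom/pos fallback for rows
#' whose ids do not match), aligns the GWIS records to the GWAS effect
#' allele, and applies the QC filters in `qc`:
#'
#' * swapped-allele rows have the genotype-anchored GWIS effects
#'   (`beta1_hat`, `beta3_hat`) sign-flipped and `eaf` replaced by `1 - eaf`
#'   (the exposure main effect `beta2_hat` is not allele-anchored and is
#'   left untouched);
#' * rows whose allele pairs cannot be reconciled are dropped;
#' * palindromic (A/T, C/G) variants are dropped when
#'   `qc$drop_palindromic`;
#' * rows with minor-allele-frequency difference above `qc$maf_diff_max`
#'   are dropped (rows missing `eaf` in one source are retained, exempt from
#'   MAF filters, and flagged `eaf_missing`);
#' * positional (id-less) matches must agree in MAF within
#'   `qc$maf_diff_positional_max`; ties at a position are resolved by the
#'   smallest MAF difference;
#' * rows failing the per-source effective-sample-size floors are dropped.
#'
#' @param gwas_table,gwis_table Tibbles as returned by [read_sumstats()].
#' @param qc A [qc_config()].
#' @return A tibble with one row per retained variant carrying both record
#'   sets (`alpha_hat`, `se_alpha`, `p_gwas`, `n_gwas`, `beta*`, `p_beta3`,
#'   `n_gwis`, `eaf_gwas`, `eaf_gwis`) plus flags `flipped`,
#'   `positional_match` and `eaf_missing`. Attribute `"qc_log"` counts every
#'   dropped row by reason.
#' @export
harmonize <- function(gwas_table, gwis_table, qc = qc_config()) {
  stopifnot(inherits(qc, "qc_config"))
  if (nrow(gwas_table) == 0 || nrow(gwis_table) == 0) {
    abort("Both input tables must be non-empty.")
  }
  g <- dplyr::rename(gwas_table, eaf_gwas = "eaf", n_gwas = "n_eff",
                     p_gwas = "p_value")
  w <- dplyr::rename(gwis_table, eaf_gwis = "eaf", n_gwis = "n_eff")
  w <- dplyr::rename_with(w, ~ paste0(.x, "_gwis"),
                          dplyr::all_of(c("chrom", "pos", "effect_allele",
                                          "other_allele")))

  log <- tibble::tibble(reason = character(), n = integer())

  exact <- dplyr::inner_join(g, w, by = "variant_id")
  exact$positional_match <- FALSE

  g_rest <- g[!g$variant_id %in% exact$variant_id, ]
  w_rest <- dplyr::rename(w[!w$variant_id %in% exact$variant_id, ],
                          variant_id_gwis = "variant_id")
  positional <- dplyr::inner_join(
    g_rest, w_rest,
    by = c("chrom" = "chrom_gwis", "pos" = "pos_gwis"),
    relationship = "many-to-many"
  )
  if (nrow(positional) > 0) {
    positional$chrom_gwis <- positional$chrom
    positional$pos_gwis <- positional$pos
    maf <- function(x) pmin(x, 1 - x)
    positional$.maf_diff <- abs(maf(positional$eaf_gwas) -
                                  maf(positional$eaf_gwis))
    # multi-allelic positional matches must agree closely in MAF
    ok <- !is.na(positional$.maf_diff) &
      positional$.maf_diff < qc$maf_diff_positional_max
    log <- add_reason(log, "positional_maf_mismatch", sum(!ok))
    positional <- positional[ok, ]
    positional <- positional |>
      dplyr::group_by(.data$variant_id) |>
      dplyr::slice_min(.data$.maf_diff, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::select(-".maf_diff", -"variant_id_gwis")
    positional$positional_match <- TRUE
  }
  tbl <- dplyr::bind_rows(exact, positional)
  if (nrow(tbl) == 0) abort("No overlapping variants between the two tables.")

  up <- function(x) toupper(x)
  same <- up(tbl$effect_allele) == up(tbl$effect_allele_gwis) &
    up(tbl$other_allele) == up(tbl$other_allele_gwis)
  swapped <- up(tbl$effect_allele) == up(tbl$other_allele_gwis) &
    up(tbl$other_allele) == up(tbl$effect_allele_gwis)
  impossible <- !(same | swapped)
  log <- add_reason(log, "allele_mismatch", sum(impossible))
  tbl <- tbl[!impossible, ]
  swapped <- swapped[!impossible]

  tbl$flipped <- swapped
  tbl$beta1_hat[swapped] <- -tbl$beta1_hat[swapped]
  tbl$beta3_hat[swapped] <- -tbl$beta3_hat[swapped]
  tbl$eaf_gwis[swapped] <- 1 - tbl$eaf_gwis[swapped]

  if (qc$drop_palindromic) {
    pal <- is_palindromic(tbl$effect_allele, tbl$other_allele)
    log <- add_reason(log, "palindromic", sum(pal))
    tbl <- tbl[!pal, ]
  }

  tbl$eaf_missing <- is.na(tbl$eaf_gwas) | is.na(tbl$eaf_gwis)
  maf_diff <- abs(pmin(tbl$eaf_gwas, 1 - tbl$eaf_gwas) -
                    pmin(tbl$eaf_gwis, 1 - tbl$eaf_gwis))
  bad_maf <- !tbl$eaf_missing & maf_diff > qc$maf_diff_max
  log <- add_reason(log, "maf_difference", sum(bad_maf))
  tbl <- tbl[!bad_maf, ]

  small_n <- tbl$n_gwas < qc$min_n_primary | tbl$n_gwis < qc$min_n_secondary
  log <- add_reason(log, "n_eff_below_floor", sum(small_n))
  tbl <- tbl[!small_n, ]

  tbl <- dplyr::select(tbl, -dplyr::ends_with("_gwis") |
                         dplyr::all_of(c("eaf_gwis", "n_gwis")))
  if (sum(log$n) > 0) {
    inform(paste0("harmonize: dropped ", sum(log$n), " row(s) [",
                  paste(log$reason, log$n, sep = "=", collapse = ", "), "]"))
  }
  set_qc_log(tbl, log)
}

#' Exclude loci associated with the environmental exposure
#'
#' Removes every variant within `window_bp` (closed interval) of a reported
#' exposure-associated hit, to limit contamination of the screen by large
#' mediation effects (variants acting on the trait through the exposure
#' itself).
#'
#' @param table A harmonized table from [harmonize()].
#' @param env_hits Data frame of exposure GWAS hits with columns `chrom` and
#'   `pos`; an optional `p` column is filtered at `p_threshold` first.
#' @param window_bp Half-width of the exclusion window in bp.
#' @param p_threshold Hits with `p` at or above this threshold are ignored.
#' @return The table with excluded variants removed; the number removed is
#'   appended to the `"qc_log"` attribute.
#' @export
exclude_environment_loci <- function(table, env_hits, window_bp = 1e6,
                                     p_threshold = 5e-7) {
  log <- qc_log(table)
  if (is.null(env_hits) || nrow(env_hits) == 0) {
    warn("No exposure-associated hits supplied; table returned unchanged.")
    return(table)
  }
  hits <- tibble::as_tibble(env_hits)
  if ("p" %in% names(hits)) hits <- hits[hits$p < p_threshold, ]
  hits$chrom <- as.character(hits$chrom)
  if (nrow(hits) == 0) return(table)
  in_window <- rep(FALSE, nrow(table))
  for (i in seq_len(nrow(hits))) {
    in_window <- in_window |
      (table$chrom == hits$chrom[i] &
         abs(table$pos - hits$pos[i]) <= window_bp)
  }
  log <- add_reason(log, "near_exposure_locus", sum(in_window))
  if (sum(in_window) > 0) {
    inform(paste0("exclude_environment_loci: removed ", sum(in_window),
                  " variant(s) within ", window_bp, " bp of ", nrow(hits),
                  " exposure hit(s)"))
  }
  set_qc_log(table[!in_window, ], log)
}

#' Standardize effect sizes to the z / sqrt(n) scale
#'
#' Adds standardized effects and standard errors for the marginal effect and
#' the GWIS main and interaction effects: with `z = effect / se`, the
#' standardized effect is `z / sqrt(n)` with standard error `1 / sqrt(n)`
#' (or `z / sqrt(n + z^2)` under the `"z_over_sqrt_n_plus_z2"` rule; the two
#' agree to first order for |z| well below sqrt(n)). On this scale
#' `var(alpha_std) = 1/n_gwas`, the form the slope theory assumes.
#' Original columns are preserved; rows with `n <= 1` are dropped.
#'
#' @param table A harmonized table from [harmonize()].
#' @param qc A [qc_config()]; only the `standardization` field is used.
#' @return The table with added columns `alpha_std`, `se_alpha_std`,
#'   `beta1_std`, `se_beta1_std`, `beta3_std`, `se_beta3_std`.
#' @export
standardize_effects <- function(table, qc = qc_config()) {
  log <- qc_log(table)
  bad_n <- table$n_gwas <= 1 | table$n_gwis <= 1
  log <- add_reason(log, "n_eff_not_above_1", sum(bad_n))
  table <- table[!bad_n, ]
  shrunk <- identical(qc$standardization, "z_over_sqrt_n_plus_z2")
  std <- function(effect, se, n) {
    z <- effect / se
    denom <- if (shrunk) sqrt(n + z^2) else sqrt(n)
    list(b = z / denom, se = 1 / denom)
  }
  a <- std(table$alpha_hat, table$se_alpha, table$n_gwas)
  b1 <- std(table$beta1_hat, table$se_beta1, table$n_gwis)
  b3 <- std(table$beta3_hat, table$se_beta3, table$n_gwis)
  table$alpha_std <- a$b;  table$se_alpha_std <- a$se
  table$beta1_std <- b1$b; table$se_beta1_std <- b1$se
  table$beta3_std <- b3$b; table$se_beta3_std <- b3$se
  set_qc_log(table, log)
}
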