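# mrgxe

Screening gene-environment (G×E) interactions and environmental mediation
from GWAS and GWIS summary statistics, via a Mendelian-randomization-style
slope fit.

## The problem

Testing the interaction coefficient β₃ of the genome-wide interaction model

    Y = β₀ + β₁G + β₂E + β₃·G×E + ε        (GWIS)

directly is underpowered: G and G×E are collinear, and GWIS cohorts are far
smaller than the GWAS cohorts that fit the marginal model

    Y = α₀ + αG + ε                        (GWAS).

The marginal and main effects differ by

    α − β₁ = (ρσ_E1/σ_G1)·β₂ + (μ_E1 + ρσ_E1/σ_G1)·β₃,

so a variant's gap between its GWAS marginal effect and its GWIS main effect
carries the combined interaction + mediation signal. Comparing the two
effect columns naively is biased when they come from different consortia,
so `mrgxe` fits the relationship the way MR handles pleiotropy: an
inverse-variance-weighted slope θ̂ through the (β̂₁, α̂) cloud over
independent genome-wide-significant instruments, iteratively removing
outlying variants, then a per-variant χ²₁ screen

    T_MR_GxE = (α̂ − θ̂β̂₁)² / (se_α² + θ̂²se_β₁² − 2θ̂·r·se_α·se_β₁),

with r the sample-overlap correlation estimated from genome-wide null
variants. Screen survivors at 5×10⁻⁸ are confirmed by the direct GWIS test
at 0.05/(X·E), X the realized number of independent signals and E the
number of exposures — the two-step procedure. Residual effects α̂ − θ̂β̂₁
feed an LD-score regression that bounds the interaction + mediation
heritability from below.

The package is tidyverse-shaped: functions take a data frame first and
return tibbles; fitted objects have `tidy()`/`glance()` methods; screens
have `autoplot()`.

## Worked example

Two hundred instrument-strength variants plus a genome-like null backbone,
with one planted interaction variant (β₃ = 0.08), GWAS n = 300K fully
containing a GWIS cohort of 40K:

```r
library(mrgxe)
set.seed(2026)
m <- 2000
truth <- tibble::tibble(
  variant_id = paste0("v", 1:m),
  beta1 = c(rnorm(100, 0, 0.05), rep(0, m - 100)),
  beta3 = c(rep(0, 100), 0.08, rep(0, m - 101)))
ss <- simulate_sumstats_fast(truth, n1 = 3e5, n2 = 4e4, n0 = 4e4,
                             mu_e1 = 1, mu_e2 = 1, seed = 7)

r  <- estimate_overlap_correlation(ss)     # 0.161
iv <- ss$variant_id[ss$p_gwas < 5e-8]
fit <- imrp_fit(ss[ss$variant_id %in% iv, ], overlap_r = r)
fit
#> MR slope fit (marginal on main effects)
#>   theta_hat = 1.0005 (SE 0.0131)
#>   instruments: 83 kept, 1 removed as interaction/mediation
#>   overlap r = 0.161, iterations = 2

sc <- screen_genome(ss, fit)
attr(sc, "lambda")                         # 0.954 — calibrated screen
hits <- sc[sc$mr_gxe_p < 5e-8, ]
hits[, c("variant_id", "mr_gxe_stat", "mr_gxe_p", "p_beta3")]
#> 1 v101              122. 1.87e-28 8.46e-53

step2_confirm(tibble::tibble(variant_id = hits$variant_id,
                             direct_p = hits$p_beta3),
              n_exposures = 1)$confirmed
#>   variant_id direct_p
#> 1 v101       8.46e-53
```

The slope is recovered at 1.00 (instruments are clean), the genomic
inflation of the screen is close to 1, the planted variant is the only hit
(it is also the one instrument the iterative fit flagged and removed), and
it survives the step-2 direct test at the realized Bonferroni threshold.

Individual-level workflows use `fit_interaction_model()` /
`fit_marginal_model()`; the two simulation designs of the methods vignette
are exposed as `simulate_design_a()` / `simulate_design_b()` with
`evaluate_error_rates()` producing type-I/power tables with binomial
confidence intervals.

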