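---
title: "Screening gene-environment interactions from summary statistics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening gene-environment interactions from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrgxe)
```

## The problem

Genome-wide interaction studies (GWIS) fit, per variant,

$$Y = \beta_0 + \beta_1 G + \beta_2 E + \beta_3\, G \times E + \epsilon,$$

and test the interaction coefficient directly,
$T_{direct} = \hat\beta_3^2 / \mathrm{var}(\hat\beta_3)$. The direct test is
underpowered: the collinearity of $G$ and $G\times E$ inflates both standard
errors, and their test statistics are negatively correlated with correlation
$-\mu_E/\sqrt{\mu_E^2+\sigma_E^2}$ (`main_interaction_corr()`), so exposures
with large means are particularly punishing.

GWAS, by contrast, fit the marginal model $Y = \alpha_0 + \alpha G +
\epsilon$ on far larger samples. The marginal and main effects differ by

$$\alpha - \beta_1 = \frac{\rho\,\sigma_{E1}}{\sigma_{G1}}\beta_2 +
  \Big(\mu_{E1} + \frac{\rho\,\sigma_{E1}}{\sigma_{G1}}\Big)\beta_3,$$

where $\rho$ captures mediation of the genotype through the exposure
(`marginal_main_gap()`). The gap is zero exactly when there is neither
interaction nor mediation, so comparing the two effect estimates tests their
combined contribution. Comparing them naively ($T_{diff}$, with $\theta$
fixed at 1) is biased when the two sets of summary statistics come from
different consortia — different phenotype transformations, covariates,
population-structure corrections. The package's central idea, borrowed from
Mendelian randomization, is to *fit* the relationship: regress marginal on
main effects across independent genome-wide-significant instruments with
inverse-variance weights,

$$\hat\theta = \frac{\sum_j w_j \hat\alpha_j \hat\beta_{1,j}}
  {\sum_j w_j \hat\beta_{1,j}^2}, \qquad w_j = 1/\mathrm{var}(\hat\alpha_j),$$

and test each variant's departure from the fitted line,

$$T_{MR\_GxE} = \frac{(\hat\alpha - \hat\theta\hat\beta_1)^2}
  {se_\alpha^2 + \hat\theta^2 se_{\beta_1}^2 -
   2\hat\theta\, r\, se_\alpha se_{\beta_1}} \sim \chi^2_1,$$

the exact analogue of a horizontal-pleiotropy test: a variant carrying
interaction or mediation is "pleiotropic" with respect to the pseudo
exposure defined by the trait's own polygenic signal. Instruments that
depart from the line are removed and the slope refitted, iterating to
convergence (`imrp_fit()`, at most 50 iterations, deterministic). Removal
tests each instrument at an unadjusted 0.05 — deliberately liberal. A
strong contaminated instrument drags the slope toward itself and inflates
the variance of its own outlier test (masking); a Bonferroni-corrected bar
can then fail to evict it from a small panel, which in the design-B
simulations collapses screen power below the direct test's and inverts the
expected two-step ordering. Shedding an occasional valid instrument at the
liberal bar barely moves the inverse-variance-weighted slope, so the
trade-off goes one way; a `bonferroni = TRUE` option remains for large,
clean panels.

## Sample overlap

When the GWAS and GWIS cohorts share $n_0$ individuals the two estimates of
the same variant are correlated even under the null. The package estimates
this single scalar $r$ empirically as the correlation of marginal/main
z-scores across variants null in both sources (p > 0.05;
`estimate_overlap_correlation()`), mirroring how practitioners feed one
correlation into pleiotropy-aware MR. The closed-form expectation of the
slope under valid instruments is implemented in `expected_theta()`:

$$E(\hat\theta) = \frac{\sigma_\beta^2 + \frac{n_0}{n_1 n_2}
  (1 + \mu_{E0}^2/\sigma_{E0}^2)}{\sigma_\beta^2 + \frac{1}{n_2}
  (1 + \mu_{E2}^2/\sigma_{E2}^2)}.$$

Two regime notes that the implementation documents and tests:

* The bound $E(\hat\theta) \le 1$ holds for $n_0 \le \min(n_1, n_2)$ *and*
  overlap samples sharing the GWIS cohort's exposure distribution — which
  they do by construction, being a subset of that cohort. Decoupling the
  overlap exposure moments can push the expression above 1; the property
  sweep therefore ties them together.
* The formula's cross term overstates the empirical same-sample covariance
  of $(\hat\alpha, \hat\beta_1)$, which measures as
  $\sigma^2 n_0/(n_1 n_2)$ in simulation (the printed term would imply an
  estimate correlation above 1 at full overlap). The fast
  summary-statistics generator (`simulate_sumstats_fast()`) therefore draws
  with the measured covariance, while `expected_theta()` keeps the closed
  form, which is exact for disjoint cohorts and approximate at high
  overlap. The simulation-versus-theory agreement test is run at zero
  overlap for this reason.

A related subtlety: the $\beta_3$ coefficient of the marginal-main gap,
$\mu_{E1} + \rho\sigma_{E1}/\sigma_{G1}$, involves the standardized
genotype's third moment. It is exact for a skewness-1 dosage (centred
Binomial(2, p) at $p = (3-\sqrt3)/6$, the design used in the cross-check
test); for a symmetric genotype the coefficient reduces to $\mu_{E1}$. The
$\rho = 0$ and $\beta_3 = 0$ projections are exact for any genotype law.

## Harmonization and QC

`harmonize()` aligns a GWAS and a GWIS table: exact variant-id join with a
chrom/position fallback, GWIS effects flipped onto the GWAS effect allele
(only genotype-anchored effects $\beta_1, \beta_3$ flip; the exposure main
effect is not allele-indexed), palindromic A/T and C/G variants dropped,
minor-allele-frequency agreement within 0.15 (0.01 for positional matches,
ties resolved by smallest MAF difference), and per-source effective-sample
floors of 100K/30K. MAF differences are computed on minor-allele
frequencies after alignment, which makes the filter strand-robust; rows
missing a frequency in one source are retained but flagged and exempted
rather than silently filtered. Every dropped row is attributed to exactly
one reason code, and the reason counts reconcile with the row difference —
a property the test suite asserts. Variants within 1 Mb (closed interval,
1-based coordinates) of exposure-associated loci (p < 5e-7) can be excluded
to limit mediation leakage (`exclude_environment_loci()`).

Standardization to the $z/\sqrt n$ scale (`standardize_effects()`) uses
$b^* = z/\sqrt n$, $se^* = 1/\sqrt n$; the alternative
$z/\sqrt{n + z^2}$ is available as a config switch and differs only in the
extreme-signal regime $|z| \sim \sqrt n$.

## Two-step procedure

Screening the genome with $T_{MR\_GxE}$ at $5\times10^{-8}$ and confirming
survivors with the direct test at $0.05/(X \cdot E)$ — $X$ the realized
number of independent signals (never a hard-coded count), $E$ the number of
exposures in the family — trades a genome-wide burden for a handful of
confirmations. Loci are 1 Mb windows around the most significant variants;
independent signals within a locus require pairwise LD $r^2 < 0.1$,
computed as squared Pearson correlation of dosage columns from any
user-supplied reference. Because screen and confirmation share data when
run on the same cohorts, `step2_confirm()` labels such results
"non-independent confirmation" and reserves "replication" for a direct test
from independent data; two-stage evidence is combined by Fisher's method
with 4 degrees of freedom (`combine_replication_p()`).

## Simulation designs

`simulate_design_a()` (the defaults *are* the study conditions): 102
independent variants, allele frequencies Uniform(0.05, 0.5), dosages scaled
by $1/\sqrt{2p(1-p)}$ to unit variance (the scale on which the theory sets
$\sigma_G^2 = 1$; the unsquared-root divisor sometimes written for this
design would not standardize), main effects $\beta_{1j} \sim N(0,
\sigma_\beta^2)$ with $\sigma_\beta^2 = 0.005$ per instrument, exposure
effect 0.1, one interaction variant with $\beta_3 = 0.05$, unit residual
variance, cohorts of 20000 with configurable overlap and exposure means.
Variant 1 probes power, variant 2 type-I error, variants 3..102 are the
slope's instruments. The sign scenario `s` makes variant 1's main effect
align with (+1), oppose (-1), or vanish under (0) the interaction.

`simulate_design_b()`: 20 Binomial(2, 0.3) variants standardized *without*
centring (deliberately literal: the nonzero genotype mean feeds the gap),
GWIS cohort of 20000 nested in a GWAS cohort of up to 300000,
non-overlapping individuals with a 1.5-fold exposure mean. Scenarios: pure
null; mediation ($E = 0.05G + N(\mu, 0.9975)$, so the genotype explains
exactly 0.25% of exposure variance); mediation plus interaction (0.1). The
exposure mean is a swept parameter of this design rather than a fixed
constant: 1 is the default and 0.5 and 2 are the other presets, all set
through the `env_mean` argument. Covariates are omitted throughout the
simulations.

Problem sizes used by the shipped tests and the acceptance script — 500
replicates of design A at $n = 20000$, 1000 replicates of design B (GWAS
cohort 60000 in the power-ordering study), $10^5$-point theory sweeps,
$10^4$-variant LD-score fixtures — were chosen as the smallest sizes at
which Monte-Carlo error is clearly below the effects being measured.

What the generators deliberately do not emulate: linkage disequilibrium
between causal variants (the designs' variants are independent),
binary traits, covariate structure, or meta-analytic heterogeneity across
contributing cohorts. Passing tests therefore demonstrate the estimators'
sampling behaviour under clean designs, not robustness to confounding or
LD — the screen's robustness argument in real data rests on the fitted
slope absorbing between-study scaling, which the designs emulate only
through differing exposure distributions.

## Residual-effect heritability

`residual_effects()` forms $\hat\alpha - \hat\theta\hat\beta_1$ with the
same variance as the screening denominator (so the squared residual z-score
*is* the screening statistic — asserted as an identity). LD-score
regression of the residual chi-squares on $\ell_j n / M$ (`ldsc_fit()`)
bounds the interaction-plus-mediation heritability from below; it is a
component of, and must not exceed, the marginal-effect heritability.
Weights are $1/\max(\ell_j, 1)$ with a second pass down-weighting by
squared fitted values; standard errors come from a 200-block delete-one
jackknife. The intercept is free by default; with constant LD scores
(independent-variant panels) slope and intercept are jointly
unidentifiable, so such fits require constraining the intercept (to 1 when
no confounding is modelled) — the error message says so.

## Numerical choices and degenerate inputs

* The IVW closed form is asserted against an independent numeric minimizer
  of its objective to 1e-10 relative error.
* $\hat\theta$ is treated as fixed inside the test variance (standard in
  pleiotropy testing); a delta-method option propagating its standard error
  exists but is off by default.
* Genomic-control correction of GWAS p-values before instrument selection
  divides the chi-squares by the inflation factor computed from the full
  table, and is only applied when that factor exceeds 1.
* Pruning and locus ties break deterministically: ascending p-value, then
  ascending position.
* Degenerate inputs fail loudly rather than silently: overlap correlations
  that make the test variance non-positive name the offending value; zero
  main effects leave the slope undefined; a zero exposure mean makes the
  gap-based interaction estimate unidentifiable; p-values of exactly 0 are
  clipped to the smallest positive double with a warning.
* All randomness flows from a single integer seed per entry point.

## Known limitations

The screen tests interaction *and* mediation jointly; only the two-step
confirmation isolates interaction. The exposure-locus exclusion mitigates
but does not remove mediation leakage. The slope's weak-instrument
attenuation ($E(\hat\theta) < 1$ for small $\sigma_\beta^2$) propagates a
proportionally small bias into the gap-based interaction estimator; it
vanishes as instrument strength or sample size grows. Real-data findings
that depend on consortium-scale inputs (specific loci, inflation-factor
ranges, cross-population correlation drops, lipid heritabilities) are
outside what synthetic data can certify; the package covers them with
property-style analogues instead.
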