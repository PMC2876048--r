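# gainscore

Growth standardization and obesity-risk-allele score analysis for birth
cohorts.

## What it is for

Polygenic risk scores built from adult-obesity GWAS variants can be used in
birth cohorts to ask *when* in childhood the genetic influence on body size
appears — at birth, in early infancy, or later. Doing that credibly takes a
chain of steps that epidemiologists usually re-implement ad hoc:

1. **LMS standardization** — raw weight/length/BMI at precise ages are
   converted to age- and sex-standardized SD scores (SDS) against a growth
   reference: `z = ((x/M)^L − 1)/(L·S)` (log branch at `L = 0`), with L, M, S
   interpolated linearly in age and no extrapolation.
2. **Risk-allele score** — the count of risk alleles over a fixed SNP panel
   (default 8 variants, extended 10), complete-case, with Hardy-Weinberg
   (1-df chi-square) and call-rate QC, plus an optional effect-weighted
   score.
3. **Conditional infancy weight gain** — weight gain from birth to 6 weeks
   corrected for regression to the mean,
   `gain = (z_6w − r·z_birth)/√(1 − r²)`, with `r` estimated in-sample;
   "failure to thrive" flags the slowest 5%.
4. **Association models** — cross-sectional OLS per-allele effects with Wald
   95% CIs, per-age coefficient profiles, logistic odds ratios for failure to
   thrive and overweight/obesity (IOTF-style age-interpolated BMI cutoffs),
   and variance explained.
5. **Longitudinal models** — ML random-intercept models (`lme4`) with a
   score-by-age interaction (SDS/allele/year), piecewise birth-to-6-week vs
   6-week-onward slopes, and polynomial interaction checks.

Because the motivating individual-level cohort data are restricted, the
package ships a **synthetic birth-cohort generator** (`simulate_cohort()`):
HWE genotypes, latent SDS trajectories with a piecewise-linear per-allele
age profile, subject random intercepts, visit-level missingness, jittered
measurement ages, 9-year body composition, and synthetic stand-ins for the
licensed reference and cutoff tables. Every pipeline stage is tested against
it end to end.

## Worked example

```r
library(gainscore)

cfg <- pipeline_config(sim = sim_config(n_subjects = 2000, seed = 42),
                       seed = 42)
res <- run_pipeline(cfg)

res$cross_sectional
#> # A tibble: 5 × 6
#>   outcome                 n effect_per_allele   ci_low ci_high p_value
#>   <chr>               <int>             <dbl>    <dbl>   <dbl>   <dbl>
#> 1 bmi_sds              1032            0.0148 -0.0208   0.0503 0.415
#> 2 weight_sds           1032            0.0497  0.0156   0.0839 0.00428
#> 3 length_height_sds    1032            0.0268 -0.00776  0.0613 0.129
#> 4 fat_mass_index       1032            0.0449 -0.00825  0.0980 0.0978
#> 5 fat_free_mass_index  1032            0.0124 -0.00980  0.0346 0.274

res$piecewise$slopes
#> # A tibble: 2 × 7
#>   window       term            estimate       se   ci_low ci_high   p_value
#>   <chr>        <chr>              <dbl>    <dbl>    <dbl>   <dbl>     <dbl>
#> 1 birth_to_6wk score:age_years  0.0866  0.132    -0.173   0.346   0.513
#> 2 6wk_onward   score:age_years  0.00389 0.000892  0.00215 0.00564 0.0000127

res$odds[res$odds$outcome == "failure_to_thrive", ]
#> # A tibble: 1 × 7
#>   outcome           n_cases n_total or_per_allele ci_low ci_high p_value
#>   <chr>               <int>   <int>         <dbl>  <dbl>   <dbl>   <dbl>
#> 1 failure_to_thrive      64    1252         0.952  0.826    1.10   0.498
```

Reading the output: at age 9, each extra risk allele is associated with
+0.050 weight SDS (95% CI 0.016-0.084) in this simulated cohort of 2,000
children (1,032 with complete genotypes and a 9-year visit). The
score-by-age interaction — how much stronger the per-allele weight effect
gets per year — is 0.0039 SDS/allele/y from 6 weeks onward, while the
birth-to-6-week window gives a much larger but noisy slope (0.087, CI
crossing zero at this n). Each allele is also (non-significantly, at this n)
protective against infancy failure to thrive (OR 0.95 per allele). With the
default full-size cohort (n = 7,000) the same quantities are estimated with
far tighter precision.

The run log reconciles every exclusion (incomplete genotypes, rows outside
the reference grid) exactly against the cohort size, and reports are
byte-identical under identical config and seed.

A thin CLI over the same functions lives at `inst/cli/gainscore.R`
(subcommands `simulate`, `standardize`, `score`, `gain`, `associate`,
`longitudinal`, `report`, `all`).

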