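---
title: "Methods: growth standardization, allele scores, and longitudinal models in gainscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth standardization, allele scores, and longitudinal models in gainscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gainscore)
```

## The problem

Common genetic variants associated with adult obesity have small individual
effects, but summed into a polygenic allele count they are strong enough to
ask *when* in childhood their influence on body size appears. Answering that
question in a birth cohort requires a chain of standard but
error-prone steps: converting raw weight and length measurements taken at
irregular ages into age- and sex-standardized SD scores (SDS); building a
quality-controlled risk-allele score; correcting early weight gain for
regression to the mean; and fitting cross-sectional and random-intercept
longitudinal models of the score-by-age effect. `gainscore` implements that
chain as tested, reusable functions, together with a synthetic birth-cohort
generator so the whole pipeline can be exercised and validated without
access to restricted individual-level data.

## Growth standardization (LMS)

A growth reference summarises the distribution of a measure at each age and
sex by three parameters: the Box-Cox power `L`, the median `M`, and the
coefficient of variation `S`. A raw value `x` maps to an SD score

$$z = \frac{(x/M)^L - 1}{L\,S} \quad (L \neq 0), \qquad
  z = \frac{\log(x/M)}{S} \quad (L = 0).$$

Numerical choices:

* `L`, `M` and `S` are each interpolated **linearly in age** between grid
  rows; this is standard practice for tabulated LMS references and is exact
  at the grid points.
* No extrapolation: ages outside the reference grid are excluded and
  reported (`standardize_cohort()` returns them in an `excluded` attribute
  with a reason), never silently dropped or extended.
* The logarithmic branch is taken when `|L| < 1e-12`. The transform is
  continuous in `L` at 0, and the inverse `lms_from_sds()` round-trips to
  better than 1e-9 across the valid domain (`1 + LSz > 0`).
* Ages are decimal years; 6 weeks is 42/365.25 y and 9 months 0.75 y. These
  conventions are the package's own choice, since "precise age at
  measurement" fixes no unit convention.
* Birth measurements are accepted as already adjusted for gestational age;
  an optional gestational-age column is carried through but unused. Building
  gestational-age adjustment into the reference machinery is out of scope.

Licensed national reference tables (and the licensed BMI cutoff tables) are
**not** shipped; users supply them as CSV, and `simulate_reference()` /
`simulate_cutoff_curves()` fabricate internally consistent synthetic
stand-ins for testing and demonstration.

## The obesity-risk-allele score

Genotypes are stored pre-oriented to the risk allele (dosage 0/1/2); raw
base calls are a reader concern (`read_genotypes_vcf()`) with explicit
allele-mismatch errors, never a silent strand flip. The primary score is the
plain count of risk alleles over a fixed panel (8 variants by default, 10 as
the extended panel), with a strict complete-case rule: subjects missing any
panel genotype are excluded, and the exclusion count is logged and
reconciled in the pipeline run log. The weighted score multiplies each
dosage by a user-supplied per-variant weight (their published effect on
adult BMI); weights default to 1, which reproduces the unweighted analysis.

QC helpers: `hwe_test()` is the 1-df chi-square goodness-of-fit test against
Hardy-Weinberg expectations computed from the sample allele frequency,
without continuity correction — appropriate at cohort sample sizes; a
monomorphic variant returns p = 1 by convention with a message.
`call_rate()` is the non-missing fraction per variant.

## Conditional weight gain and failure to thrive

Raw change in weight SDS from birth regresses to the mean. Conditional gain
removes this:

$$\mathrm{gain} = \frac{z_{6w} - r\,z_{birth}}{\sqrt{1 - r^2}},$$

with `r` the Pearson correlation between the two, estimated **within the
analysis sample** on complete pairs. When both columns are scaled to unit
variance the gain has exactly unit variance and zero sample correlation with
the baseline (an algebraic identity, tested to 1e-10). The denominator
follows the standard conditional-SDS form. Failure to thrive is membership
in the slowest 5% of conditional gain; the threshold is the empirical
quantile with linear interpolation between order statistics (R type 7), and
ties at the threshold are all flagged — reproducible and conservative toward
flagging. Fewer than 20 values is refused (the percentile is unstable).

## Association models

Cross-sectional effects are ordinary least squares of the SDS outcome on the
score, adjusted for sex and precise age (plus height for the fat and
fat-free mass indices); binary outcomes (failure to thrive,
overweight-or-obese, obese) use maximum-likelihood logistic regression. All
models are complete-case; no imputation, matching the analysis style this
package supports. Confidence intervals are Wald-type (`estimate ± 1.96 SE`)
throughout, matching the symmetric intervals conventional in this
literature. Two failure modes are explicit errors rather than quiet
misbehaviour: rank-deficient designs (the collinear columns are named) and
complete separation in the logistic model (detected as non-overlapping
linear predictors at a boundary fit).

`per_age_profile()` repeats the linear model at each measurement occasion.
When the data carry a nominal `visit_age` column, rows are matched to visits
exactly; otherwise a precise-age window is used. A covariate that is
constant within an age stratum — age at birth is exactly zero for everyone —
is dropped from that stratum's model with a message instead of failing.
`variance_explained()` is the R² increment when the score is added to the
covariate-only model.

## Longitudinal models

Repeated SDS outcomes are fitted with a subject-level random intercept
(`lme4::lmer`), estimated by **maximum likelihood rather than REML** because
the polynomial interaction checks compare models with different fixed
effects, which requires ML for valid likelihood comparisons. The
score-by-age interaction is the target quantity: the change in the
per-allele effect per year of age. Sex is kept as a fixed covariate in all
longitudinal models for consistency with the cross-sectional adjustments,
although SDS outcomes are already sex-standardized.

* `piecewise_slopes()` fits two independent window-restricted models split
  at the 6-week visit, reporting both score-by-age coefficients; the
  boundary observation belongs to both windows (a small tolerance covers
  jitter in the precise 6-week age).
* `polynomial_interaction_test()` adds score-by-age² and score-by-age³
  terms and reports their Wald p-values.
* If subjects effectively contribute single observations (mean observations
  per subject below 1.5) the random intercept is unidentifiable and the fit
  falls back to pooled OLS with a warning.
* Convergence uses tight optimizer tolerances (absolute f/x tolerances
  1e-12); a failed optimizer status is an explicit error carrying the
  optimizer messages. Fixed effects are invariant to subject relabeling and
  row order, and on balanced designs the variance components agree with the
  closed-form ML solution — both are tested.

## The synthetic cohort generator

`simulate_cohort()` generates the data-generating process the analysis
assumes:

$$z_i(t) = u_i + g(t)\,(s_i - \bar{s}) + \varepsilon_{it}, \qquad
  u_i \sim N(0, \sigma_u^2), \;\; \varepsilon_{it} \sim N(0, \sigma_e^2),$$

where `s_i` is the allele count from panel genotypes drawn independently as
Binomial(2, f) (Hardy-Weinberg), and `g(t)` is a piecewise-linear per-allele
effect profile with nodes at birth, 6 weeks and 11 years. Latent SDS are
back-transformed through the (synthetic) LMS reference to raw kg/cm values
at each child's jittered visit ages, so injected and estimated parameters
live on the same scale.

Key defaults, with units and why:

| parameter | default | rationale |
|---|---|---|
| `n_subjects` | 7,000 | size of the complete-genotype analysis sample the design emulates |
| weight `g(t)` | 0.010 SDS/allele at birth, +0.119/y to 6 wk, +0.004/y to 11 y | the early-steep/late-shallow profile the analysis is designed to detect |
| length `g(t)` | 0.012 at birth, +0.158/y to 6 wk, flat after | infancy-only length effect |
| `random_intercept_sd` | 0.8 SDS | strong within-child tracking of size |
| `residual_sd` | 0.6 SDS | visit-level measurement/biological noise; total variance 1 |
| `visit_ages` | 0, 6 wk, 9 mo, 1.5, 3.5, 7, 8, 9, 10, 11 y | the emulated visit schedule |
| `missingness_prob` | 0.05-0.39, rising with age | per-visit completeness typical of routine + clinic measurement |
| `genotype_missingness` | 2% per variant; 6.7% and 7.7% for the two lower-quality assays | emulates realistic call rates (93.3%, 92.3%) |
| `age_jitter_sd` | 0.06 y | "precise age at measurement": visits do not happen on the nominal day; also keeps age estimable within a visit |
| `sex_ratio` | 0.505 | typical live-birth ratio |

Design choices worth knowing:

* **Score centering.** The injected effect multiplies the score centred at
  its expected value `2*sum(f)`, so marginal SDS stay near N(0,1) at every
  age; slopes are unaffected by centring.
* **Reproducible substreams.** All randomness for subject `i` comes from a
  private substream keyed by `(seed, i)`, drawn in a fixed order. Identical
  seeds give byte-identical cohorts, and enlarging the cohort never perturbs
  existing subjects (both tested). Visit-level draws live inside the
  subject's substream.
* **Missingness is completely at random** per visit, so complete-case
  analyses stay unbiased and estimator behaviour is isolated from
  missingness mechanisms.
* **Derived BMI.** The generator models weight and length; BMI is computed
  from them, and the BMI reference's `S` (0.124) is set so derived BMI SDS
  have approximately unit variance given the shared intercept. Because BMI
  is fully determined by weight and length here, its per-allele effect is a
  *contrast* of the weight and length effects (roughly
  `(S_w g_w - 2 S_l g_l)/S_{bmi}`), noticeably smaller than the weight
  effect — unlike real cohorts, where BMI-specific adiposity variation makes
  the BMI association the strongest. BMI-based quantities from synthetic
  cohorts (BMI effect, variance explained in BMI, overweight/obesity odds)
  are therefore attenuated by construction.
* Body composition at 9 years links fat and fat-free mass indices linearly
  to the child's BMI SDS with sex-specific means, with slopes in the ratio
  observed between adiposity and lean-mass associations (1.6 and 0.4 kg/m²
  per BMI SDS).

What passing tests on synthetic cohorts do **not** show about real data:
secular trends, sibling structure, informative dropout, population
stratification, genotyping batch effects and real reference-vs-cohort
mismatch are all absent by design.

## Validation problem sizes

The packaged checks run the chain end to end at sizes chosen to give each
property the power it needs while staying fast: LMS round trips on 10,000
random parameter tuples; Hardy-Weinberg calibration over 1,000 simulated
variants of 2,000 subjects; type-I error of the score test over 500
null cohorts of 1,000 children; recovery of a 0.08 SDS/allele
cross-sectional effect over 100 cohorts of 5,000; coverage of a 0.005
SDS/allele/y interaction over 100 cohorts of 2,000 children at 8 visits; and
polynomial-interaction size over 200 cohorts of 1,000. The early-versus-late
slope *ordering* check uses 100 cohorts of 20,000 children: under the
generator's noise settings the early-window slope carries a standard error
of about `0.078 * sqrt(7000/n)`, so 20,000 subjects place the injected
early-late separation at ~2.3 standard errors per replicate, the power the
ordering assertion presumes.

## Known limitations

* The conditional-gain operation is defined for one baseline/follow-up pair
  (birth to 6 weeks); arbitrary later age pairs are out of scope.
* No robust/sandwich variances, no multiple-testing correction, no random
  slopes or serial correlation structures, no genotype imputation or LD
  handling.
* Licensed reference and cutoff tables must be supplied by the user; the
  synthetic stand-ins are for testing and demonstration only.
* Wald intervals everywhere; profile-likelihood intervals are not provided.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(sim = sim_config(n_subjects = 2000, seed = 1),
                       outdir = "report", seed = 1)
res <- run_pipeline(cfg)
res$cross_sectional
res$piecewise$slopes
```
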