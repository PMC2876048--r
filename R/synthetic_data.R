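# Synthetic birth-cohort generator.
#
# Individual-level data from the motivating cohort are restricted, so the
# generator fabricates a cohort with the statistical structure the analysis
# assumes: biallelic SNPs in Hardy-Weinberg equilibrium, a latent weight and
# length SDS trajectory per child
#   SDS_i(t) = u_i + g(t) * (score_i - E[score]) + eps_it,
#   u_i ~ N(0, sigma_u^2), eps_it ~ N(0, sigma_e^2),
# with g(t) a piecewise-linear per-allele effect profile (steep in early
# infancy, shallow through childhood), back-transformed through a synthetic
# LMS reference to raw kg/cm values at jittered visit ages, with visit-level
# missingness. The score is centred at its expected value 2*sum(f_j) when the
# effect is injected, so marginal SDS stay near N(0,1) at every age; slopes
# are unaffected by centring.
#
# All randomness for subject i comes from a private substream keyed by
# (seed, i), so enlarging the cohort never perturbs existing subjects.

six_weeks <- 42 / 365.25

subject_seed <- function(seed, i) {
  h <- abs(as.numeric(seed)) %% 2^31
  as.integer((h * 69069 + i * 2654435761) %% 2^31)
}

#' Simulation configuration for the synthetic cohort
#'
#' Defaults encode the study conditions the analysis is designed for: ~7,000
#' children, an 8-variant risk panel in HWE, visits at birth, 6 weeks, 9
#' months, 1.5 and 3.5 years and annually from 7 to 11 years, a per-allele
#' weight-SDS effect rising steeply from birth to 6 weeks (0.119 SDS/allele/y)
#' and gently thereafter (0.004 SDS/allele/y), an analogous length profile
#' that is flat after 6 weeks, strong within-child tracking (random-intercept
#' SD 0.8, residual SD 0.6, total variance 1), visit-level missingness rising
#' with age, and genotype missingness emulating the two lower call-rate
#' assays (93.3% and 92.3%).
#'
#' @param n_subjects Cohort size.
#' @param seed Integer seed; all randomness flows from it.
#' @param panel Variant panel (see [default_panel()]).
#' @param effect_nodes,effect_values Ages (years) and per-allele weight-SDS
#'   effects defining the piecewise-linear profile g(t).
#' @param length_effect_values Per-allele length-SDS effects at the same nodes.
#' @param random_intercept_sd,residual_sd Variance components of the latent
#'   SDS model (SDS units).
#' @param visit_ages Nominal visit ages (decimal years).
#' @param missingness_prob Per-visit probability a visit is missed (recycled
#'   to `length(visit_ages)`).
#' @param genotype_missingness Per-variant probability of a missing call
#'   (recycled to the panel size).
#' @param sex_ratio Probability a child is male.
#' @param age_jitter_sd SD (years) of jitter on the precise age at
#'   measurement; birth is exact.
#' @param fat_mass_params Parameters linking 9-year body composition to the
#'   latent BMI SDS: sex-specific FMI/FFMI means (kg/m^2), slopes per BMI SDS
#'   and residual SDs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 7000,
                       seed = 1,
                       panel = default_panel(8),
                       effect_nodes = c(0, six_weeks, 11),
                       effect_values = c(0.010,
                                         0.010 + 0.119 * six_weeks,
                                         0.010 + 0.119 * six_weeks +
                                           0.004 * (11 - six_weeks)),
                       length_effect_values = c(0.030 - 0.158 * six_weeks,
                                                0.030, 0.030),
                       random_intercept_sd = 0.8,
                       residual_sd = 0.6,
                       visit_ages = c(0, six_weeks, 0.75, 1.5, 3.5,
                                      7, 8, 9, 10, 11),
                       missingness_prob = c(0.05, 0.13, 0.21, 0.26, 0.25,
                                            0.27, 0.38, 0.32, 0.35, 0.39),
                       genotype_missingness = NULL,
                       sex_ratio = 0.505,
                       age_jitter_sd = 0.06,
                       fat_mass_params = list(
                         fmi_mean = c(male = 3.7, female = 4.9),
                         fmi_per_sds = 1.6, fmi_sd = 1.0,
                         ffmi_mean = c(male = 13.0, female = 12.1),
                         ffmi_per_sds = 0.4, ffmi_sd = 0.6)) {
  panel <- validate_panel(panel)
  if (is.null(genotype_missingness)) {
    genotype_missingness <- stats::setNames(rep(0.02, nrow(panel)), panel$rsid)
    genotype_missingness[panel$rsid == "rs925946"] <- 1 - 0.933
    genotype_missingness[panel$rsid == "rs7647305"] <- 1 - 0.923
  }
  genotype_missingness <- rep_len(genotype_missingness, nrow(panel))
  missingness_prob <- rep_len(missingness_prob, length(visit_ages))
  stopifnot(n_subjects >= 1,
            random_intercept_sd >= 0, residual_sd >= 0,
            all(missingness_prob >= 0 & missingness_prob < 1),
            all(genotype_missingness >= 0 & genotype_missingness < 1),
            sex_ratio > 0, sex_ratio < 1,
            length(effect_nodes) == length(effect_values),
            length(effect_nodes) == length(length_effect_values),
            all(diff(effect_nodes) > 0))
  structure(list(
    n_subjects = n_subjects, seed = seed, panel = panel,
    effect_nodes = effect_nodes, effect_values = effect_values,
    length_effect_values = length_effect_values,
    random_intercept_sd = random_intercept_sd, residual_sd = residual_sd,
    visit_ages = visit_ages, missingness_prob = missingness_prob,
    genotype_missingness = genotype_missingness,
    sex_ratio = sex_ratio, age_jitter_sd = age_jitter_sd,
    fat_mass_params = fat_mass_params
  ), class = "sim_config")
}

#' Null simulation configuration
#'
#' Convenience wrapper: no genetic effect on growth (`g(t) = 0` for weight
#' and length), everything else as [sim_config()].
#'
#' @param ... Passed to [sim_config()].
#' @return A `sim_config` with zero effect profiles.
#' @export
null_config <- function(...) {
  sim_config(effect_values = c(0, 0, 0),
             length_effect_values = c(0, 0, 0), ...)
}

#' Synthetic LMS growth reference
#'
#' Fabricates a smooth LMS reference for weight, length/height and BMI over
#' ages 0-12 years for both sexes, as a stand-in for licensed national
#' references. Median weight and length rise monotonically from realistic
#' birth values (3.49 kg / 51.1 cm for boys); the BMI median is derived from
#' the weight and length medians so the three measures are mutually
#' consistent. S is constant per measure within 0.08-0.12 and L is fixed per
#' measure.
#'
#' @param age_grid Tabulation ages (years); the default covers 0-12 at
#'   quarter-year steps plus the 6-week and 9-month visit ages.
#' @return An [lms_reference()] table.
#' @export
simulate_reference <- function(age_grid = sort(unique(c(
  0, six_weeks, 0.25, 0.5, 0.75, seq(1, 12, by = 0.25))))) {
  t <- age_grid
  median_weight <- function(birth, scale) {
    birth + scale * (6.2 * (1 - exp(-t / 0.45)) + 1.6 * t + 0.10 * t^2)
  }
  median_length <- function(birth, scale) {
    birth + scale * (24 * (1 - exp(-t / 0.6)) + 6.2 * t)
  }
  build <- function(sex, wb, ws, lb, ls) {
    mw <- median_weight(wb, ws)
    ml <- median_length(lb, ls)
    dplyr::bind_rows(
      tibble::tibble(sex = sex, measure = "weight", age_years = t,
                     L = -0.2, M = mw, S = 0.12),
      tibble::tibble(sex = sex, measure = "length_height", age_years = t,
                     L = 1.0, M = ml, S = 0.08),
      # S chosen so derived BMI SDS have ~unit variance given the shared
      # intercept and the weight/length S values
      tibble::tibble(sex = sex, measure = "bmi", age_years = t,
                     L = -1.3, M = mw / (ml / 100)^2, S = 0.124)
    )
  }
  lms_reference(dplyr::bind_rows(
    build("male", 3.49, 1.00, 51.1, 1.000),
    build("female", 3.38, 0.95, 50.4, 0.985)
  ))
}

#' Synthetic age-varying BMI cutoff curves
#'
#' Internally consistent stand-in for licensed overweight/obesity cutoff
#' tables: smooth sex-specific curves over ages 2-18 that pass exactly
#' through 25 and 30 kg/m^2 at age 18, with the obesity cutoff above the
#' overweight cutoff at every age.
#'
#' @return A [cutoff_curves()] table.
#' @export
simulate_cutoff_curves <- function() {
  ages <- seq(2, 18, by = 0.5)
  build <- function(sex, e_ow, e_ob) {
    tibble::tibble(
      sex = sex, age_years = ages,
      bmi_overweight_cutoff = 25 * (0.66 + 0.34 * (ages / 18)^e_ow),
      bmi_obese_cutoff = 30 * (0.60 + 0.40 * (ages / 18)^e_ob)
    )
  }
  cutoff_curves(dplyr::bind_rows(build("male", 1.30, 1.60),
                                 build("female", 1.25, 1.55)))
}

# One subject's full set of random draws, in fixed order, from a private
# substream. Everything downstream (genotypes-only or full cohort) consumes
# the same draws so the two views of a subject are consistent.
draw_subject <- function(config, i) {
  set.seed(subject_seed(config$seed, i))
  k <- nrow(config$panel)
  nv <- length(config$visit_ages)
  list(
    sex_u = stats::runif(1),
    dosage = stats::rbinom(k, 2, config$panel$risk_allele_freq),
    geno_miss_u = stats::runif(k),
    u = stats::rnorm(1),
    eps_w = stats::rnorm(nv),
    eps_l = stats::rnorm(nv),
    visit_miss_u = stats::runif(nv),
    age_jit = stats::rnorm(nv),
    fat_noise = stats::rnorm(2)
  )
}

#' Simulate panel genotypes in Hardy-Weinberg equilibrium
#'
#' Draws risk-allele dosages independently per variant as Binomial(2, f_j)
#' and masks calls at the configured per-variant missingness to emulate
#' call rates. Uses the same per-subject substreams as [simulate_cohort()],
#' so the genotypes agree with a cohort generated under the same config.
#'
#' @param config A [sim_config()].
#' @return Tibble: `subject_id` plus one dosage column per panel rsid
#'   (NA = missing call). The true (unmasked) dosages are in attribute
#'   `true_dosage`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  k <- nrow(config$panel)
  true <- matrix(0L, n, k, dimnames = list(NULL, config$panel$rsid))
  miss_u <- matrix(0, n, k)
  for (i in seq_len(n)) {
    d <- draw_subject(config, i)
    true[i, ] <- d$dosage
    miss_u[i, ] <- d$geno_miss_u
  }
  observed <- true
  observed[miss_u < matrix(config$genotype_missingness, n, k, byrow = TRUE)] <- NA
  out <- tibble::as_tibble(observed)
  out <- dplyr::mutate(out, subject_id = seq_len(n), .before = 1)
  attr(out, "true_dosage") <- true
  out
}

#' Simulate a full synthetic birth cohort
#'
#' Generates genotypes, longitudinal weight and length/height measurements,
#' and 9-year body composition under the latent SDS model described in
#' [sim_config()]. Latent SDS are back-transformed through the reference to
#' raw values at each child's jittered visit ages; missed visits drop both
#' the weight and length rows. Output is deterministic given the config seed,
#' and per-subject substreams mean existing subjects are unchanged when
#' `n_subjects` grows.
#'
#' @param config A [sim_config()].
#' @param ref An [lms_reference()]; default [simulate_reference()].
#' @return List of class `synthetic_cohort`: `measurements` (long tibble with
#'   `subject_id`, `sex`, `age_years` (precise), `visit_age` (nominal),
#'   `measure`, `value`), `genotypes` (as [simulate_genotypes()]),
#'   `body_composition` (`subject_id`, `sex`, `age_years`, `fat_mass_kg`,
#'   `fat_free_mass_kg`, `height_m`), `subjects` (per-subject sex, latent
#'   intercept and centred score), and `config`.
#' @export
simulate_cohort <- function(config, ref = simulate_reference()) {
  stopifnot(inherits(config, "sim_config"), inherits(ref, "lms_reference"))
  n <- config$n_subjects
  k <- nrow(config$panel)
  nv <- length(config$visit_ages)

  true <- matrix(0L, n, k, dimnames = list(NULL, config$panel$rsid))
  geno_miss_u <- matrix(0, n, k)
  sex_u <- u <- numeric(n)
  eps_w <- eps_l <- visit_miss_u <- age_jit <- matrix(0, n, nv)
  fat_noise <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    d <- draw_subject(config, i)
    sex_u[i] <- d$sex_u
    true[i, ] <- d$dosage
    geno_miss_u[i, ] <- d$geno_miss_u
    u[i] <- d$u
    eps_w[i, ] <- d$eps_w
    eps_l[i, ] <- d$eps_l
    visit_miss_u[i, ] <- d$visit_miss_u
    age_jit[i, ] <- d$age_jit
    fat_noise[i, ] <- d$fat_noise
  }

  sex <- ifelse(sex_u < config$sex_ratio, "male", "female")
  score_centred <- rowSums(true) - 2 * sum(config$panel$risk_allele_freq)

  # precise ages: nominal visit age + jitter, birth exact, clamped to grid
  nominal <- matrix(config$visit_ages, n, nv, byrow = TRUE)
  ages <- nominal + age_jit * config$age_jitter_sd
  grid_max <- max(ref$age_years)
  ages <- pmin(pmax(ages, 0.02), grid_max)  # keep jittered visits off birth
  ages[, config$visit_ages == 0] <- 0

  g_w <- matrix(stats::approx(config$effect_nodes, config$effect_values,
                              ages, rule = 2)$y, n, nv)
  g_l <- matrix(stats::approx(config$effect_nodes, config$length_effect_values,
                              ages, rule = 2)$y, n, nv)
  z_w <- config$random_intercept_sd * u + g_w * score_centred +
    config$residual_sd * eps_w
  z_l <- config$random_intercept_sd * u + g_l * score_centred +
    config$residual_sd * eps_l

  long <- tibble::tibble(
    subject_id = rep(seq_len(n), times = 2 * nv),
    sex = rep(sex, times = 2 * nv),
    visit = rep(rep(seq_len(nv), each = n), times = 2),
    age_years = c(as.vector(ages), as.vector(ages)),
    visit_age = c(as.vector(nominal), as.vector(nominal)),
    measure = rep(c("weight", "length_height"), each = n * nv),
    z = c(as.vector(z_w), as.vector(z_l))
  )

  lms <- interpolate_lms(ref, long$sex, long$measure, long$age_years)
  bad <- with(lms, abs(L) >= 1e-12 & (1 + L * S * long$z) <= 0)
  iter <- 0
  while (any(bad) && iter < 50) {
    iter <- iter + 1
    set.seed(subject_seed(config$seed, -iter))
    long$z[bad] <- config$random_intercept_sd *
      u[long$subject_id[bad]] +
      stats::approx(config$effect_nodes, config$effect_values,
                    long$age_years[bad], rule = 2)$y *
      score_centred[long$subject_id[bad]] +
      config$residual_sd * stats::rnorm(sum(bad))
    bad <- with(lms, abs(L) >= 1e-12 & (1 + L * S * long$z) <= 0)
  }
  if (iter > 0) message("Resampled ", iter, " round(s) of out-of-domain SDS")
  long$value <- lms_from_sds(long$z, lms$L, lms$M, lms$S)

  observed <- visit_miss_u >= matrix(config$missingness_prob, n, nv,
                                     byrow = TRUE)
  keep <- observed[cbind(long$subject_id, long$visit)]
  measurements <- long[keep, c("subject_id", "sex", "age_years", "visit_age",
                               "measure", "value")]
  measurements <- dplyr::arrange(measurements, .data$subject_id,
                                 .data$age_years, .data$measure)

  geno <- true
  geno[geno_miss_u < matrix(config$genotype_missingness, n, k,
                            byrow = TRUE)] <- NA
  genotypes <- tibble::as_tibble(geno)
  genotypes <- dplyr::mutate(genotypes, subject_id = seq_len(n), .before = 1)
  attr(genotypes, "true_dosage") <- true

  body_composition <- simulate_body_composition(
    config, measurements, ref, fat_noise, sex)

  structure(list(measurements = measurements, genotypes = genotypes,
                 body_composition = body_composition,
                 subjects = tibble::tibble(subject_id = seq_len(n), sex = sex,
                                           intercept = config$random_intercept_sd * u,
                                           score_centred = score_centred),
                 config = config),
            class = "synthetic_cohort")
}

# Body composition at the 9-year visit: FMI/FFMI are linear in the child's
# BMI SDS at 9 y plus noise; masses are recovered as index * height^2.
simulate_body_composition <- function(config, measurements, ref, fat_noise,
                                      sex) {
  if (!any(config$visit_ages == 9)) {
    return(tibble::tibble(subject_id = integer(), sex = character(),
                          age_years = numeric(), fat_mass_kg = numeric(),
                          fat_free_mass_kg = numeric(), height_m = numeric()))
  }
  nine <- measurements[measurements$visit_age == 9, ]
  w9 <- nine[nine$measure == "weight", c("subject_id", "age_years", "value")]
  h9 <- nine[nine$measure == "length_height", c("subject_id", "value")]
  names(w9)[3] <- "weight_kg"; names(h9)[2] <- "height_cm"
  j <- dplyr::inner_join(w9, h9, by = "subject_id")
  if (nrow(j) == 0) return(tibble::tibble(
    subject_id = integer(), sex = character(), age_years = numeric(),
    fat_mass_kg = numeric(), fat_free_mass_kg = numeric(),
    height_m = numeric()))
  j$sex <- sex[j$subject_id]
  bmi9 <- bmi(j$weight_kg, j$height_cm / 100)
  lms <- interpolate_lms(ref, j$sex, rep("bmi", nrow(j)), j$age_years)
  z_bmi <- lms_to_sds(bmi9, lms$L, lms$M, lms$S)
  fp <- config$fat_mass_params
  fmi <- fp$fmi_mean[j$sex] + fp$fmi_per_sds * z_bmi +
    fp$fmi_sd * fat_noise[j$subject_id, 1]
  ffmi <- fp$ffmi_mean[j$sex] + fp$ffmi_per_sds * z_bmi +
    fp$ffmi_sd * fat_noise[j$subject_id, 2]
  fmi <- pmax(fmi, 0.1); ffmi <- pmax(ffmi, 1)
  h_m <- j$height_cm / 100
  tibble::tibble(subject_id = j$subject_id, sex = j$sex,
                 age_years = j$age_years,
                 fat_mass_kg = fmi * h_m^2,
                 fat_free_mass_kg = ffmi * h_m^2,
                 height_m = h_m)
}
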