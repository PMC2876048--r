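test_that("synthetic reference passes its own invariants", {
  ref <- simulate_reference()
  expect_s3_class(ref, "lms_reference")  # constructor enforces invariants
  for (sx in c("male", "female")) {
    for (ms in c("weight", "length_height")) {
      tab <- ref[ref$sex == sx & ref$measure == ms, ]
      expect_true(all(diff(tab$M) > 0))  # median curves rise monotonically
    }
  }
  expect_true(all(ref$S >= 0.08 & ref$S <= 0.15))
  expect_equal(length(unique(ref$L[ref$measure == "weight"])), 1)
  # configured birth medians
  birth_w <- ref[ref$measure == "weight" & ref$age_years == 0, ]
  expect_equal(birth_w$M[birth_w$sex == "male"], 3.49)
  # standardizing the median curve itself gives zero everywhere
  z <- lms_to_sds(ref$M, ref$L, ref$M, ref$S)
  expect_equal(max(abs(z)), 0)
})

test_that("simulated genotypes follow Binomial(2, f) and HWE", {
  cfg <- sim_config(n_subjects = 10000, seed = 51,
                    panel = validate_panel(tibble::tibble(
                      rsid = c("a", "b"), risk_allele = "A",
                      other_allele = "G", risk_allele_freq = c(0.5, 0.1),
                      weight = 1)),
                    genotype_missingness = 0)
  g <- simulate_genotypes(cfg)
  expect_lt(abs(mean(g$a) - 1.0), 0.03)
  expect_lt(abs(mean(g$b) - 0.2), 0.03)
  counts <- genotype_counts(g, "a")
  expect_gt(hwe_test(counts$n_rr, counts$n_rh, counts$n_hh)$p_value, 1e-4)
  # missingness emulates call rates
  cfg2 <- sim_config(n_subjects = 5000, seed = 52)
  g2 <- simulate_genotypes(cfg2)
  expect_equal(call_rate(g2, "rs925946"), 0.933, tolerance = 0.02)
  expect_equal(call_rate(g2, "rs7647305"), 0.923, tolerance = 0.02)
})

test_that("cohort generation is deterministic and stable under growth", {
  cfg <- sim_config(n_subjects = 300, seed = 53)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$body_composition, b$body_composition)
  # adding subjects never perturbs existing ones
  big <- simulate_cohort(sim_config(n_subjects = 400, seed = 53))
  expect_identical(a$measurements,
                   big$measurements[big$measurements$subject_id <= 300, ])
  strip <- function(x) {
    attr(x, "true_dosage") <- NULL
    as.data.frame(x)
  }
  expect_identical(strip(a$genotypes),
                   strip(big$genotypes[big$genotypes$subject_id <= 300, ]))
  # different seeds give different cohorts
  other <- simulate_cohort(sim_config(n_subjects = 300, seed = 54))
  expect_false(identical(a$measurements$value, other$measurements$value))
})

test_that("null configuration yields i.i.d. standard-normal SDS and flat profile", {
  cfg <- null_config(n_subjects = 1500, seed = 55,
                     visit_ages = c(0, 0.75, 9), missingness_prob = 0,
                     random_intercept_sd = 0, residual_sd = 1)
  coh <- simulate_cohort(cfg)
  sds <- standardize_cohort(coh$measurements, simulate_reference())
  w <- sds[sds$measure == "weight", ]
  per_age <- tapply(w$sds, w$visit_age, function(z) c(mean(z), sd(z)))
  for (z in per_age) {
    expect_lt(abs(z[1]), 4 / sqrt(1500))
    expect_gt(z[2], 0.9); expect_lt(z[2], 1.1)
  }
  scores <- risk_allele_score(coh$genotypes, cfg$panel,
                              require_complete = FALSE)
  prof <- suppressMessages(
    per_age_profile(sds, scores, ages = cfg$visit_ages,
                    measures = "weight"))
  expect_true(all(abs(prof$effect_per_allele) < 0.05))
})

test_that("stronger effect profiles raise every per-age coefficient", {
  levels <- c(0, 0.05, 0.15)
  profiles <- lapply(levels, function(eff) {
    cfg <- sim_config(n_subjects = 2500, seed = 56,
                      effect_values = rep(eff, 3),
                      length_effect_values = rep(0, 3),
                      visit_ages = c(0, 1.5, 9), missingness_prob = 0)
    coh <- simulate_cohort(cfg)
    sds <- standardize_cohort(coh$measurements, simulate_reference())
    scores <- suppressMessages(risk_allele_score(coh$genotypes, cfg$panel))
    suppressMessages(per_age_profile(sds, scores, ages = cfg$visit_ages,
                                     measures = "weight"))
  })
  for (age_i in seq_len(nrow(profiles[[1]]))) {
    ests <- vapply(profiles, function(p) p$effect_per_allele[age_i],
                   numeric(1))
    expect_true(all(diff(ests) > 0))
  }
})

test_that("measurement values are the back-transformed latent SDS", {
  cfg <- sim_config(n_subjects = 50, seed = 57, missingness_prob = 0)
  ref <- simulate_reference()
  coh <- simulate_cohort(cfg, ref)
  # round trip: standardizing the raw values recovers finite SDS, and the
  # weight values sit in a plausible biological range at every age
  w <- coh$measurements[coh$measurements$measure == "weight", ]
  expect_true(all(w$value > 0.5 & w$value < 120))
  sds <- standardize_cohort(coh$measurements, ref)
  expect_true(all(is.finite(sds$sds)))
  # body composition only for children seen at the 9-year visit
  expect_true(all(coh$body_composition$subject_id %in%
                    w$subject_id[w$visit_age == 9]))
  expect_true(all(coh$body_composition$fat_mass_kg >= 0))
})
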