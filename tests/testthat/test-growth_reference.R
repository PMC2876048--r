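test_that("LMS interpolation is exact at grid points and linear between them", {
  ref <- toy_reference()
  # grid point: the tabulated row comes back unchanged
  at1 <- interpolate_lms(ref, "male", "weight", 1)
  expect_equal(unlist(at1), c(L = -0.4, M = 9.5, S = 0.12))
  # midpoint: arithmetic mean of the bracketing rows
  mid <- interpolate_lms(ref, "male", "weight", 1.5)
  expect_equal(unlist(mid), c(L = (-0.4 - 0.3) / 2, M = (9.5 + 12.5) / 2,
                              S = 0.12))
  # random ages: match an independent piecewise-linear evaluation
  set.seed(42)
  ages <- runif(50, 0, 10)
  got <- interpolate_lms(ref, "male", "weight", ages)
  tab <- ref[ref$sex == "male" & ref$measure == "weight", ]
  manual <- t(vapply(ages, function(a) {
    i <- max(which(tab$age_years <= a))
    if (i == nrow(tab)) i <- i - 1
    w <- (a - tab$age_years[i]) / (tab$age_years[i + 1] - tab$age_years[i])
    c((1 - w) * tab$L[i] + w * tab$L[i + 1],
      (1 - w) * tab$M[i] + w * tab$M[i + 1],
      (1 - w) * tab$S[i] + w * tab$S[i + 1])
  }, numeric(3)))
  expect_equal(unname(as.matrix(got)), unname(manual), tolerance = 1e-12)
})

test_that("interpolation refuses to extrapolate", {
  ref <- toy_reference()
  expect_error(interpolate_lms(ref, "male", "weight", 10.5), "outside")
  expect_error(interpolate_lms(ref, "male", "weight", -0.1), "outside")
  expect_error(interpolate_lms(ref, "male", "bmi", 5), "No reference rows")
})

test_that("LMS transform maps the median to zero and is linear when L = 1", {
  expect_equal(lms_to_sds(9.5, -0.4, 9.5, 0.12), 0)
  expect_equal(lms_to_sds(10 * 1.08, 1, 10, 0.08), 1)
  # continuity in L at 0: near the median the power branch at |L| = 1e-6
  # matches the log branch to 1e-8 (the leading error term is L*log(x/M)^2/2S)
  x <- 9.5 * c(0.98, 1, 1.02); M <- 9.5; S <- 0.12
  log_branch <- log(x / M) / S
  expect_lt(max(abs(lms_to_sds(x, 1e-6, M, S) - log_branch)), 1e-8)
  expect_lt(max(abs(lms_to_sds(x, -1e-6, M, S) - log_branch)), 1e-8)
  # and over a wide value range the two branches stay within the error bound
  xw <- 9.5 * seq(0.5, 2, by = 0.1)
  bound <- 1e-6 * log(xw / M)^2 / (2 * S) + 1e-9
  expect_true(all(abs(lms_to_sds(xw, 1e-6, M, S) - log(xw / M) / S) <= bound))
})

test_that("LMS transform rejects non-positive inputs", {
  expect_error(lms_to_sds(0, -0.4, 9.5, 0.12), "positive")
  expect_error(lms_to_sds(5, -0.4, -1, 0.12), "M > 0")
  expect_error(lms_from_sds(0, -0.4, 9.5, -0.1), "S > 0")
})

test_that("from_sds inverts to_sds to 1e-9 across the valid domain", {
  expect_equal(lms_from_sds(0, -0.4, 9.5, 0.12), 9.5)
  expect_equal(lms_from_sds(1, 1, 10, 0.08), 10.8)
  set.seed(7)
  n <- 1000
  L <- runif(n, -2, 2); L[sample(n, 50)] <- 0
  M <- runif(n, 2, 50); S <- runif(n, 0.05, 0.2); z <- rnorm(n)
  ok <- abs(L) < 1e-12 | (1 + L * S * z) > 0
  L <- L[ok]; M <- M[ok]; S <- S[ok]; z <- z[ok]
  round_trip <- lms_to_sds(lms_from_sds(z, L, M, S), L, M, S)
  expect_lt(max(abs(round_trip - z)), 1e-9)
  # inverse undefined beyond the domain boundary
  expect_error(lms_from_sds(-100, 1, 10, 0.08), "undefined")
})

test_that("standardize_cohort recovers zeros at the median and flags bad rows", {
  ref <- toy_reference()
  m <- tibble::tibble(
    subject_id = 1:4,
    sex = c("male", "male", "female", "male"),
    age_years = c(1, 2, 1, 12),          # last is out of range
    measure = "weight",
    value = c(9.5, 12.5, 9.1, 20)
  )
  expect_message(out <- standardize_cohort(m, ref), "excluded")
  expect_equal(nrow(out), 3)
  expect_equal(out$sds[1:3], c(0, 0, 0), tolerance = 1e-12)
  exc <- attr(out, "excluded")
  expect_equal(exc$subject_id, 4)
  expect_match(exc$reason, "outside")

  # empty input gives an empty table
  empty <- standardize_cohort(m[0, ], ref)
  expect_equal(nrow(empty), 0)
  expect_true("sds" %in% names(empty))

  # unknown codes are a validation error naming rows
  bad <- m; bad$measure[2] <- "head_circumference"
  expect_error(standardize_cohort(bad, ref), "Invalid sex/measure")
})

test_that("standardizing the reference median curve gives exactly zero", {
  ref <- simulate_reference()
  m <- tibble::tibble(
    subject_id = seq_len(nrow(ref)), sex = ref$sex,
    age_years = ref$age_years, measure = ref$measure, value = ref$M
  )
  out <- standardize_cohort(m, ref)
  expect_equal(max(abs(out$sds)), 0, tolerance = 1e-12)
})

test_that("null synthetic cohort standardizes to mean 0, SD 1 per age", {
  cfg <- null_config(n_subjects = 1200, seed = 5,
                     visit_ages = c(0, 42 / 365.25, 1.5, 9),
                     missingness_prob = 0, residual_sd = 0.6,
                     random_intercept_sd = 0.8)
  coh <- simulate_cohort(cfg)
  sds <- standardize_cohort(coh$measurements, simulate_reference())
  per_age <- dplyr::summarise(
    dplyr::group_by(sds[sds$measure %in% c("weight", "length_height"), ],
                    .data$visit_age, .data$measure),
    m = mean(.data$sds), s = sd(.data$sds), n = dplyr::n(), .groups = "drop"
  )
  expect_true(all(abs(per_age$m) < 4 / sqrt(per_age$n)))
  expect_true(all(per_age$s > 0.9 & per_age$s < 1.1))
})
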