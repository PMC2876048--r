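test_that("linear_assoc recovers a noiseless slope exactly", {
  d <- tibble::tibble(score = rep(0:16, 10))
  d$y <- 0.1 * d$score
  res <- suppressWarnings(linear_assoc(d, "y"))  # lm flags the perfect fit
  expect_equal(res$effect_per_allele, 0.1, tolerance = 1e-12)
  expect_equal(res$ci_high - res$ci_low, 0, tolerance = 1e-10)
  expect_equal(res$n, 170)
})

test_that("linear_assoc rejects degenerate designs", {
  d <- tibble::tibble(score = rep(5, 50), y = rnorm(50))
  expect_error(linear_assoc(d, "y"), "no variance")
  d2 <- tibble::tibble(score = rnorm(100), y = rnorm(100))
  d2$twin <- d2$score  # collinear covariate
  expect_error(linear_assoc(d2, "y", covariates = "twin"), "collinear|Rank",
               ignore.case = TRUE)
})

test_that("linear_assoc standard error matches the closed-form OLS variance", {
  set.seed(15)
  n <- 5000
  score <- rbinom(n, 16, 0.45)
  y <- 0.08 * score + rnorm(n)
  res <- linear_assoc(tibble::tibble(score = score, y = y), "y")
  se_expected <- 1 / (sqrt(n) * sd(score))
  se_observed <- (res$ci_high - res$effect_per_allele) / 1.96
  expect_lt(abs(res$effect_per_allele - 0.08), 2 * se_observed)
  expect_lt(abs(se_observed - se_expected) / se_expected, 0.05)
})

test_that("logistic_assoc is calibrated under the null and recovers an OR", {
  set.seed(16)
  n <- 10000
  score <- rbinom(n, 16, 0.45)
  y <- rbinom(n, 1, 0.3)
  res <- logistic_assoc(tibble::tibble(score = score, y = y), "y")
  expect_gt(res$or_per_allele, 0.93)
  expect_lt(res$or_per_allele, 1.07)
  expect_equal(res$n_cases, sum(y))

  # parameter recovery: injected log-OR covered by the Wald CI in >= 90/100
  beta <- log(1.15)
  covered <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    s <- rbinom(2000, 16, 0.45)
    p <- plogis(-2 + beta * (s - mean(s)))
    yy <- rbinom(2000, 1, p)
    r <- logistic_assoc(tibble::tibble(score = s, y = yy), "y")
    r$ci_low <= 1.15 && 1.15 <= r$ci_high
  }, logical(1))
  expect_gte(sum(covered), 90)
})

test_that("complete separation is an explicit error", {
  d <- tibble::tibble(score = c(rep(0, 30), rep(10, 30)),
                      y = c(rep(0, 30), rep(1, 30)))
  expect_error(logistic_assoc(d, "y"), "separation")
  expect_error(logistic_assoc(tibble::tibble(score = 1:30, y = 1), "y"),
               "Both outcome classes")
})

test_that("linear and logistic associations agree in sign", {
  for (i in 1:10) {
    set.seed(200 + i)
    s <- rbinom(3000, 16, 0.45)
    p <- plogis(-1 + 0.04 * (i - 5) * (s - mean(s)))
    y <- rbinom(3000, 1, p)
    if (length(unique(y)) < 2) next
    lin <- linear_assoc(tibble::tibble(score = s, y = y), "y")
    log_ <- logistic_assoc(tibble::tibble(score = s, y = y), "y")
    expect_equal(sign(lin$effect_per_allele), sign(log(log_$or_per_allele)))
  }
})

test_that("variance_explained isolates the score's R-squared increment", {
  set.seed(17)
  n <- 5000
  score <- rbinom(n, 16, 0.45)
  # score orthogonal to the outcome: increment ~ 0
  y0 <- rnorm(n)
  expect_lt(variance_explained(tibble::tibble(score = score, y = y0), "y"),
            0.002)
  # noiseless outcome: increment 1 with no covariates
  y1 <- 0.3 * score
  expect_equal(suppressWarnings(
    variance_explained(tibble::tibble(score = score, y = y1), "y")),
    1, tolerance = 1e-10)
  # constructed so the score explains 1.7% of the outcome variance
  target <- 0.017
  b <- sqrt(target / (1 - target)) / sd(score)
  y2 <- b * score + rnorm(n)
  expect_lt(abs(variance_explained(tibble::tibble(score = score, y = y2),
                                   "y") - target), 0.006)
})

test_that("per_age_profile reduces to linear_assoc at a single age", {
  set.seed(18)
  n <- 400
  sds <- tibble::tibble(
    subject_id = seq_len(n), sex = sample(c("male", "female"), n, TRUE),
    age_years = 9 + rnorm(n, 0, 0.05), visit_age = 9, measure = "weight",
    sds = rnorm(n)
  )
  scores <- tibble::tibble(subject_id = seq_len(n),
                           score = rbinom(n, 16, 0.45))
  prof <- per_age_profile(sds, scores, ages = 9)
  d <- dplyr::inner_join(sds, scores, by = "subject_id")
  direct <- linear_assoc(d, "sds", covariates = c("sex", "age_years"))
  expect_equal(nrow(prof), 1)
  expect_equal(prof$effect_per_allele, direct$effect_per_allele)
  expect_equal(prof$p_value, direct$p_value)
  expect_equal(prof$age_years, 9)
})

test_that("per_age_profile tracks where in childhood the effect acts", {
  # effect injected only after age 3: near-zero profile before, positive after
  set.seed(19)
  n <- 1500
  ages <- c(0.5, 2, 5, 9)
  scores <- tibble::tibble(subject_id = seq_len(n),
                           score = rbinom(n, 16, 0.45))
  g <- function(a) ifelse(a > 3, 0.08, 0)
  sds <- tidyr::expand_grid(subject_id = seq_len(n), visit_age = ages)
  sds$age_years <- sds$visit_age
  sds$sex <- sample(c("male", "female"), nrow(sds), TRUE)
  sds$measure <- "weight"
  sc <- scores$score[sds$subject_id]
  sds$sds <- g(sds$visit_age) * (sc - mean(sc)) + rnorm(nrow(sds))
  prof <- suppressMessages(
    per_age_profile(sds, scores, ages = ages, covariates = "sex"))
  early <- prof$effect_per_allele[prof$age_years < 3]
  late <- prof$effect_per_allele[prof$age_years > 3]
  expect_true(all(abs(early) < 0.03))
  expect_true(all(late > 0.05))
})
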