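# Cross-sectional association of the risk-allele score with outcomes.
#
# Linear models for continuous (SDS) outcomes and logistic models for binary
# outcomes, always complete-case, with Wald 95% confidence intervals
# (estimate +/- 1.96 * SE) matching the symmetric intervals conventional in
# this literature.

complete_case_frame <- function(data, cols) {
  d <- tibble::as_tibble(data)[, cols]
  d[stats::complete.cases(d), ]
}

check_rank <- function(fit) {
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("Rank-deficient design; collinear column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  invisible(fit)
}

#' Linear association of an outcome with the risk-allele score
#'
#' Ordinary least squares of `outcome ~ score + covariates` on complete
#' cases. The per-allele effect is the coefficient on the score, with Wald
#' 95% CI (normal approximation) and two-sided p-value.
#'
#' @param data Data frame holding all model columns.
#' @param outcome Name of the outcome column (e.g. a BMI SDS column).
#' @param score Name of the score column.
#' @param covariates Character vector of adjustment columns (may be empty).
#' @param label Outcome label carried into the result; defaults to `outcome`.
#' @return One-row tibble: `outcome`, `n`, `effect_per_allele`, `ci_low`,
#'   `ci_high`, `p_value`.
#' @export
linear_assoc <- function(data, outcome, score = "score",
                         covariates = character(), label = outcome) {
  d <- complete_case_frame(data, c(outcome, score, covariates))
  if (nrow(d) <= length(covariates) + 2) {
    stop("Too few complete cases to fit the model", call. = FALSE)
  }
  if (stats::sd(d[[score]]) == 0) {
    stop("Score has no variance in the analysis sample", call. = FALSE)
  }
  f <- stats::reformulate(c(score, covariates), response = outcome)
  fit <- stats::lm(f, data = d)
  check_rank(fit)
  est <- stats::coef(fit)[[score]]
  se <- sqrt(diag(stats::vcov(fit)))[[score]]
  z <- est / se
  tibble::tibble(
    outcome = label,
    n = nrow(d),
    effect_per_allele = est,
    ci_low = est - 1.96 * se,
    ci_high = est + 1.96 * se,
    p_value = 2 * stats::pnorm(-abs(z))
  )
}

#' Per-age association profile of the score
#'
#' Repeats [linear_assoc()] at each measurement occasion and measure,
#' producing the per-age coefficient profile (effect of one risk allele on
#' the SDS outcome at each age from birth onward). Rows are matched to a
#' nominal visit age within `age_tol`. Covariates that are constant within an
#' age stratum (e.g. age at birth, which is exactly 0 for everyone) are
#' dropped from that stratum's model with a message.
#'
#' @param sds_table Long SDS table ([standardize_cohort()] output).
#' @param scores Tibble (`subject_id`, `score`) from [risk_allele_score()].
#' @param ages Nominal visit ages (decimal years).
#' @param measures Measures to profile; default all present.
#' @param covariates Adjustment columns found in `sds_table` (default sex and
#'   precise age).
#' @param age_tol Half-width of the age window matching rows to visits; when
#'   the table carries a nominal `visit_age` column it is matched exactly
#'   instead.
#' @param min_n Minimum complete cases per stratum (strata below are skipped).
#' @return Tibble with one [linear_assoc()] row per age x measure, plus
#'   `measure` and `age_years` columns.
#' @export
per_age_profile <- function(sds_table, scores, ages,
                            measures = NULL,
                            covariates = c("sex", "age_years"),
                            age_tol = 0.25, min_n = 50) {
  s <- tibble::as_tibble(sds_table)
  if (is.null(measures)) measures <- unique(s$measure)
  d <- dplyr::inner_join(s, scores[, c("subject_id", "score")],
                         by = "subject_id")
  has_visit <- "visit_age" %in% names(d)
  res <- list()
  for (ms in measures) {
    for (a in ages) {
      in_window <- if (has_visit) abs(d$visit_age - a) <= 1e-9
                   else abs(d$age_years - a) <= age_tol
      stratum <- d[d$measure == ms & in_window, ]
      stratum <- stratum[stats::complete.cases(
        stratum[, c("sds", "score", intersect(covariates, names(stratum)))]), ]
      if (nrow(stratum) < min_n) next
      covs <- intersect(covariates, names(stratum))
      constant <- vapply(covs, function(cc) {
        v <- stratum[[cc]]
        length(unique(v)) < 2
      }, logical(1))
      if (any(constant)) {
        message("Dropping constant covariate(s) at age ", signif(a, 3), ": ",
                paste(covs[constant], collapse = ", "))
        covs <- covs[!constant]
      }
      row <- linear_assoc(stratum, "sds", score = "score",
                          covariates = covs, label = ms)
      row <- dplyr::mutate(row, measure = ms, age_years = a,
                           .before = "outcome")
      res[[length(res) + 1]] <- row
    }
  }
  dplyr::bind_rows(res)
}

#' Logistic association of a binary outcome with the score
#'
#' Maximum-likelihood logistic regression of a binary outcome (e.g. failure
#' to thrive, overweight-or-obese) on the score plus covariates; reports the
#' odds ratio per allele with Wald 95% CI. Complete separation is an explicit
#' error rather than a silently non-converged fit.
#'
#' @inheritParams linear_assoc
#' @param outcome Name of a binary (0/1 or logical) outcome column.
#' @return One-row tibble: `outcome`, `n_cases`, `n_total`, `or_per_allele`,
#'   `ci_low`, `ci_high`, `p_value`.
#' @export
logistic_assoc <- function(data, outcome, score = "score",
                           covariates = character(), label = outcome) {
  d <- complete_case_frame(data, c(outcome, score, covariates))
  y <- as.numeric(d[[outcome]])
  if (!all(y %in% c(0, 1))) {
    stop("Outcome must be binary (0/1 or logical)", call. = FALSE)
  }
  if (length(unique(y)) < 2) {
    stop("Both outcome classes must be present", call. = FALSE)
  }
  d[[outcome]] <- y
  f <- stats::reformulate(c(score, covariates), response = outcome)
  boundary_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(f, data = d, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        boundary_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  eta <- stats::predict(fit, type = "link")
  separated <- min(eta[y == 1]) > max(eta[y == 0]) ||
               max(eta[y == 1]) < min(eta[y == 0])
  # classes split perfectly on the linear predictor and the fit sits on the
  # boundary of the parameter space: the ML odds ratio does not exist
  if (separated && (fit$deviance < 1e-6 || boundary_warn || !fit$converged)) {
    stop("Complete separation: outcome classes do not overlap on the linear ",
         "predictor; odds ratio is not estimable", call. = FALSE)
  }
  if (!fit$converged) {
    stop("Logistic model failed to converge", call. = FALSE)
  }
  check_rank(fit)
  est <- stats::coef(fit)[[score]]
  se <- sqrt(diag(stats::vcov(fit)))[[score]]
  tibble::tibble(
    outcome = label,
    n_cases = sum(y == 1),
    n_total = nrow(d),
    or_per_allele = exp(est),
    ci_low = exp(est - 1.96 * se),
    ci_high = exp(est + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(est / se))
  )
}

#' Variance in an outcome explained by the score
#'
#' Increment in R-squared when the score is added to the covariate-only
#' model: `R2(covariates + score) - R2(covariates)`.
#'
#' @inheritParams linear_assoc
#' @return Incremental R-squared in `[0, 1]`.
#' @export
variance_explained <- function(data, outcome, score = "score",
                               covariates = character()) {
  d <- complete_case_frame(data, c(outcome, score, covariates))
  if (nrow(d) <= length(covariates) + 2) {
    stop("Too few complete cases to fit the model", call. = FALSE)
  }
  full <- stats::lm(stats::reformulate(c(score, covariates), response = outcome),
                    data = d)
  check_rank(full)
  reduced_terms <- if (length(covariates) > 0) covariates else "1"
  reduced <- stats::lm(stats::reformulate(reduced_terms, response = outcome),
                       data = d)
  r2 <- function(fit) summary(fit)$r.squared
  max(0, r2(full) - r2(reduced))
}
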