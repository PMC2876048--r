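# Random-intercept longitudinal models of SDS trajectories.
#
# Repeated SDS measurements cluster within children; a subject-level random
# intercept absorbs stable between-child differences. The score-by-age
# interaction is the quantity of interest: how much stronger the per-allele
# effect on the outcome becomes per year of age, i.e. the per-allele effect
# on the *rate* of SDS change. Estimation is maximum likelihood (not REML)
# so that models with different fixed effects (the polynomial interaction
# checks) are compared on valid likelihoods.

default_lmm_control <- function() {
  lme4::lmerControl(
    calc.derivs = FALSE,
    check.conv.singular = "ignore",
    check.scaleX = "ignore",
    optCtrl = list(xtol_abs = 1e-12, ftol_abs = 1e-12)
  )
}

fixed_effect_table <- function(est, se) {
  z <- est / se
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    ci_low = unname(est - 1.96 * se),
    ci_high = unname(est + 1.96 * se),
    p_value = unname(2 * stats::pnorm(-abs(z)))
  )
}

new_mixed_fit <- function(fixed, sigma_u, sigma_e, logLik, n_obs, n_subjects,
                          converged, method) {
  structure(
    list(fixed = fixed, sigma_u = sigma_u, sigma_e = sigma_e,
         logLik = logLik, n_obs = n_obs, n_subjects = n_subjects,
         converged = converged, method = method),
    class = "mixed_fit"
  )
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat("Random-intercept model (", x$method, "), ", x$n_obs, " obs / ",
      x$n_subjects, " subjects\n", sep = "")
  cat("  random-intercept SD:", signif(x$sigma_u, 5),
      " residual SD:", signif(x$sigma_e, 5),
      " logLik:", signif(x$logLik, 8), "\n")
  print(as.data.frame(x$fixed), digits = 4)
  invisible(x)
}

#' Fit a random-intercept model to repeated SDS outcomes
#'
#' Maximum-likelihood linear mixed model
#' `outcome_sds ~ fixed terms + (1 | subject_id)`, with Wald 95% CIs on the
#' fixed effects. If no subject contributes two or more observations (or
#' replication is negligible) the random intercept is unidentifiable and the
#' fit falls back to pooled OLS with a warning.
#'
#' @param obs Long data frame with columns `subject_id`, `age_years`,
#'   `outcome_sds`, `score`, and any further covariates named in
#'   `model_terms` (by default `sex`).
#' @param model_terms Character vector of fixed-effect terms; the default
#'   fits score, age, their interaction, and sex.
#' @return A `mixed_fit` object: `fixed` (term/estimate/se/ci/p tibble),
#'   `sigma_u` (random-intercept SD), `sigma_e` (residual SD), `logLik`,
#'   `n_obs`, `n_subjects`, `converged`, `method`.
#' @export
fit_random_intercepts <- function(obs,
                                  model_terms = c("score", "age_years",
                                                  "score:age_years", "sex")) {
  d <- tibble::as_tibble(obs)
  needed <- unique(c("subject_id", "outcome_sds",
                     all.vars(stats::reformulate(c(model_terms, "1")))))
  d <- d[stats::complete.cases(d[, intersect(needed, names(d))]), ]
  if (nrow(d) == 0) stop("No complete observations to fit", call. = FALSE)
  obs_per_subject <- table(d$subject_id)
  n_subjects <- length(obs_per_subject)

  rhs <- if (length(model_terms) > 0) model_terms else "1"
  if (mean(obs_per_subject) < 1.5) {
    warning("Fewer than 2 observations per subject on average; random ",
            "intercept not identifiable, falling back to pooled OLS",
            call. = FALSE)
    fit <- stats::lm(stats::reformulate(rhs, response = "outcome_sds"),
                     data = d)
    check_rank(fit)
    est <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    n <- nrow(d)
    sigma_e_ml <- sqrt(sum(stats::residuals(fit)^2) / n)
    return(new_mixed_fit(fixed_effect_table(est, se), 0, sigma_e_ml,
                         as.numeric(stats::logLik(fit)), n, n_subjects,
                         TRUE, "ols"))
  }

  f <- stats::as.formula(paste("outcome_sds ~", paste(rhs, collapse = " + "),
                               "+ (1 | subject_id)"))
  fit <- lme4::lmer(f, data = d, REML = FALSE, control = default_lmm_control())
  opt_ok <- is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt == 0
  if (!opt_ok) {
    stop("Random-intercept model failed to converge; optimizer messages: ",
         paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; "),
         call. = FALSE)
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_u <- vc$sdcor[vc$grp == "subject_id"]
  sigma_e <- vc$sdcor[vc$grp == "Residual"]
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  new_mixed_fit(fixed_effect_table(est, se), sigma_u, sigma_e,
                as.numeric(stats::logLik(fit)), nrow(d), n_subjects,
                TRUE, "ml")
}

#' Piecewise early-infancy and childhood score-by-age slopes
#'
#' Fits two independent random-intercept models on age windows split at the
#' 6-week visit: birth to 6 weeks (where the per-allele effect on the rate of
#' weight gain is expected to be much larger) and 6 weeks onward. The
#' boundary observation is included in both windows.
#'
#' @inheritParams fit_random_intercepts
#' @param breakpoint_years Window boundary, default 6 weeks (42/365.25 y).
#' @param boundary_tol Half-width (years) around the breakpoint within which
#'   observations count as boundary visits belonging to both windows; covers
#'   jitter in the precise age at the 6-week measurement.
#' @return List with elements `early` and `late` (`mixed_fit` objects) and
#'   `slopes`, a tibble of the two score-by-age coefficients.
#' @export
piecewise_slopes <- function(obs,
                             model_terms = c("score", "age_years",
                                             "score:age_years", "sex"),
                             breakpoint_years = 42 / 365.25,
                             boundary_tol = 0.05) {
  d <- tibble::as_tibble(obs)
  early <- d[d$age_years <= breakpoint_years + boundary_tol, ]
  late <- d[d$age_years >= breakpoint_years - boundary_tol, ]
  if (nrow(early) == 0 || nrow(late) == 0) {
    stop("Both age windows must be non-empty", call. = FALSE)
  }
  fit_early <- fit_random_intercepts(early, model_terms)
  fit_late <- fit_random_intercepts(late, model_terms)
  slope <- function(fit, window) {
    row <- fit$fixed[fit$fixed$term == "score:age_years", ]
    dplyr::mutate(row, window = window, .before = "term")
  }
  list(early = fit_early, late = fit_late,
       slopes = dplyr::bind_rows(slope(fit_early, "birth_to_6wk"),
                                 slope(fit_late, "6wk_onward")))
}

#' Wald tests for polynomial score-by-age interactions
#'
#' Extends the random-intercept model with score-by-age-squared (and -cubed)
#' terms and reports their Wald p-values. Non-significant higher-order terms
#' support a linear-in-age per-allele effect.
#'
#' @inheritParams fit_random_intercepts
#' @param max_degree Highest age power interacted with the score (2 or 3);
#'   `max_degree = 1` returns an empty table (no higher-order terms).
#' @return Tibble (`term`, `estimate`, `se`, `p_value`) for the degree >= 2
#'   interaction terms.
#' @export
polynomial_interaction_test <- function(obs,
                                        model_terms = c("score", "age_years",
                                                        "score:age_years",
                                                        "sex"),
                                        max_degree = 3) {
  stopifnot(max_degree >= 1, max_degree <= 3)
  if (max_degree == 1) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          se = numeric(), p_value = numeric()))
  }
  d <- tibble::as_tibble(obs)
  extra <- character()
  if (max_degree >= 2) {
    d$age2 <- d$age_years^2
    extra <- c(extra, "age2", "score:age2")
  }
  if (max_degree >= 3) {
    d$age3 <- d$age_years^3
    extra <- c(extra, "age3", "score:age3")
  }
  fit <- fit_random_intercepts(d, c(model_terms, extra))
  keep <- fit$fixed$term %in% c("score:age2", "score:age3")
  fit$fixed[keep, c("term", "estimate", "se", "p_value")]
}
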