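# Config-driven orchestration of the full analysis chain.

#' Pipeline configuration
#'
#' Collects inputs and analysis settings for [run_pipeline()]. Each data
#' input may be a file path (CSV, read with the package readers), an
#' in-memory data frame, or `NULL`. When `measurements` is `NULL` the
#' pipeline simulates a cohort from `sim` (so a demo run needs no files).
#'
#' @param measurements,genotypes,reference,cutoffs,body_composition Data
#'   inputs (path, data frame, or NULL).
#' @param panel Panel choice: `"eight"`, `"ten"`, or a path/data frame for a
#'   custom panel.
#' @param sim A [sim_config()] used when no measurements are supplied.
#' @param baseline_age,followup_age Conditional-gain ages (years).
#' @param covariates Per-outcome adjustment sets: `sds` for SDS outcomes,
#'   `body_comp` for fat/fat-free mass indices, `binary` for logistic models.
#' @param cross_sectional_age Age (years) of the cross-sectional analysis.
#' @param age_tol Age window half-width matching rows to nominal visits.
#' @param outdir Optional report directory; tables are written when set.
#' @param seed Seed recorded in the run log and used for any simulation.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(measurements = NULL, genotypes = NULL,
                            panel = "eight", reference = NULL,
                            cutoffs = NULL, body_composition = NULL,
                            sim = NULL,
                            baseline_age = 0, followup_age = six_weeks,
                            covariates = list(
                              sds = c("sex", "age_years"),
                              body_comp = c("sex", "age_years", "height_m"),
                              binary = "sex"),
                            cross_sectional_age = 9,
                            age_tol = 0.25,
                            outdir = NULL, seed = 1) {
  structure(list(measurements = measurements, genotypes = genotypes,
                 panel = panel, reference = reference, cutoffs = cutoffs,
                 body_composition = body_composition, sim = sim,
                 baseline_age = baseline_age, followup_age = followup_age,
                 covariates = covariates,
                 cross_sectional_age = cross_sectional_age,
                 age_tol = age_tol, outdir = outdir, seed = seed),
            class = "pipeline_config")
}

resolve_input <- function(x, reader) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1) return(reader(x))
  if (is.data.frame(x)) return(tibble::as_tibble(x))
  x
}

resolve_panel <- function(panel) {
  if (is.character(panel) && length(panel) == 1) {
    if (panel == "eight") return(default_panel(8))
    if (panel == "ten") return(default_panel(10))
    return(read_panel(panel))
  }
  validate_panel(panel)
}

#' Per-score-value outcome summary
#'
#' Tabulates, for each observed (integer) score value, the number of
#' subjects and the mean outcome with its 95% CI (`mean +/- 1.96 * SD/sqrt(n)`)
#' -- the score-distribution figure in table form. Score values carried by a
#' single subject have an undefined CI and are flagged.
#'
#' @param scores Tibble (`subject_id`, `score`), integer-valued scores.
#' @param outcomes Tibble (`subject_id`, `outcome`) of the outcome (e.g. BMI
#'   SDS at 9 y).
#' @return Tibble (`score`, `n`, `mean_outcome`, `ci_low`, `ci_high`,
#'   `degenerate`).
#' @export
score_distribution_table <- function(scores, outcomes) {
  if (any(scores$score != round(scores$score))) {
    stop("score_distribution_table expects integer allele counts",
         call. = FALSE)
  }
  d <- dplyr::inner_join(scores[, c("subject_id", "score")],
                         outcomes, by = "subject_id")
  d <- d[stats::complete.cases(d), ]
  out <- dplyr::summarise(
    dplyr::group_by(d, .data$score),
    n = dplyr::n(),
    mean_outcome = mean(.data$outcome),
    sd = stats::sd(.data$outcome),
    .groups = "drop"
  )
  se <- out$sd / sqrt(out$n)
  dplyr::mutate(out,
                ci_low = .data$mean_outcome - 1.96 * se,
                ci_high = .data$mean_outcome + 1.96 * se,
                degenerate = .data$n < 2,
                sd = NULL)
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage end to end: standardization of weight,
#' length/height and derived BMI to SDS; allele-score construction with
#' complete-case exclusions; the score-distribution summary; cross-sectional
#' associations at the analysis age (SDS outcomes plus fat and fat-free mass
#' indices); per-age coefficient profiles; random-intercept longitudinal and
#' piecewise fits with polynomial interaction checks; conditional infancy
#' weight gain with failure-to-thrive, overweight and obesity logistic
#' models; and variance explained. All randomness flows from the config
#' seed; identical config and seed give identical outputs. When
#' `config$outdir` is set the report tables are also written as CSV plus a
#' text summary.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result` with elements
#'   `score_distribution`, `cross_sectional`, `per_age_profile`,
#'   `longitudinal`, `piecewise`, `polynomial`, `gain_association`, `odds`,
#'   `variance_explained`, `conditional_gain`, `run_log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  panel <- resolve_panel(config$panel)
  ref <- resolve_input(config$reference, read_lms_reference)
  if (!is.null(ref) && !inherits(ref, "lms_reference")) ref <- lms_reference(ref)
  if (is.null(ref)) ref <- simulate_reference()
  cutoffs <- resolve_input(config$cutoffs, read_cutoff_curves)
  if (!is.null(cutoffs) && !inherits(cutoffs, "cutoff_curves")) {
    cutoffs <- cutoff_curves(cutoffs)
  }
  if (is.null(cutoffs)) cutoffs <- simulate_cutoff_curves()

  measurements <- resolve_input(config$measurements, read_measurements)
  genotypes <- resolve_input(config$genotypes, read_genotypes)
  body_comp <- resolve_input(config$body_composition, read_body_composition)
  if (is.null(measurements)) {
    sim <- config$sim
    if (is.null(sim)) sim <- sim_config(seed = config$seed, panel = panel)
    cohort <- simulate_cohort(sim, ref)
    measurements <- cohort$measurements
    genotypes <- cohort$genotypes
    body_comp <- cohort$body_composition
  }
  if (is.null(genotypes)) stop("Genotypes are required", call. = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("Pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- standardization -------------------------------------------------
  sds_table <- stage("standardize", {
    with_bmi <- dplyr::bind_rows(measurements, derive_bmi(measurements))
    standardize_cohort(with_bmi, ref)
  })
  n_std_excluded <- nrow(attr(sds_table, "excluded"))

  # --- allele score ----------------------------------------------------
  scores <- stage("score", risk_allele_score(genotypes, panel,
                                             require_complete = TRUE))
  n_geno_excluded <- length(attr(scores, "excluded"))

  xs_age <- config$cross_sectional_age
  tol <- config$age_tol
  at_age <- function(ms) {
    in_window <- if ("visit_age" %in% names(sds_table)) {
      abs(sds_table$visit_age - xs_age) <= 1e-9
    } else {
      abs(sds_table$age_years - xs_age) <= tol
    }
    s <- sds_table[sds_table$measure == ms & in_window, ]
    dplyr::inner_join(s, scores[, c("subject_id", "score")], by = "subject_id")
  }

  # --- score distribution (per-score mean BMI SDS at analysis age) -----
  score_distribution <- stage("score_distribution", {
    b <- at_age("bmi")
    score_distribution_table(scores,
                             tibble::tibble(subject_id = b$subject_id,
                                            outcome = b$sds))
  })

  # --- cross-sectional associations (per-allele effects) ---------------
  cross_sectional <- stage("cross_sectional", {
    sds_rows <- lapply(c(bmi = "bmi", weight = "weight",
                         height = "length_height"), function(ms) {
      d <- at_age(ms)
      linear_assoc(d, "sds", covariates =
                     intersect(config$covariates$sds, names(d)),
                   label = paste0(ms, "_sds"))
    })
    body_rows <- list()
    if (!is.null(body_comp) && nrow(body_comp) > 0) {
      bc <- dplyr::inner_join(body_comp, scores[, c("subject_id", "score")],
                              by = "subject_id")
      bc$fmi <- mass_index(bc$fat_mass_kg, bc$height_m)
      bc$ffmi <- mass_index(bc$fat_free_mass_kg, bc$height_m)
      covs <- intersect(config$covariates$body_comp, names(bc))
      body_rows <- list(
        linear_assoc(bc, "fmi", covariates = covs, label = "fat_mass_index"),
        linear_assoc(bc, "ffmi", covariates = covs,
                     label = "fat_free_mass_index"))
    }
    dplyr::bind_rows(c(sds_rows, body_rows))
  })

  # --- per-age coefficient profiles ------------------------------------
  visit_ages <- if ("visit_age" %in% names(measurements)) {
    sort(unique(measurements$visit_age))
  } else {
    sort(unique(round(measurements$age_years * 4) / 4))
  }
  profile <- stage("per_age_profile",
                   per_age_profile(sds_table, scores, visit_ages,
                                   covariates = config$covariates$sds,
                                   age_tol = tol))

  # --- longitudinal weight-SDS models ----------------------------------
  long_obs <- stage("longitudinal_data", {
    w <- sds_table[sds_table$measure == "weight", ]
    d <- dplyr::inner_join(w, scores[, c("subject_id", "score")],
                           by = "subject_id")
    tibble::tibble(subject_id = d$subject_id, age_years = d$age_years,
                   outcome_sds = d$sds, score = d$score, sex = d$sex)
  })
  longitudinal <- stage("longitudinal", fit_random_intercepts(long_obs))
  piecewise <- stage("piecewise", piecewise_slopes(long_obs))
  polynomial <- stage("polynomial", polynomial_interaction_test(long_obs))

  # --- conditional gain, failure to thrive, overweight/obesity ---------
  gain <- stage("conditional_gain",
                conditional_gain_pipeline(sds_table,
                                          baseline_age = config$baseline_age,
                                          followup_age = config$followup_age))
  gain_assoc <- stage("gain_association", {
    subj <- unique(sds_table[, c("subject_id", "sex")])
    g <- dplyr::inner_join(gain, scores[, c("subject_id", "score")],
                           by = "subject_id")
    g <- dplyr::inner_join(g, subj, by = "subject_id")
    linear_assoc(g, "sds_gain",
                 covariates = intersect(config$covariates$binary, names(g)),
                 label = "conditional_weight_gain")
  })

  # overweight/obesity classification uses raw BMI values at the analysis age
  odds <- stage("odds", {
    subj <- unique(sds_table[, c("subject_id", "sex")])
    g <- dplyr::inner_join(gain, scores[, c("subject_id", "score")],
                           by = "subject_id")
    g <- dplyr::inner_join(g, subj, by = "subject_id")
    covs_g <- intersect(config$covariates$binary, names(g))
    ftt_row <- logistic_assoc(g, "ftt_flag", covariates = covs_g,
                              label = "failure_to_thrive")
    bmi_rows <- dplyr::inner_join(
      derive_bmi(measurements), scores[, c("subject_id", "score")],
      by = "subject_id")
    bmi_rows <- bmi_rows[abs(bmi_rows$age_years - xs_age) <= tol, ]
    cls <- iotf_classify(bmi_rows$value, bmi_rows$age_years, bmi_rows$sex,
                         cutoffs)
    bmi_rows$overweight_or_obese <- cls >= "overweight"
    bmi_rows$obese <- cls >= "obese"
    covs_b <- intersect(config$covariates$binary, names(bmi_rows))
    dplyr::bind_rows(
      ftt_row,
      logistic_assoc(bmi_rows, "overweight_or_obese", covariates = covs_b,
                     label = "overweight_or_obese"),
      logistic_assoc(bmi_rows, "obese", covariates = covs_b, label = "obese"))
  })

  # --- variance explained ----------------------------------------------
  varexp <- stage("variance_explained", {
    rows <- lapply(c(bmi = "bmi", weight = "weight"), function(ms) {
      d <- at_age(ms)
      tibble::tibble(
        outcome = paste0(ms, "_sds"),
        n = sum(stats::complete.cases(d[, c("sds", "score")])),
        delta_r2 = variance_explained(
          d, "sds", covariates = intersect(config$covariates$sds, names(d))))
    })
    dplyr::bind_rows(rows)
  })

  run_log <- tibble::tibble(
    key = c("seed", "config_hash", "n_genotyped",
            "n_score_complete", "n_excluded_incomplete_genotype",
            "n_measurement_rows", "n_sds_rows", "n_std_excluded",
            "panel_size", "r_birth_6wk"),
    value = as.character(c(config$seed,
                           rlang::hash(unclass(config)[setdiff(
                             names(config), "outdir")]),
                           nrow(genotypes), nrow(scores), n_geno_excluded,
                           nrow(measurements), nrow(sds_table),
                           n_std_excluded, nrow(panel),
                           signif(attr(gain, "r"), 8)))
  )

  result <- structure(list(
    score_distribution = score_distribution,
    cross_sectional = cross_sectional,
    per_age_profile = profile,
    longitudinal = longitudinal,
    piecewise = piecewise,
    polynomial = polynomial,
    gain_association = gain_assoc,
    odds = odds,
    variance_explained = varexp,
    conditional_gain = gain,
    run_log = run_log
  ), class = "pipeline_result")

  if (!is.null(config$outdir)) write_pipeline_report(result, config$outdir)
  result
}

#' Write pipeline report tables
#'
#' Writes each result table as tidy CSV plus a human-readable `summary.txt`.
#'
#' @param result A [run_pipeline()] result.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_pipeline_report <- function(result, outdir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  mixed_tbl <- function(fit, model) {
    dplyr::mutate(fit$fixed, model = model, sigma_u = fit$sigma_u,
                  sigma_e = fit$sigma_e, log_lik = fit$logLik,
                  n_obs = fit$n_obs, n_subjects = fit$n_subjects,
                  .before = "term")
  }
  long_tbl <- dplyr::bind_rows(
    mixed_tbl(result$longitudinal, "birth_to_11y"),
    mixed_tbl(result$piecewise$early, "birth_to_6wk"),
    mixed_tbl(result$piecewise$late, "6wk_to_11y"))
  tables <- list(
    score_distribution = result$score_distribution,
    cross_sectional = result$cross_sectional,
    per_age_profile = result$per_age_profile,
    longitudinal = long_tbl,
    polynomial = result$polynomial,
    gain_association = result$gain_association,
    odds = result$odds,
    variance_explained = result$variance_explained,
    conditional_gain = result$conditional_gain,
    run_log = result$run_log
  )
  paths <- character()
  for (nm in names(tables)) {
    p <- file.path(outdir, paste0(nm, ".csv"))
    readr::write_csv(tables[[nm]], p)
    paths <- c(paths, p)
  }
  sm <- file.path(outdir, "summary.txt")
  lines <- c(
    "Pipeline report",
    paste0(utils::capture.output(print(as.data.frame(result$run_log),
                                       row.names = FALSE)), collapse = "\n"),
    "",
    "Cross-sectional per-allele effects:",
    paste0(utils::capture.output(
      print(as.data.frame(result$cross_sectional), digits = 3,
            row.names = FALSE)), collapse = "\n"),
    "",
    "Piecewise score-by-age slopes (SDS/allele/y):",
    paste0(utils::capture.output(
      print(as.data.frame(result$piecewise$slopes), digits = 3,
            row.names = FALSE)), collapse = "\n")
  )
  writeLines(lines, sm)
  invisible(c(paths, sm))
}
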