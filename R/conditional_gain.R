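# Conditional infancy weight gain and failure-to-thrive flagging.
#
# Raw change in weight SDS from birth regresses to the mean: lighter-born
# infants tend to show larger SDS gains for purely statistical reasons.
# Conditional weight gain removes this by measuring the follow-up SDS
# relative to its expectation given the birth SDS:
#   gain = (SDS_followup - r * SDS_baseline) / sqrt(1 - r^2)
# where r is the population correlation between the two. When both columns
# are standardized to unit variance, the gain has unit variance and is
# uncorrelated with the baseline by construction.

#' Baseline-follow-up correlation for conditional gain
#'
#' Pearson correlation between weight SDS at baseline (birth) and follow-up
#' (6 weeks), estimated within the analysis sample itself on complete pairs.
#'
#' @param pairs Data frame with columns `sds_baseline`, `sds_followup`
#'   (complete pairs only).
#' @return The correlation r in (-1, 1) (boundary values are returned but
#'   rejected by [conditional_gain()]).
#' @export
estimate_r <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("sds_baseline", "sds_followup") %in% names(pairs)))
  b <- pairs$sds_baseline; f <- pairs$sds_followup
  if (anyNA(b) || anyNA(f)) {
    stop("estimate_r requires complete pairs (no missing SDS)", call. = FALSE)
  }
  if (length(b) < 3) stop("Need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(b) == 0 || stats::sd(f) == 0) {
    stop("Degenerate input: zero variance in baseline or follow-up SDS",
         call. = FALSE)
  }
  stats::cor(b, f)
}

#' Conditional weight gain from birth
#'
#' `(sds_followup - r * sds_baseline) / sqrt(1 - r^2)`. Positive values mean
#' faster-than-expected gain given the birth weight; the scaling restores
#' unit variance when the inputs have unit variance and correlation r.
#'
#' @param pairs Data frame with columns `subject_id` (optional),
#'   `sds_baseline`, `sds_followup`.
#' @param r Baseline-follow-up correlation, `|r| < 1`; defaults to
#'   [estimate_r()] on `pairs`.
#' @return Tibble (`subject_id`, `sds_gain`).
#' @export
conditional_gain <- function(pairs, r = estimate_r(pairs)) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("sds_baseline", "sds_followup") %in% names(pairs)))
  if (!is.finite(r) || abs(r) >= 1) {
    stop("Conditional gain requires |r| < 1", call. = FALSE)
  }
  gain <- (pairs$sds_followup - r * pairs$sds_baseline) / sqrt(1 - r^2)
  tibble::tibble(
    subject_id = if ("subject_id" %in% names(pairs)) pairs$subject_id
                 else seq_len(nrow(pairs)),
    sds_gain = gain
  )
}

#' Flag failure to thrive
#'
#' Failure to thrive is defined as membership in the slowest 5% of
#' conditional weight gain within the population. The threshold is the
#' empirical quantile with linear interpolation between order statistics;
#' ties at the threshold are all flagged (conservative toward flagging).
#'
#' @param gains Numeric vector of conditional gains (>= 20 values; the
#'   percentile is unstable below that).
#' @param quantile Flagging quantile, default 0.05.
#' @return Logical vector, `TRUE` for flagged subjects.
#' @export
flag_failure_to_thrive <- function(gains, quantile = 0.05) {
  if (anyNA(gains)) stop("Gains must not contain missing values", call. = FALSE)
  if (length(gains) < 20) {
    stop("Refusing to flag failure to thrive on fewer than 20 gains",
         call. = FALSE)
  }
  stopifnot(quantile > 0, quantile < 1)
  threshold <- stats::quantile(gains, probs = quantile, type = 7, names = FALSE)
  flag <- gains <= threshold
  if (all(flag)) {
    warning("All gains at or below the flagging threshold (degenerate ties); ",
            "all subjects flagged", call. = FALSE)
  }
  flag
}

#' Conditional gain and failure-to-thrive in one step
#'
#' Builds complete baseline/follow-up pairs from an SDS table, estimates r
#' within the sample, computes conditional gains and flags the slowest 5%.
#'
#' @param sds_table Output of [standardize_cohort()] restricted to weight.
#' @param baseline_age,followup_age Ages (decimal years) identifying the two
#'   measurements. If the table carries a nominal `visit_age` column it is
#'   matched exactly; otherwise the precise `age_years` is matched within
#'   `age_tol`.
#' @param age_tol Age-matching tolerance in years (precise-age matching only).
#' @return Tibble (`subject_id`, `sds_baseline`, `sds_followup`, `sds_gain`,
#'   `ftt_flag`) with attribute `r`.
#' @export
conditional_gain_pipeline <- function(sds_table, baseline_age = 0,
                                      followup_age = 42 / 365.25,
                                      age_tol = 0.2) {
  s <- tibble::as_tibble(sds_table)
  s <- s[s$measure == "weight", ]
  match_age <- if ("visit_age" %in% names(s)) {
    function(target) abs(s$visit_age - target) <= 1e-9
  } else {
    function(target) abs(s$age_years - target) <= age_tol
  }
  base <- s[match_age(baseline_age), c("subject_id", "sds")]
  fol <- s[match_age(followup_age), c("subject_id", "sds")]
  base <- base[!duplicated(base$subject_id), ]
  fol <- fol[!duplicated(fol$subject_id), ]
  names(base)[2] <- "sds_baseline"
  names(fol)[2] <- "sds_followup"
  pairs <- dplyr::inner_join(base, fol, by = "subject_id")
  r <- estimate_r(pairs)
  out <- conditional_gain(pairs, r)
  out <- dplyr::mutate(pairs, sds_gain = out$sds_gain,
                       ftt_flag = flag_failure_to_thrive(out$sds_gain))
  attr(out, "r") <- r
  out
}
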