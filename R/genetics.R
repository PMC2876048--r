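# Genotype QC and obesity-risk-allele scores.
#
# Genotypes are stored pre-oriented to the risk allele: each variant column
# holds the risk-allele dosage 0/1/2 (NA = missing call). The unweighted
# score counts risk alleles across a fixed panel; the weighted variant
# multiplies each dosage by a per-variant effect weight.

#' Default eight-variant obesity-risk panel
#'
#' The eight GWAS-established adult-obesity variants used for the primary
#' risk-allele score (in/near FTO, MC4R, TMEM18, GNPDA2, KCTD15, NEGR1,
#' BDNF, ETV5), optionally extended to ten with SH2B1 and MTCH2. Risk-allele
#' frequencies are simulation parameters drawn from the source GWAS
#' literature (they are cohort inputs, not estimated here); weights default
#' to 1 so the weighted score reduces to the allele count.
#'
#' @param n_variants 8 (primary panel) or 10 (extended panel).
#' @return A tibble with columns `rsid`, `locus_label`, `risk_allele`,
#'   `other_allele`, `risk_allele_freq`, `weight`.
#' @export
default_panel <- function(n_variants = 8) {
  stopifnot(n_variants %in% c(8, 10))
  panel <- tibble::tibble(
    rsid = c("rs9939609", "rs17782313", "rs6548238", "rs10938397",
             "rs368794", "rs2568958", "rs925946", "rs7647305",
             "rs7498665", "rs10838738"),
    locus_label = c("FTO", "MC4R", "TMEM18", "GNPDA2", "KCTD15", "NEGR1",
                    "BDNF", "ETV5", "SH2B1", "MTCH2"),
    risk_allele = c("A", "C", "C", "G", "T", "A", "T", "C", "G", "G"),
    other_allele = c("T", "T", "T", "A", "C", "G", "G", "T", "A", "A"),
    risk_allele_freq = c(0.40, 0.24, 0.83, 0.43, 0.66, 0.62, 0.30, 0.79,
                         0.38, 0.34),
    weight = 1
  )
  validate_panel(panel[seq_len(n_variants), ])
}

#' Validate a variant panel definition
#'
#' @param panel Data frame with columns `rsid`, `risk_allele`, `other_allele`,
#'   `risk_allele_freq` and optionally `locus_label`, `weight`.
#' @return The panel as a tibble, after invariant checks.
#' @export
validate_panel <- function(panel) {
  panel <- tibble::as_tibble(panel)
  required <- c("rsid", "risk_allele", "other_allele", "risk_allele_freq")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols) > 0) {
    stop("Panel is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(panel) == 0) stop("Panel is empty", call. = FALSE)
  if (anyDuplicated(panel$rsid)) stop("Duplicate rsids in panel", call. = FALSE)
  if (any(panel$risk_allele == panel$other_allele)) {
    stop("risk_allele must differ from other_allele", call. = FALSE)
  }
  if (any(panel$risk_allele_freq <= 0 | panel$risk_allele_freq >= 1)) {
    stop("risk_allele_freq must lie strictly in (0, 1)", call. = FALSE)
  }
  panel
}

check_genotypes <- function(geno, rsids) {
  geno <- tibble::as_tibble(geno)
  if (!"subject_id" %in% names(geno)) {
    stop("Genotype table needs a subject_id column", call. = FALSE)
  }
  absent <- setdiff(rsids, names(geno))
  if (length(absent) > 0) {
    stop("Panel rsid(s) absent from genotype table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  dos <- as.matrix(geno[, rsids, drop = FALSE])
  ok <- is.na(dos) | dos %in% c(0, 1, 2)
  if (!all(ok)) {
    stop("Dosages must be 0, 1, 2 or missing; offending entries: ",
         sum(!ok), call. = FALSE)
  }
  geno
}

#' Unweighted obesity-risk-allele score
#'
#' Counts risk alleles across the panel for each subject. With
#' `require_complete = TRUE` (the primary analysis rule) subjects missing a
#' genotype at any panel variant are excluded and the exclusion count is
#' messaged; the excluded ids are available in the `excluded` attribute.
#'
#' @param geno Genotype table: `subject_id` plus one risk-allele dosage
#'   column (0/1/2, NA missing) per rsid.
#' @param panel Variant panel ([default_panel()] format).
#' @param require_complete Drop subjects with any missing panel genotype.
#' @return Tibble (`subject_id`, `n_variants_used`, `score`).
#' @export
risk_allele_score <- function(geno, panel, require_complete = TRUE) {
  panel <- validate_panel(panel)
  geno <- check_genotypes(geno, panel$rsid)
  dos <- as.matrix(geno[, panel$rsid, drop = FALSE])
  n_used <- rowSums(!is.na(dos))
  score <- rowSums(dos, na.rm = TRUE)
  out <- tibble::tibble(subject_id = geno$subject_id,
                        n_variants_used = as.integer(n_used),
                        score = score)
  if (require_complete) {
    incomplete <- out$n_variants_used < nrow(panel)
    if (any(incomplete)) {
      message(sum(incomplete),
              " subject(s) excluded for incomplete panel genotypes")
    }
    excluded_ids <- out$subject_id[incomplete]
    out <- out[!incomplete, ]
    attr(out, "excluded") <- excluded_ids
  }
  out
}

#' Weighted obesity-risk-allele score
#'
#' Sum of per-variant `weight * dosage`, where weights reflect each variant's
#' apparent effect size on adult BMI. With all weights equal to 1 this is the
#' unweighted allele count. Complete genotype data are required per subject.
#'
#' @inheritParams risk_allele_score
#' @return Tibble (`subject_id`, `n_variants_used`, `score`).
#' @export
weighted_score <- function(geno, panel, require_complete = TRUE) {
  panel <- validate_panel(panel)
  if (!"weight" %in% names(panel) || any(is.na(panel$weight))) {
    stop("Every panel variant needs a weight for the weighted score",
         call. = FALSE)
  }
  if (any(panel$weight < 0)) stop("Weights must be >= 0", call. = FALSE)
  geno <- check_genotypes(geno, panel$rsid)
  dos <- as.matrix(geno[, panel$rsid, drop = FALSE])
  n_used <- rowSums(!is.na(dos))
  dos0 <- dos; dos0[is.na(dos0)] <- 0
  score <- drop(dos0 %*% panel$weight)
  out <- tibble::tibble(subject_id = geno$subject_id,
                        n_variants_used = as.integer(n_used),
                        score = score)
  if (require_complete) {
    incomplete <- out$n_variants_used < nrow(panel)
    if (any(incomplete)) {
      message(sum(incomplete),
              " subject(s) excluded for incomplete panel genotypes")
    }
    excluded_ids <- out$subject_id[incomplete]
    out <- out[!incomplete, ]
    attr(out, "excluded") <- excluded_ids
  }
  out
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom chi-square goodness-of-fit test of observed genotype
#' counts against the Hardy-Weinberg expectations p^2 / 2pq / q^2 computed
#' from the sample allele frequency. No continuity correction. A monomorphic
#' sample (allele frequency 0 or 1) is in trivial equilibrium: p-value 1 by
#' convention, with a message.
#'
#' @param n_rr Count of risk-allele homozygotes.
#' @param n_rh Count of heterozygotes.
#' @param n_hh Count of other-allele homozygotes.
#' @return List with `chisq`, `df`, `p_value` and the sample risk-allele
#'   frequency `freq`.
#' @export
hwe_test <- function(n_rr, n_rh, n_hh) {
  counts <- c(n_rr, n_rh, n_hh)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("Genotype counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0) stop("Total genotype count must be positive", call. = FALSE)
  p <- (2 * n_rr + n_rh) / (2 * n)
  if (p == 0 || p == 1) {
    message("Monomorphic sample: HWE p-value set to 1 by convention")
    return(list(chisq = 0, df = 1L, p_value = 1, freq = p))
  }
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chisq <- sum((counts - expected)^2 / expected)
  list(chisq = chisq, df = 1L,
       p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       freq = p)
}

#' Genotyping call rate of one variant
#'
#' @param geno Genotype table (see [risk_allele_score()]).
#' @param rsid Variant column name.
#' @return Fraction of subjects with a non-missing call, in `[0, 1]`.
#' @export
call_rate <- function(geno, rsid) {
  geno <- check_genotypes(geno, rsid)
  mean(!is.na(geno[[rsid]]))
}

#' Genotype counts for one variant
#'
#' Tallies risk-allele dosage classes (2 / 1 / 0) for use with [hwe_test()].
#'
#' @inheritParams call_rate
#' @return Named list `n_rr`, `n_rh`, `n_hh` (missing calls omitted).
#' @export
genotype_counts <- function(geno, rsid) {
  geno <- check_genotypes(geno, rsid)
  d <- geno[[rsid]]
  list(n_rr = sum(d == 2, na.rm = TRUE),
       n_rh = sum(d == 1, na.rm = TRUE),
       n_hh = sum(d == 0, na.rm = TRUE))
}
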