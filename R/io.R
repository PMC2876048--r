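# CSV readers/writers for the pipeline's external interfaces.

#' Read an LMS reference table from CSV
#'
#' Expects columns `sex, measure, age_years, L, M, S`.
#'
#' @param path CSV file path.
#' @return An [lms_reference()].
#' @export
read_lms_reference <- function(path) {
  lms_reference(readr::read_csv(path, show_col_types = FALSE))
}

#' Read long-format measurements from CSV
#'
#' Expects columns `subject_id, sex, age_years, measure, value`; extra
#' columns (e.g. nominal `visit_age`, gestational age) are carried through.
#'
#' @param path CSV file path.
#' @return Tibble of measurements.
#' @export
read_measurements <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("subject_id", "sex", "age_years", "measure", "value")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols) > 0) {
    stop("Measurement CSV missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  m
}

#' Read a genotype dosage table from CSV
#'
#' Expects `subject_id` plus one risk-allele dosage column per rsid; blank
#' cells are missing calls.
#'
#' @param path CSV file path.
#' @return Tibble of dosages.
#' @export
read_genotypes <- function(path) {
  g <- readr::read_csv(path, show_col_types = FALSE)
  if (!"subject_id" %in% names(g)) {
    stop("Genotype CSV needs a subject_id column", call. = FALSE)
  }
  g
}

#' Read a variant panel from CSV
#'
#' @param path CSV with [default_panel()] columns.
#' @return Validated panel tibble.
#' @export
read_panel <- function(path) {
  validate_panel(readr::read_csv(path, show_col_types = FALSE))
}

#' Read BMI cutoff curves from CSV
#'
#' @param path CSV with [cutoff_curves()] columns.
#' @return A `cutoff_curves` table.
#' @export
read_cutoff_curves <- function(path) {
  cutoff_curves(readr::read_csv(path, show_col_types = FALSE))
}

#' Read a body-composition table from CSV
#'
#' Expects columns `subject_id, sex, age_years, fat_mass_kg,
#' fat_free_mass_kg, height_m`.
#'
#' @param path CSV file path.
#' @return Tibble.
#' @export
read_body_composition <- function(path) {
  b <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("subject_id", "fat_mass_kg", "fat_free_mass_kg", "height_m")
  missing_cols <- setdiff(required, names(b))
  if (length(missing_cols) > 0) {
    stop("Body-composition CSV missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(b$height_m <= 0, na.rm = TRUE) ||
      any(b$fat_mass_kg < 0, na.rm = TRUE) ||
      any(b$fat_free_mass_kg < 0, na.rm = TRUE)) {
    stop("Body composition requires non-negative masses and positive height",
         call. = FALSE)
  }
  b
}

#' Read genotypes from a minimal VCF
#'
#' Maps GT fields to risk-allele dosages using the panel's allele
#' definitions. The variant's REF/ALT pair must match the panel's
#' risk/other alleles (in either orientation); a mismatch is an explicit
#' error, never a silent strand flip.
#'
#' @param path VCF file path (uncompressed, with GT in FORMAT).
#' @param panel Variant panel with `rsid`, `risk_allele`, `other_allele`.
#' @return Tibble: `subject_id` plus one dosage column per panel rsid.
#' @export
read_genotypes_vcf <- function(path, panel) {
  panel <- validate_panel(panel)
  lines <- readLines(path)
  header <- lines[startsWith(lines, "#CHROM")]
  if (length(header) != 1) stop("Malformed VCF: no #CHROM header", call. = FALSE)
  cols <- strsplit(sub("^#", "", header), "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  out <- matrix(NA_integer_, length(samples), nrow(panel),
                dimnames = list(NULL, panel$rsid))
  for (ln in body) {
    f <- strsplit(ln, "\t")[[1]]
    rsid <- f[3]
    idx <- match(rsid, panel$rsid)
    if (is.na(idx)) next
    ref <- f[4]; alt <- f[5]
    risk <- panel$risk_allele[idx]; other <- panel$other_allele[idx]
    if (ref == other && alt == risk) {
      risk_is_alt <- TRUE
    } else if (ref == risk && alt == other) {
      risk_is_alt <- FALSE
    } else {
      stop("Allele mismatch for ", rsid, ": VCF ", ref, "/", alt,
           " vs panel ", risk, "/", other, call. = FALSE)
    }
    fmt <- strsplit(f[9], ":")[[1]]
    gt_i <- match("GT", fmt)
    if (is.na(gt_i)) stop("No GT field for ", rsid, call. = FALSE)
    gts <- vapply(strsplit(f[-(1:9)], ":"), `[`, character(1), gt_i)
    alleles <- strsplit(gsub("\\|", "/", gts), "/")
    dose <- vapply(alleles, function(a) {
      if (any(a == ".")) return(NA_integer_)
      n_alt <- sum(a == "1")
      as.integer(if (risk_is_alt) n_alt else length(a) - n_alt)
    }, integer(1))
    out[, idx] <- dose
  }
  res <- tibble::as_tibble(out)
  dplyr::mutate(res, subject_id = samples, .before = 1)
}

#' Write a synthetic cohort to CSV files
#'
#' Writes the measurement, genotype, panel, reference, cutoff-curve and
#' body-composition tables in the dialects the readers consume.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param ref Reference used to generate the cohort.
#' @param cutoffs Cutoff curves to write alongside.
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort_csv <- function(cohort, dir, ref = simulate_reference(),
                             cutoffs = simulate_cutoff_curves()) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    measurements = file.path(dir, "measurements.csv"),
    genotypes = file.path(dir, "genotypes.csv"),
    panel = file.path(dir, "panel.csv"),
    reference = file.path(dir, "lms_reference.csv"),
    cutoffs = file.path(dir, "cutoff_curves.csv"),
    body_composition = file.path(dir, "body_composition.csv")
  )
  readr::write_csv(cohort$measurements, paths["measurements"])
  readr::write_csv(cohort$genotypes, paths["genotypes"])
  readr::write_csv(cohort$config$panel, paths["panel"])
  readr::write_csv(tibble::as_tibble(ref), paths["reference"])
  readr::write_csv(tibble::as_tibble(cutoffs), paths["cutoffs"])
  readr::write_csv(cohort$body_composition, paths["body_composition"])
  invisible(paths)
}
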