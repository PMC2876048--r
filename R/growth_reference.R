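# LMS growth-reference standardization.
#
# A reference distribution for a growth measure at a given age and sex is
# summarised by three age-varying parameters: L (Box-Cox skewness power),
# M (median, in measure units) and S (coefficient of variation). A raw value
# x maps to a standard deviation score (SDS) via
#   z = ((x/M)^L - 1) / (L * S)   for L != 0
#   z = log(x/M) / S              for L == 0.

#' Construct and validate an LMS reference table
#'
#' An LMS reference tabulates, per sex and measure, the L (skewness), M
#' (median) and S (coefficient of variation) parameters on an ascending age
#' grid. Raw measurements are converted to age- and sex-standardized SD
#' scores by interpolating L, M and S at the exact age of measurement.
#'
#' @param x A data frame with columns `sex` (`"male"`/`"female"`), `measure`
#'   (`"weight"`, `"length_height"` or `"bmi"`), `age_years`, `L`, `M`, `S`.
#' @return A validated tibble of class `lms_reference`.
#' @examples
#' ref <- lms_reference(data.frame(
#'   sex = "female", measure = "weight", age_years = c(0, 1),
#'   L = -0.2, M = c(3.4, 9.0), S = 0.12
#' ))
#' @export
lms_reference <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("sex", "measure", "age_years", "L", "M", "S")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("LMS reference is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad_sex <- setdiff(unique(x$sex), c("male", "female"))
  if (length(bad_sex) > 0) {
    stop("Unknown sex codes in LMS reference: ", paste(bad_sex, collapse = ", "),
         call. = FALSE)
  }
  bad_measure <- setdiff(unique(x$measure), c("weight", "length_height", "bmi"))
  if (length(bad_measure) > 0) {
    stop("Unknown measure codes in LMS reference: ",
         paste(bad_measure, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(x$age_years)) || any(!is.finite(x$L)) ||
      any(!is.finite(x$M)) || any(!is.finite(x$S))) {
    stop("LMS reference contains non-finite values", call. = FALSE)
  }
  if (any(x$M <= 0)) stop("LMS reference requires M > 0 everywhere", call. = FALSE)
  if (any(x$S <= 0)) stop("LMS reference requires S > 0 everywhere", call. = FALSE)
  x <- dplyr::arrange(x, .data$sex, .data$measure, .data$age_years)
  grp <- dplyr::group_by(x, .data$sex, .data$measure)
  chk <- dplyr::summarise(grp,
    n = dplyr::n(),
    strict = all(diff(.data$age_years) > 0),
    .groups = "drop"
  )
  if (any(chk$n < 2)) {
    stop("Each sex x measure needs at least 2 age grid points", call. = FALSE)
  }
  if (!all(chk$strict)) {
    stop("age_years must be strictly increasing within each sex x measure",
         call. = FALSE)
  }
  class(x) <- c("lms_reference", class(x))
  x
}

#' Interpolate LMS parameters at an exact age
#'
#' The reference is tabulated at discrete ages; measurements are taken at
#' precise ages. L, M and S are each interpolated linearly in age. No
#' extrapolation is performed: ages outside the grid are an error.
#'
#' @param ref An [lms_reference()] table.
#' @param sex `"male"` or `"female"` (scalar or vector).
#' @param measure `"weight"`, `"length_height"` or `"bmi"` (scalar or vector).
#' @param age_years Ages in decimal years (vectorized).
#' @return A tibble with columns `L`, `M`, `S`, one row per input age.
#' @export
interpolate_lms <- function(ref, sex, measure, age_years) {
  stopifnot(inherits(ref, "lms_reference"))
  n <- max(length(sex), length(measure), length(age_years))
  sex <- rep_len(sex, n)
  measure <- rep_len(measure, n)
  age_years <- rep_len(age_years, n)
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("L", "M", "S")))
  key <- paste(sex, measure, sep = "\r")
  for (k in unique(key)) {
    idx <- which(key == k)
    sx <- sex[idx[1]]; ms <- measure[idx[1]]
    tab <- ref[ref$sex == sx & ref$measure == ms, ]
    if (nrow(tab) == 0) {
      stop("No reference rows for sex='", sx, "', measure='", ms, "'",
           call. = FALSE)
    }
    ages <- age_years[idx]
    lo <- min(tab$age_years); hi <- max(tab$age_years)
    if (any(ages < lo | ages > hi)) {
      bad <- ages[ages < lo | ages > hi]
      stop("Age(s) outside reference grid [", lo, ", ", hi, "] for ",
           sx, "/", ms, ": ", paste(utils::head(signif(bad, 4), 5), collapse = ", "),
           call. = FALSE)
    }
    out[idx, "L"] <- stats::approx(tab$age_years, tab$L, ages, rule = 1)$y
    out[idx, "M"] <- stats::approx(tab$age_years, tab$M, ages, rule = 1)$y
    out[idx, "S"] <- stats::approx(tab$age_years, tab$S, ages, rule = 1)$y
  }
  tibble::as_tibble(out)
}

#' Convert a raw measurement to an SD score
#'
#' Applies the LMS (Box-Cox) transform `z = ((x/M)^L - 1)/(L*S)`, with the
#' logarithmic branch `z = log(x/M)/S` when `|L| < 1e-12`. The transform is
#' continuous in L at L = 0.
#'
#' @param value Raw measurement(s), strictly positive, in measure units.
#' @param L,M,S LMS parameters (vectorized; `M > 0`, `S > 0`).
#' @return SD score(s), unitless.
#' @export
lms_to_sds <- function(value, L, M, S) {
  if (any(!is.finite(value)) || any(value <= 0)) {
    stop("lms_to_sds requires strictly positive finite values", call. = FALSE)
  }
  if (any(M <= 0) || any(S <= 0)) {
    stop("lms_to_sds requires M > 0 and S > 0", call. = FALSE)
  }
  n <- max(length(value), length(L), length(M), length(S))
  value <- rep_len(value, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  z <- numeric(n)
  log_branch <- abs(L) < 1e-12
  z[log_branch] <- log(value[log_branch] / M[log_branch]) / S[log_branch]
  i <- !log_branch
  z[i] <- ((value[i] / M[i])^L[i] - 1) / (L[i] * S[i])
  z
}

#' Convert an SD score back to a raw measurement
#'
#' Inverse of [lms_to_sds()]: `x = M * (1 + L*S*z)^(1/L)` for L != 0, and
#' `x = M * exp(S*z)` for L = 0. Needed by the synthetic-data back-transform.
#' The inverse is undefined when `1 + L*S*z <= 0`.
#'
#' @param sds SD score(s).
#' @inheritParams lms_to_sds
#' @return Raw value(s) in measure units.
#' @export
lms_from_sds <- function(sds, L, M, S) {
  if (any(M <= 0) || any(S <= 0)) {
    stop("lms_from_sds requires M > 0 and S > 0", call. = FALSE)
  }
  n <- max(length(sds), length(L), length(M), length(S))
  sds <- rep_len(sds, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  x <- numeric(n)
  log_branch <- abs(L) < 1e-12
  x[log_branch] <- M[log_branch] * exp(S[log_branch] * sds[log_branch])
  i <- !log_branch
  base <- 1 + L[i] * S[i] * sds[i]
  if (any(base <= 0)) {
    stop("lms_from_sds: inverse undefined (1 + L*S*z <= 0) for ",
         sum(base <= 0), " value(s)", call. = FALSE)
  }
  x[i] <- M[i] * base^(1 / L[i])
  x
}

#' Standardize a cohort of measurements against an LMS reference
#'
#' Converts a long-format anthropometry table to SD scores at each child's
#' precise age at measurement. Rows whose age falls outside the reference
#' grid (no extrapolation) or whose value is non-positive are excluded, not
#' silently dropped: they are returned in the `excluded` attribute with a
#' reason, and their count is messaged.
#'
#' @param measurements Data frame with columns `subject_id`, `sex`,
#'   `age_years`, `measure`, `value`. Extra columns are carried through.
#' @param ref An [lms_reference()] table.
#' @return A tibble (`subject_id`, `sex`, `age_years`, `measure`, `sds`, plus
#'   any extra input columns) with attribute `excluded` holding the rejected
#'   rows and a `reason` column.
#' @export
standardize_cohort <- function(measurements, ref) {
  stopifnot(inherits(ref, "lms_reference"))
  m <- tibble::as_tibble(measurements)
  required <- c("subject_id", "sex", "age_years", "measure", "value")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols) > 0) {
    stop("Measurements are missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_sex <- !m$sex %in% c("male", "female")
  bad_measure <- !m$measure %in% unique(ref$measure)
  if (any(bad_sex) || any(bad_measure)) {
    stop("Invalid sex/measure codes in measurement rows: ",
         paste(utils::head(which(bad_sex | bad_measure), 10), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(m) == 0) {
    out <- dplyr::mutate(m[, setdiff(names(m), "value")], sds = numeric(0))
    attr(out, "excluded") <- dplyr::mutate(m, reason = character(0))
    return(out)
  }

  reason <- rep(NA_character_, nrow(m))
  reason[!is.finite(m$value) | m$value <= 0] <- "non-positive or missing value"
  rng <- dplyr::summarise(
    dplyr::group_by(ref, .data$sex, .data$measure),
    lo = min(.data$age_years), hi = max(.data$age_years), .groups = "drop"
  )
  j <- dplyr::left_join(m, rng, by = c("sex", "measure"))
  oor <- is.na(reason) & (j$age_years < j$lo | j$age_years > j$hi)
  reason[oor] <- "age outside reference grid"

  keep <- is.na(reason)
  excluded <- dplyr::mutate(m[!keep, ], reason = reason[!keep])
  kept <- m[keep, ]
  if (nrow(excluded) > 0) {
    message(nrow(excluded), " measurement row(s) excluded from standardization")
  }
  lms <- interpolate_lms(ref, kept$sex, kept$measure, kept$age_years)
  out <- dplyr::mutate(kept[, setdiff(names(kept), "value")],
                       sds = lms_to_sds(kept$value, lms$L, lms$M, lms$S))
  attr(out, "excluded") <- excluded
  out
}
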