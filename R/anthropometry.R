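# Derived body-size quantities and overweight/obesity classification.

#' Body mass index
#'
#' `weight (kg) / height (m)^2`.
#'
#' @param weight_kg Weight in kilograms (>= 0).
#' @param height_m Height in metres (> 0).
#' @return BMI in kg/m^2 (vectorized).
#' @export
bmi <- function(weight_kg, height_m) {
  if (any(height_m <= 0, na.rm = TRUE)) {
    stop("Height must be strictly positive", call. = FALSE)
  }
  if (any(weight_kg < 0, na.rm = TRUE)) {
    stop("Weight must be non-negative", call. = FALSE)
  }
  weight_kg / height_m^2
}

#' Fat or fat-free mass index
#'
#' `mass (kg) / height (m)^2`, used for fat mass index (FMI) and fat-free
#' mass index (FFMI) from body-composition scans.
#'
#' @param mass_kg Mass component in kilograms (>= 0).
#' @param height_m Height in metres (> 0).
#' @return Mass index in kg/m^2 (vectorized).
#' @export
mass_index <- function(mass_kg, height_m) {
  bmi(mass_kg, height_m)
}

#' Derive BMI measurement rows from weight and length/height rows
#'
#' Pairs weight and length/height values recorded for the same subject at the
#' same age and emits `measure = "bmi"` rows (length/height assumed in cm).
#' Unpaired rows are ignored.
#'
#' @param measurements Long-format table with columns `subject_id`, `sex`,
#'   `age_years`, `measure`, `value`.
#' @return Tibble of BMI rows in the same long format.
#' @export
derive_bmi <- function(measurements) {
  m <- tibble::as_tibble(measurements)
  keys <- intersect(c("subject_id", "sex", "age_years", "visit_age"), names(m))
  w <- m[m$measure == "weight", c(keys, "value")]
  h <- m[m$measure == "length_height",
         c(setdiff(keys, "sex"), "value")]
  names(w)[names(w) == "value"] <- "weight_kg"
  names(h)[names(h) == "value"] <- "length_cm"
  j <- dplyr::inner_join(w, h, by = setdiff(keys, "sex"))
  out <- j[, keys]
  out$measure <- "bmi"
  out$value <- bmi(j$weight_kg, j$length_cm / 100)
  tibble::as_tibble(out)
}

#' Validate age-varying BMI cutoff curves
#'
#' Cutoff curves give, per sex, the BMI thresholds for overweight and obesity
#' as a function of age; the curves are centile-based and anchored so that at
#' age 18 they equal exactly 25 and 30 kg/m^2.
#'
#' @param x Data frame with columns `sex`, `age_years`,
#'   `bmi_overweight_cutoff`, `bmi_obese_cutoff`.
#' @return Validated tibble of class `cutoff_curves`.
#' @export
cutoff_curves <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("sex", "age_years", "bmi_overweight_cutoff", "bmi_obese_cutoff")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("Cutoff curves missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(x$bmi_obese_cutoff <= x$bmi_overweight_cutoff)) {
    stop("Obese cutoff must exceed overweight cutoff at every age",
         call. = FALSE)
  }
  at18 <- x[x$age_years == 18, ]
  if (nrow(at18) > 0 &&
      (any(abs(at18$bmi_overweight_cutoff - 25) > 1e-8) ||
       any(abs(at18$bmi_obese_cutoff - 30) > 1e-8))) {
    stop("Cutoff curves must pass through 25 and 30 kg/m^2 at age 18",
         call. = FALSE)
  }
  x <- dplyr::arrange(x, .data$sex, .data$age_years)
  class(x) <- c("cutoff_curves", class(x))
  x
}

#' Classify BMI as normal, overweight or obese
#'
#' Compares BMI with sex-specific cutoff curves interpolated linearly at the
#' exact age. Boundaries are inclusive: a BMI equal to the cutoff takes the
#' heavier category, so at age 18 a BMI of exactly 25 (30) is overweight
#' (obese). Ages outside the curve grid are an error (no extrapolation).
#'
#' @param bmi_value BMI in kg/m^2 (vectorized).
#' @param age_years Age(s) in decimal years.
#' @param sex `"male"` / `"female"` (vectorized).
#' @param curves A [cutoff_curves()] table.
#' @return Factor with levels `normal < overweight < obese`.
#' @export
iotf_classify <- function(bmi_value, age_years, sex, curves) {
  stopifnot(inherits(curves, "cutoff_curves"))
  n <- max(length(bmi_value), length(age_years), length(sex))
  bmi_value <- rep_len(bmi_value, n)
  age_years <- rep_len(age_years, n)
  sex <- rep_len(sex, n)
  ow <- ob <- numeric(n)
  for (sx in unique(sex)) {
    idx <- which(sex == sx)
    tab <- curves[curves$sex == sx, ]
    if (nrow(tab) == 0) stop("No cutoff curves for sex '", sx, "'", call. = FALSE)
    ages <- age_years[idx]
    if (any(ages < min(tab$age_years) | ages > max(tab$age_years))) {
      stop("Age(s) outside cutoff-curve grid for sex '", sx, "'", call. = FALSE)
    }
    ow[idx] <- stats::approx(tab$age_years, tab$bmi_overweight_cutoff, ages)$y
    ob[idx] <- stats::approx(tab$age_years, tab$bmi_obese_cutoff, ages)$y
  }
  cls <- ifelse(bmi_value >= ob, "obese",
                ifelse(bmi_value >= ow, "overweight", "normal"))
  factor(cls, levels = c("normal", "overweight", "obese"), ordered = TRUE)
}
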