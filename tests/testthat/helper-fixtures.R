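# Small fixtures built in code, shared across test files.

# Two-measure toy reference with hand-pickable grid values.
toy_reference <- function() {
  grid <- tibble::tibble(
    age_years = c(0, 1, 2, 5, 10),
    L = c(-0.5, -0.4, -0.3, -0.2, -0.1),
    M_w = c(3.5, 9.5, 12.5, 18.0, 32.0),
    M_l = c(51, 75, 87, 110, 140)
  )
  one_sex <- function(sx, shift) dplyr::bind_rows(
    tibble::tibble(sex = sx, measure = "weight", age_years = grid$age_years,
                   L = grid$L, M = grid$M_w + shift, S = 0.12),
    tibble::tibble(sex = sx, measure = "length_height",
                   age_years = grid$age_years,
                   L = 1, M = grid$M_l + shift, S = 0.08)
  )
  lms_reference(dplyr::bind_rows(one_sex("male", 0), one_sex("female", -0.4)))
}

# Deterministic little genotype table: 4 subjects x 3 variants.
toy_panel <- function() {
  validate_panel(tibble::tibble(
    rsid = c("rs1", "rs2", "rs3"),
    locus_label = c("L1", "L2", "L3"),
    risk_allele = c("A", "C", "G"),
    other_allele = c("G", "T", "A"),
    risk_allele_freq = c(0.3, 0.5, 0.7),
    weight = c(1, 1, 1)
  ))
}

toy_genotypes <- function() {
  tibble::tibble(
    subject_id = 1:4,
    rs1 = c(2L, 1L, 0L, NA),
    rs2 = c(2L, 0L, 1L, 2L),
    rs3 = c(2L, 1L, 1L, NA)
  )
}

# Long observations with known fixed effects and no clustering.
sim_long_obs <- function(n_subj, visits, beta_score = 0.02,
                         beta_age = -0.01, beta_int = 0.005,
                         beta_sex = 0.05, sigma_u = 0.5, sigma_e = 0.6,
                         seed = 1) {
  set.seed(seed)
  nv <- length(visits)
  score_subj <- rbinom(n_subj, 16, 0.45)
  sex_subj <- rbinom(n_subj, 1, 0.5)
  u <- rnorm(n_subj, 0, sigma_u)
  score <- rep(score_subj, each = nv)
  sex <- rep(sex_subj, each = nv)
  age <- rep(visits, n_subj)
  tibble::tibble(
    subject_id = rep(seq_len(n_subj), each = nv),
    age_years = age,
    score = score,
    sex = sex,
    outcome_sds = rep(u, each = nv) + beta_score * score + beta_age * age +
      beta_int * score * age + beta_sex * sex +
      rnorm(n_subj * nv, 0, sigma_e)
  )
}
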