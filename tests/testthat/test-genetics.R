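test_that("unweighted score counts risk alleles with complete-case rule", {
  geno <- toy_genotypes()
  panel <- toy_panel()
  expect_message(sc <- risk_allele_score(geno, panel), "1 subject")
  expect_equal(sc$subject_id, 1:3)
  expect_equal(sc$score, c(6, 2, 2))  # subject 1 all-2s hits the 2*k maximum
  expect_equal(attr(sc, "excluded"), 4L)
  # without the rule, missing genotypes contribute zero and n_variants_used says so
  all4 <- risk_allele_score(geno, panel, require_complete = FALSE)
  expect_equal(all4$n_variants_used, c(3L, 3L, 3L, 1L))

  # mixed dosages across 8 variants: (2,1,0,1,2,0,1,1) -> 8
  p8 <- validate_panel(tibble::tibble(
    rsid = paste0("v", 1:8), risk_allele = "A", other_allele = "G",
    risk_allele_freq = 0.5, weight = 1))
  g8 <- tibble::as_tibble(as.list(stats::setNames(c(2, 1, 0, 1, 2, 0, 1, 1),
                                                  paste0("v", 1:8))))
  g8$subject_id <- 1
  expect_equal(risk_allele_score(g8, p8)$score, 8)
  g0 <- g8; g0[paste0("v", 1:8)] <- 0
  expect_equal(risk_allele_score(g0, p8)$score, 0)
})

test_that("complete-case exclusion count is exact", {
  set.seed(3)
  panel <- toy_panel()
  n <- 500
  geno <- tibble::tibble(
    subject_id = seq_len(n),
    rs1 = sample(c(0:2, NA), n, replace = TRUE, prob = c(.3, .3, .3, .1)),
    rs2 = sample(c(0:2, NA), n, replace = TRUE, prob = c(.3, .3, .3, .1)),
    rs3 = sample(c(0:2, NA), n, replace = TRUE, prob = c(.3, .3, .3, .1))
  )
  n_any_missing <- sum(!stats::complete.cases(geno[, panel$rsid]))
  sc <- suppressMessages(risk_allele_score(geno, panel))
  expect_equal(length(attr(sc, "excluded")), n_any_missing)
  expect_equal(nrow(sc) + n_any_missing, n)
})

test_that("weighted score is the dosage-weight dot product", {
  geno <- toy_genotypes()[1:3, ]
  panel <- toy_panel()
  # all weights 1 reduces to the unweighted count
  expect_equal(weighted_score(geno, panel)$score,
               risk_allele_score(geno, panel)$score)
  # all weights 0 gives zero scores
  p0 <- dplyr::mutate(panel, weight = 0)
  expect_equal(weighted_score(geno, p0)$score, c(0, 0, 0))
  # random weights against a hand-computed dot product
  set.seed(9)
  w <- runif(3)
  pw <- dplyr::mutate(panel, weight = w)
  manual <- as.matrix(geno[, panel$rsid]) %*% w
  expect_equal(weighted_score(geno, pw)$score, drop(manual))
  # a missing weight is a configuration error
  pna <- dplyr::mutate(panel, weight = c(1, NA, 1))
  expect_error(weighted_score(geno, pna), "weight")
})

test_that("panel/genotype validation catches configuration errors", {
  geno <- toy_genotypes()
  bad_panel <- dplyr::mutate(toy_panel(), rsid = c("rs1", "rs2", "rs99"))
  expect_error(risk_allele_score(geno, bad_panel), "rs99")
  bad_geno <- geno; bad_geno$rs1[1] <- 3
  expect_error(risk_allele_score(bad_geno, toy_panel()), "Dosages")
  expect_error(validate_panel(dplyr::mutate(toy_panel(),
                                            risk_allele_freq = c(0, .5, .7))),
               "strictly in")
})

test_that("HWE chi-square matches hand computation", {
  # exact HWE proportions: chi-square 0, p = 1
  h <- hwe_test(25, 50, 25)
  expect_equal(h$chisq, 0)
  expect_equal(h$p_value, 1)
  # (30, 40, 30): allele freq 0.5, expected 25/50/25, chi-square 4
  h2 <- hwe_test(30, 40, 30)
  expect_equal(h2$chisq, 4)
  expect_equal(h2$p_value, pchisq(4, 1, lower.tail = FALSE))
  expect_equal(round(h2$p_value, 4), 0.0455)
  # monomorphic: p = 1 by convention, with a message
  expect_message(h3 <- hwe_test(50, 0, 0), "Monomorphic")
  expect_equal(h3$p_value, 1)
  expect_error(hwe_test(-1, 5, 5), "non-negative")
})

test_that("call rate is the non-missing fraction", {
  geno <- toy_genotypes()
  expect_equal(call_rate(geno, "rs2"), 1)
  expect_equal(call_rate(geno, "rs1"), 0.75)
  g <- tibble::tibble(subject_id = 1:1000,
                      v = c(rep(1L, 933), rep(NA_integer_, 67)))
  expect_equal(call_rate(g, "v"), 0.933)
})

test_that("simulated score distribution matches the binomial convolution", {
  cfg <- sim_config(n_subjects = 10000, seed = 21, genotype_missingness = 0)
  geno <- simulate_genotypes(cfg)
  sc <- risk_allele_score(geno, cfg$panel)
  # independent oracle: exact pmf by convolving 8 Binomial(2, f_j) pmfs
  pmf <- 1
  for (f in cfg$panel$risk_allele_freq) {
    pmf <- convolve(pmf, rev(c((1 - f)^2, 2 * f * (1 - f), f^2)), type = "open")
  }
  expected <- nrow(sc) * pmf
  observed <- tabulate(sc$score + 1, nbins = length(pmf))
  # pool tail cells so all expected counts are >= 5
  keep <- expected >= 5
  obs <- c(sum(observed[!keep]), observed[keep])
  exp <- c(sum(expected[!keep]), expected[keep])
  chisq <- sum((obs - exp)^2 / exp)
  p <- pchisq(chisq, df = length(exp) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})
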