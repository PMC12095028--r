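test_that("trio allele-number arithmetic matches the cohort footnote rules", {
  expect_equal(cohort_allele_numbers(52, "autosomal"),
               list(proband_an = 104L, parent_an = 208L))
  expect_equal(cohort_allele_numbers(52, "X", rep("male", 52)),
               list(proband_an = 52L, parent_an = 156L))
  expect_equal(cohort_allele_numbers(1, "autosomal"),
               list(proband_an = 2L, parent_an = 4L))
  mixed <- cohort_allele_numbers(4, "X", c("male", "female", "male", "female"))
  expect_equal(mixed$proband_an, 6L)
  expect_equal(mixed$parent_an, 12L)
  expect_error(cohort_allele_numbers(4, "X"), "proband_sexes")
})

test_that("allele tables use database counts, fallbacks and parental pooling correctly", {
  # database-documented locus, parents excluded from the tested table
  t1 <- build_allele_table(1, 104, db_ac = 1, db_an = 19954,
                           parental_carriers = 0, parent_an = 208)
  expect_equal(unlist(t1[1, 1:4]),
               c(case_carriers = 1, case_total = 104,
                 ref_carriers = 1, ref_total = 19954))
  expect_equal(t1$ref_provenance, "database")
  expect_equal(t1$ref_display, "1 + 0/(19,954 + 208)")

  # undocumented locus: fallback denominator plus pooled parents
  t2 <- build_allele_table(1, 52, db_ac = NA, db_an = NA,
                           fallback_an = 10904, parental_carriers = 0,
                           parent_an = 156, include_parents = TRUE)
  expect_equal(t2$ref_carriers, 0L)
  expect_equal(t2$ref_total, 11060L)
  expect_equal(t2$ref_provenance, "fallback+parental_added")

  # allele conservation across the pooled table
  expect_equal(t2$case_total + t2$ref_total, 52 + 11060)

  expect_error(build_allele_table(1, 52, db_ac = NA, db_an = NA),
               "fallback")
})

test_that("the one-sided Fisher p matches frozen exact-rational values", {
  p <- function(a, b, c, d) {
    fisher_one_sided(tibble::tibble(case_carriers = a, case_total = a + b,
                                    ref_carriers = c, ref_total = c + d))$p_one_sided
  }
  # values computed independently with exact rational arithmetic
  expect_equal(p(1, 103, 1, 19953), 0.0103433005345, tolerance = 1e-10)
  expect_equal(p(2, 3, 1, 4), 0.5, tolerance = 1e-12)
  expect_equal(p(3, 7, 2, 18), 0.191234053303, tolerance = 1e-10)
  expect_equal(p(5, 0, 0, 5), 1 / choose(10, 5), tolerance = 1e-12)
  # zero case carriers -> certainty
  expect_equal(p(0, 10, 5, 85), 1)
  expect_equal(p(0, 104, 0, 1000), 1)
})

test_that("fisher_one_sided agrees with stats::fisher.test across table space", {
  set.seed(404)
  n_checked <- 0
  for (total in seq(2, 200, by = 3)) {
    for (rep in 1:4) {
      n <- sample.int(total - 1, 1)
      K <- sample.int(total - 1, 1)
      a_max <- min(K, n); a_min <- max(0, n - (total - K))
      a <- sample(a_min:a_max, 1)
      tab <- tibble::tibble(case_carriers = a, case_total = n,
                            ref_carriers = K - a, ref_total = total - n)
      m <- matrix(c(a, n - a, K - a, (total - n) - (K - a)), nrow = 2,
                  byrow = TRUE)
      want <- stats::fisher.test(m, alternative = "greater")$p.value
      expect_equal(fisher_one_sided(tab)$p_one_sided, want,
                   tolerance = 1e-12)
      want2 <- stats::fisher.test(m)$p.value
      expect_equal(fisher_one_sided(tab, alternative = "two.sided")$p_one_sided,
                   want2, tolerance = 1e-9)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 250)
  # spot-check at reference-database scale against the hypergeometric tail
  big <- tibble::tibble(case_carriers = 3, case_total = 104,
                        ref_carriers = 13, ref_total = 18392)
  expect_equal(fisher_one_sided(big)$p_one_sided,
               stats::phyper(2, 16, 104 + 18392 - 16, 104,
                             lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("the Fisher p is monotone non-increasing in the case carrier count", {
  for (K in c(5, 20)) {
    ps <- vapply(0:K, function(a) {
      fisher_one_sided(tibble::tibble(case_carriers = a, case_total = 50,
                                      ref_carriers = K - a,
                                      ref_total = 150))$p_one_sided
    }, numeric(1))
    expect_true(all(diff(ps) <= 1e-12))
  }
})

test_that("chi-square handles boundaries and recommends Fisher for small expecteds", {
  even <- chi_square(matrix(c(10, 10, 10, 10), 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)
  expect_false(even$recommend_fisher)

  skewed <- chi_square(matrix(c(20, 10, 10, 20), 2, byrow = TRUE))
  expect_equal(skewed$statistic, 20 / 3, tolerance = 1e-10)

  rare <- chi_square(matrix(c(1, 51, 0, 11060), 2, byrow = TRUE))
  expect_true(rare$recommend_fisher)

  expect_error(chi_square(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "zero marginal")
})

test_that("phenotype summaries reproduce the printed percentages", {
  flags <- tibble::tibble(
    trio_id = sprintf("T%02d", 1:52),
    atrial_septal_defect = c(rep(TRUE, 32), rep(FALSE, 20)),
    right_aortic_arch = c(rep(TRUE, 30), rep(FALSE, 22)),
    truncus_arteriosus = FALSE
  )
  s <- summarize_phenotypes(flags)
  expect_equal(s$percent[s$category == "atrial_septal_defect"], 61.54)
  expect_equal(s$percent[s$category == "right_aortic_arch"], 57.69)
  expect_equal(s$percent[s$category == "truncus_arteriosus"], 0)
  expect_equal(s$category, names(flags)[-1])  # fixed display order
})

test_that("percentages over an exhaustive category partition sum to ~100", {
  set.seed(5)
  lev <- sample(c("a", "b", "c"), 52, replace = TRUE)
  flags <- tibble::tibble(trio_id = sprintf("T%02d", 1:52),
                          a = lev == "a", b = lev == "b", c = lev == "c")
  s <- summarize_phenotypes(flags)
  expect_equal(sum(s$percent), 100, tolerance = 0.02)
})

test_that("sex ratio matches the cohort arithmetic", {
  ped <- function(m, f) tibble::tibble(proband_sex = c(rep("male", m),
                                                       rep("female", f)))
  expect_equal(sex_ratio(ped(31, 21))$ratio, 1.48)
  expect_equal(sex_ratio(ped(10, 10))$ratio, 1.00)
  expect_equal(sex_ratio(ped(3, 2))$ratio, 1.50)
  expect_warning(inf <- sex_ratio(ped(5, 0)), "infinite")
  expect_equal(inf$ratio, Inf)
})

test_that("tidy and glance expose the Fisher result in broom shape", {
  fr <- fisher_one_sided(build_allele_table(1, 104, db_ac = 1,
                                            db_an = 19954))
  td <- tidy(fr)
  expect_equal(td$case_carriers, 1L)
  expect_equal(td$p.value, fr$p_one_sided)
  gl <- glance(fr)
  expect_equal(gl$method, "hypergeometric_tail")
})
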