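#' Cohort allele numbers for case/control allele tables
#'
#' Computes the proband-side and parent-side allele numbers for a trio
#' cohort. Autosomal loci contribute 2 alleles per proband and 4 per
#' parent pair (`2n` and `4n`). X-chromosome loci contribute 1 allele per
#' male and 2 per female proband, and 3 per parent pair (hemizygous father
#' plus diploid mother).
#'
#' @param n_trios Number of trios (>= 1).
#' @param chrom_class `"autosomal"` or `"X"`.
#' @param proband_sexes Character vector of proband sexes
#'   (`"male"`/`"female"`), required for `"X"`; length must equal
#'   `n_trios`.
#' @return A list with `proband_an` and `parent_an`.
#' @examples
#' cohort_allele_numbers(52, "autosomal")           # 104 and 208
#' cohort_allele_numbers(52, "X", rep("male", 52))  # 52 and 156
#' @export
cohort_allele_numbers <- function(n_trios, chrom_class = c("autosomal", "X"),
                                  proband_sexes = NULL) {
  chrom_class <- match.arg(chrom_class)
  stopifnot(n_trios >= 1)
  if (chrom_class == "autosomal") {
    list(proband_an = 2L * n_trios, parent_an = 4L * n_trios)
  } else {
    if (is.null(proband_sexes) || length(proband_sexes) != n_trios) {
      abort("proband_sexes of length n_trios is required for X loci")
    }
    list(proband_an = sum(ifelse(proband_sexes == "male", 1L, 2L)),
         parent_an = 3L * n_trios)
  }
}

#' Build a case/reference allele-count table
#'
#' Constructs the 2x2 carrier/non-carrier allele table comparing cohort
#' probands against a reference population. The reference side uses the
#' database allele count and number when the locus is recorded there;
#' for loci absent from the database, the carrier count falls back to 0
#' over a configurable fallback allele number. Parental alleles observed
#' in the cohort can optionally be pooled into the reference side; the
#' annotated display string always shows the parental addition, mirroring
#' the published table shape, regardless of whether the p-value uses it.
#'
#' @param case_carriers Carrier allele count among probands.
#' @param case_total Proband allele number (see
#'   [cohort_allele_numbers()]).
#' @param db_ac,db_an Reference-database allele count and number, or `NA`
#'   when the locus is absent from the database.
#' @param fallback_an Allele number to use when the database lacks the
#'   locus (fatal if needed but unset).
#' @param parental_carriers Carrier allele count among cohort parents.
#' @param parent_an Parental allele number.
#' @param include_parents Pool parental alleles into the reference side of
#'   the tested table? Default `FALSE`: the published de novo p-value
#'   reproduces exactly without parental alleles.
#' @return A one-row tibble of class `allele_table` with the four cell
#'   counts, provenance tags, and an annotated `ref_display` string.
#' @export
build_allele_table <- function(case_carriers, case_total,
                               db_ac = NA, db_an = NA,
                               fallback_an = NULL,
                               parental_carriers = 0L, parent_an = 0L,
                               include_parents = FALSE) {
  stopifnot(case_carriers >= 0, case_total > 0, case_carriers <= case_total,
            parental_carriers >= 0, parent_an >= 0)
  db_absent <- is.na(db_ac) || is.na(db_an)
  if (db_absent) {
    if (is.null(fallback_an)) {
      abort("locus absent from the reference database and no fallback_an set")
    }
    base_ac <- 0L
    base_an <- as.integer(fallback_an)
    provenance <- "fallback"
  } else {
    base_ac <- as.integer(db_ac)
    base_an <- as.integer(db_an)
    provenance <- "database"
  }
  if (include_parents) {
    ref_carriers <- base_ac + as.integer(parental_carriers)
    ref_total <- base_an + as.integer(parent_an)
    provenance <- paste0(provenance, "+parental_added")
  } else {
    ref_carriers <- base_ac
    ref_total <- base_an
  }
  stopifnot(ref_carriers <= ref_total, ref_total > 0)
  out <- tibble(
    case_carriers = as.integer(case_carriers),
    case_total = as.integer(case_total),
    ref_carriers = as.integer(ref_carriers),
    ref_total = as.integer(ref_total),
    case_provenance = "cohort_arithmetic",
    ref_provenance = provenance,
    ref_display = paste0(base_ac, " + ", parental_carriers, "/(",
                         format(base_an, big.mark = ",", trim = TRUE),
                         " + ", parent_an, ")")
  )
  class(out) <- c("allele_table", class(out))
  out
}

# log-space sum of exponentials
logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

#' One-sided Fisher exact test on an allele-count table
#'
#' Computes the exact hypergeometric upper-tail probability of observing at
#' least the case carrier count among `case_total` alleles drawn from the
#' pooled allele population — the one-sided (enrichment in probands) Fisher
#' exact test. The tail is summed in log space, so allele numbers in the
#' tens of thousands are handled exactly. A two-sided mode (summing all
#' tables no more probable than the observed one) is available behind the
#' `alternative` flag.
#'
#' @param table An [build_allele_table()] result, or any one-row data frame
#'   with `case_carriers`, `case_total`, `ref_carriers`, `ref_total`.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return An object of class `trio_fisher`: a list with `p_one_sided`
#'   (full precision; round to 4 decimals for display), `table`, `method`
#'   and `alternative`.
#' @examples
#' t <- build_allele_table(1, 104, db_ac = 1, db_an = 19954)
#' round(fisher_one_sided(t)$p_one_sided, 4)  # 0.0103
#' @export
fisher_one_sided <- function(table, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  a <- table$case_carriers[1]
  n <- table$case_total[1]
  K <- a + table$ref_carriers[1]
  N <- n + table$ref_total[1]
  lpmf <- function(x) {
    lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
  }
  support <- max(0L, n - (N - K)):min(K, n)
  if (alternative == "greater") {
    xs <- support[support >= a]
    p <- if (length(xs) == 0) 0 else exp(logsumexp(lpmf(xs)))
  } else {
    lobs <- lpmf(a)
    keep <- support[lpmf(support) <= lobs + 1e-7]
    p <- exp(logsumexp(lpmf(keep)))
  }
  p <- min(1, max(0, p))
  structure(list(p_one_sided = p, table = table,
                 method = "hypergeometric_tail", alternative = alternative),
            class = "trio_fisher")
}

#' @export
print.trio_fisher <- function(x, ...) {
  cat("One-sided Fisher exact (hypergeometric tail)\n")
  cat(sprintf("  case %d/%d vs reference %d/%d\n",
              x$table$case_carriers, x$table$case_total,
              x$table$ref_carriers, x$table$ref_total))
  cat(sprintf("  p (%s) = %.4f\n", x$alternative, x$p_one_sided))
  invisible(x)
}

#' Pearson chi-square test with a small-expected-count recommendation
#'
#' Pearson chi-square without continuity correction on an r x c count
#' table. When any expected count is below 10, the result carries a flag
#' recommending the Fisher exact test instead. A zero marginal makes the
#' expected counts undefined and is fatal.
#'
#' @param m Numeric matrix of counts.
#' @return A one-row tibble with `statistic`, `df`, `p_value`,
#'   `min_expected`, `recommend_fisher`.
#' @export
chi_square <- function(m) {
  m <- as.matrix(m)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("zero marginal total; expected counts are undefined")
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = unname(res$p.value),
    min_expected = min(res$expected),
    recommend_fisher = min(res$expected) < 10
  )
}

#' Summarize binary phenotype flags over a cohort
#'
#' Counts and percentages per phenotype category, with the cohort size as
#' the denominator and 2-decimal display rounding. Category order follows
#' the column order of the input, so summaries print in a fixed,
#' reproducible layout.
#'
#' @param phenotypes Tibble with a `trio_id` column and one logical column
#'   per phenotype category.
#' @return A tibble of class `trio_phenotypes` with `category`, `count`,
#'   `percent`.
#' @export
summarize_phenotypes <- function(phenotypes) {
  stopifnot("trio_id" %in% names(phenotypes))
  n <- nrow(phenotypes)
  cats <- setdiff(names(phenotypes), "trio_id")
  out <- tibble(
    category = cats,
    count = unname(vapply(cats, function(c) sum(phenotypes[[c]], na.rm = TRUE),
                          integer(1))),
    percent = NA_real_
  ) %>%
    mutate(percent = round(100 * .data$count / n, 2))
  class(out) <- c("trio_phenotypes", class(out))
  out
}

#' Cohort sex ratio
#'
#' @param pedigree Pedigree tibble (`proband_sex` column).
#' @return A one-row tibble with `male`, `female`, `ratio` (male/female,
#'   2 decimals; infinite with a warning when there are no females).
#' @export
sex_ratio <- function(pedigree) {
  male <- sum(pedigree$proband_sex == "male")
  female <- sum(pedigree$proband_sex == "female")
  if (female == 0) {
    warn("no female probands; sex ratio is infinite")
    ratio <- Inf
  } else {
    ratio <- round(male / female, 2)
  }
  tibble(male = male, female = female, ratio = ratio)
}
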