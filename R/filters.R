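#' Filtering configuration
#'
#' Bundles the variant-level filter thresholds: minimum per-member read
#' depth, the rarity cutoff on the reference-population allele frequency,
#' the CADD cutoff for damaging nonsynonymous (DNS) calls, and the set of
#' consequence classes counted as loss of function (LOF). Both the
#' frequency and the CADD comparisons are strict ("below 0.001", "greater
#' than 20"): boundary values fail.
#'
#' @param af_threshold Rarity cutoff on allele frequency, in (0, 1).
#'   Default 0.001.
#' @param cadd_threshold PHRED-scaled CADD cutoff for DNS. Default 20.
#' @param min_depth Minimum read depth required in every trio member.
#'   Default 8.
#' @param lof_classes Consequence classes counted as loss of function.
#'   Default stopgain, stoploss, frameshift, splicing. Stoploss is
#'   included by default but the set is overridable.
#' @param af_column Annotation column used as the reference frequency
#'   (default `"AF_EAS"`).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(af_threshold = 0.001, cadd_threshold = 20,
                          min_depth = 8,
                          lof_classes = c("stopgain", "stoploss",
                                          "frameshift", "splicing"),
                          af_column = "AF_EAS") {
  stopifnot(af_threshold > 0, af_threshold < 1,
            cadd_threshold >= 0, min_depth >= 0)
  if ("missense" %in% lof_classes) {
    abort("'missense' cannot be a loss-of-function class")
  }
  structure(list(af_threshold = af_threshold,
                 cadd_threshold = cadd_threshold,
                 min_depth = min_depth,
                 lof_classes = lof_classes,
                 af_column = af_column),
            class = "filter_config")
}

#' Depth filter over trio genotype records
#'
#' A record passes when the minimum read depth over proband, father and
#' mother is at least `min_depth`. A missing depth in any member fails the
#' filter: the depth exclusion exists for specificity, so an unknown depth
#' is treated as unsupported.
#'
#' @param genotypes Genotype tibble (columns `proband_dp`, `father_dp`,
#'   `mother_dp`).
#' @param config A [filter_config()].
#' @return Logical vector, one element per row of `genotypes`.
#' @export
passes_depth <- function(genotypes, config = filter_config()) {
  dp <- pmin(genotypes$proband_dp, genotypes$father_dp,
             genotypes$mother_dp)
  !is.na(dp) & dp >= config$min_depth
}

#' Rarity predicate
#'
#' A variant is rare when its reference-population allele frequency is
#' strictly below the threshold, or when it is not documented in the
#' reference database at all (missing frequency).
#'
#' @param af_ref Numeric vector of allele frequencies (`NA` = undocumented).
#' @param config A [filter_config()].
#' @return Logical vector.
#' @export
is_rare <- function(af_ref, config = filter_config()) {
  is.na(af_ref) | af_ref < config$af_threshold
}

#' Classify variants as damaging nonsynonymous, loss of function, or neither
#'
#' `LOF` when the consequence is in the configured loss-of-function classes;
#' `DNS` when the consequence is missense with CADD strictly greater than
#' the threshold (missing CADD never qualifies); `NEITHER` otherwise.
#' Classification is frequency-agnostic: apply [is_rare()] separately.
#'
#' @param variants Variant/annotation tibble (columns `consequence`,
#'   `cadd`).
#' @param config A [filter_config()].
#' @return The input with a `variant_class` column added
#'   (`"DNS"`/`"LOF"`/`"NEITHER"`).
#' @export
classify_variants <- function(variants, config = filter_config()) {
  mutate(variants, variant_class = case_when(
    .data$consequence %in% config$lof_classes ~ "LOF",
    .data$consequence == "missense" & !is.na(.data$cadd) &
      .data$cadd > config$cadd_threshold ~ "DNS",
    TRUE ~ "NEITHER"
  ))
}

#' Tally the filtering cascade
#'
#' Counts, over an annotated variant table, the stages of the screening
#' cascade: total variants, rare variants, and rare deleterious variants
#' split into damaging nonsynonymous and loss of function. By construction
#' `rare_deleterious = rare_dns + rare_lof <= rare <= total`.
#'
#' @param variants Annotated variant tibble (one row per variant; columns
#'   `af_ref`, `consequence`, `cadd`).
#' @param config A [filter_config()].
#' @return A one-row tibble of class `trio_cascade` with columns `total`,
#'   `rare`, `rare_deleterious`, `rare_dns`, `rare_lof`.
#' @export
cascade_counts <- function(variants, config = filter_config()) {
  cls <- classify_variants(variants, config)
  rare_mask <- is_rare(cls$af_ref, config)
  out <- tibble(
    total = nrow(cls),
    rare = sum(rare_mask),
    rare_dns = sum(rare_mask & cls$variant_class == "DNS"),
    rare_lof = sum(rare_mask & cls$variant_class == "LOF")
  ) %>%
    mutate(rare_deleterious = .data$rare_dns + .data$rare_lof) %>%
    select("total", "rare", "rare_deleterious", "rare_dns", "rare_lof")
  class(out) <- c("trio_cascade", class(out))
  out
}

#' Apply the full variant-level filter cascade to a cohort
#'
#' Joins trio genotype records to their annotations, drops records failing
#' the per-trio depth filter, keeps rare variants, and retains only
#' damaging nonsynonymous or loss-of-function records. Records without an
#' annotation are dropped with a warning (they cannot be assessed).
#'
#' @param genotypes Genotype tibble from [read_cohort_vcf()].
#' @param annotation Annotation tibble from [read_annotation_table()].
#' @param config A [filter_config()].
#' @return The filtered joined tibble, one row per (variant, trio), with
#'   annotation columns and `variant_class` attached.
#' @export
filter_cascade <- function(genotypes, annotation, config = filter_config()) {
  ann <- classify_variants(annotation, config)
  joined <- left_join(genotypes, ann,
                      by = c("chrom", "pos", "ref", "alt"))
  n_unann <- sum(is.na(joined$consequence))
  if (n_unann > 0) {
    warn(paste0(n_unann, " genotype record(s) without annotation dropped"))
    joined <- filter(joined, !is.na(.data$consequence))
  }
  joined %>%
    filter(passes_depth(., config)) %>%
    filter(is_rare(.data$af_ref, config)) %>%
    filter(.data$variant_class %in% c("DNS", "LOF"))
}
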