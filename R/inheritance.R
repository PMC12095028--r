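#' Site-level inheritance labels within a trio
#'
#' Labels each (variant, trio) record with the Mendelian pattern its
#' genotypes support, from genotypes alone:
#'
#' * `DE_NOVO` — proband heterozygous (or hemizygous alt on male X) with
#'   both parents carrying no alternate allele;
#' * `AR_HOMOZYGOUS` — autosomal proband 1/1 with both parents 0/1 (also
#'   emitted, with a warning, for a female X proband 1/1 whose father is
#'   hemizygous alt and mother a carrier);
#' * `X_LINKED_RECESSIVE` — male proband hemizygous alt on X, father
#'   hemizygous ref, mother 0/1;
#' * `HET_FROM_FATHER` / `HET_FROM_MOTHER` — bookkeeping labels for a
#'   proband het with exactly one carrier parent, used for compound-het
#'   pairing;
#' * `MENDELIAN_CONFLICT` — genotypes impossible under Mendelian
#'   transmission (e.g. proband 1/1 with a 0/0 parent); excluded from calls;
#' * `NONE` — anything else, including records with any missing genotype.
#'
#' A proband 1/1 with both parents 0/0 is a double de novo hit or a
#' genotyping error; it is labeled `MENDELIAN_CONFLICT`, not `DE_NOVO`, for
#' specificity. A proband het carried by both parents is phase-ambiguous
#' and unusable for pairing, so it gets `NONE`.
#'
#' @param trio_variants Tibble with columns `chrom`, `proband_sex`,
#'   `proband_gt`, `father_gt`, `mother_gt` (canonical genotype strings).
#' @return The input with a `site_label` column added.
#' @export
classify_sites <- function(trio_variants) {
  dp <- gt_dosage(trio_variants$proband_gt)
  df <- gt_dosage(trio_variants$father_gt)
  dm <- gt_dosage(trio_variants$mother_gt)
  on_x <- is_x_chrom(trio_variants$chrom)
  male <- trio_variants$proband_sex == "male"

  any_missing <- is.na(dp) | is.na(df) | is.na(dm)

  label <- rep("NONE", nrow(trio_variants))

  # male X: proband and father haploid, mother diploid
  mx <- !any_missing & on_x & male
  label[mx & dp == 1 & df == 0 & dm == 0] <- "DE_NOVO"
  label[mx & dp == 1 & df == 0 & dm == 1] <- "X_LINKED_RECESSIVE"
  label[mx & dp == 1 & df >= 1 & dm == 0] <- "MENDELIAN_CONFLICT"

  # female X: diploid proband, haploid father
  fx <- !any_missing & on_x & !male
  label[fx & dp == 2 & df >= 1 & dm >= 1] <- "AR_HOMOZYGOUS"
  label[fx & dp == 2 & (df == 0 | dm == 0)] <- "MENDELIAN_CONFLICT"
  label[fx & dp == 1 & df == 0 & dm == 0] <- "DE_NOVO"
  label[fx & dp == 1 & df >= 1 & dm == 0] <- "HET_FROM_FATHER"
  label[fx & dp == 1 & df == 0 & dm >= 1] <- "HET_FROM_MOTHER"

  # autosomes: diploid throughout
  au <- !any_missing & !on_x
  label[au & dp == 2 & df == 1 & dm == 1] <- "AR_HOMOZYGOUS"
  label[au & dp == 2 & (df == 0 | dm == 0)] <- "MENDELIAN_CONFLICT"
  label[au & dp == 1 & df == 0 & dm == 0] <- "DE_NOVO"
  label[au & dp == 1 & df >= 1 & dm == 0] <- "HET_FROM_FATHER"
  label[au & dp == 1 & df == 0 & dm >= 1] <- "HET_FROM_MOTHER"

  if (any(label == "AR_HOMOZYGOUS" & fx)) {
    warn(paste0(sum(label == "AR_HOMOZYGOUS" & fx), " female X homozygous ",
                "call(s) emitted as AR_HOMOZYGOUS-on-X"))
  }
  mutate(trio_variants, site_label = label)
}

#' Pair inherited hets into compound-heterozygous calls
#'
#' Within each (trio, gene), every unordered pair of one maternally and one
#' paternally transmitted het yields one compound-het call; a variant may
#' participate in several pairs. Phase is inferred solely from parental
#' transmission, so hets carried by both parents never reach this stage.
#'
#' @param labeled Output of [classify_sites()] (must carry `trio_id`,
#'   `gene`, `site_label` and the variant key columns).
#' @return A tibble of compound-het call rows: two rows per call sharing a
#'   `call_id`, with `parental_origin` `"father"` or `"mother"`.
#' @export
find_compound_hets <- function(labeled) {
  hets <- filter(labeled,
                 .data$site_label %in% c("HET_FROM_FATHER",
                                         "HET_FROM_MOTHER"),
                 !is.na(.data$gene))
  if (nrow(hets) == 0) return(call_row_prototype())
  groups <- split(hets, paste(hets$trio_id, hets$gene, sep = "\r"))
  rows <- purrr::map(groups, function(g) {
    pat <- which(g$site_label == "HET_FROM_FATHER")
    mat <- which(g$site_label == "HET_FROM_MOTHER")
    if (length(pat) == 0 || length(mat) == 0) return(NULL)
    pairs <- expand.grid(f = pat, m = mat)
    purrr::map(seq_len(nrow(pairs)), function(i) {
      two <- g[c(pairs$f[i], pairs$m[i]), , drop = FALSE]
      # skip degenerate "pairs" of one and the same variant
      if (nrow(distinct(two, .data$chrom, .data$pos, .data$ref,
                        .data$alt)) < 2) return(NULL)
      two <- arrange(two, .data$chrom, .data$pos, .data$alt)
      two$parental_origin <- ifelse(two$site_label == "HET_FROM_FATHER",
                                    "father", "mother")
      two$mode <- "COMPOUND_HET"
      two$call_id <- paste("COMPOUND_HET", two$trio_id[1], two$gene[1],
                           paste(two$chrom, two$pos, two$alt,
                                 collapse = "|", sep = ":"),
                           sep = "/")
      two
    }) %>% purrr::compact() %>% bind_rows()
  })
  bind_rows(rows)
}

call_row_prototype <- function() {
  tibble(call_id = character(), trio_id = character(), gene = character(),
         mode = character(), chrom = character(), pos = integer(),
         ref = character(), alt = character(),
         parental_origin = character())
}

#' Classify a filtered cohort into inheritance-mode calls
#'
#' Runs [classify_sites()] and [find_compound_hets()] over a cohort of
#' rare deleterious (already filtered) variant-by-trio records and returns
#' the full call set across the four modes: de novo, autosomal recessive
#' homozygous, compound heterozygous, and X-linked recessive. Output order
#' is deterministic; identical (trio, gene, mode, variant) calls are
#' deduplicated; records with Mendelian-inconsistent genotypes are excluded
#' and counted in the `n_mendelian_conflict` attribute.
#'
#' @param filtered Filtered joined tibble from [filter_cascade()] (or any
#'   tibble with the genotype, annotation and `gene` columns).
#' @param pedigree Pedigree tibble; every `trio_id` in `filtered` must be
#'   present (fatal otherwise).
#' @return A tibble of call rows (one per variant; compound-het calls span
#'   two rows sharing `call_id`) with columns `call_id`, `trio_id`, `gene`,
#'   `mode`, the variant key, `parental_origin`, genotypes, and any
#'   annotation columns present in the input. Attributes:
#'   `n_mendelian_conflict`.
#' @export
classify_cohort <- function(filtered, pedigree) {
  unknown <- setdiff(unique(filtered$trio_id), pedigree$trio_id)
  if (length(unknown)) {
    abort(paste0("trio(s) absent from pedigree: ",
                 paste(unknown, collapse = ", ")))
  }
  labeled <- classify_sites(filtered)
  n_conflict <- sum(labeled$site_label == "MENDELIAN_CONFLICT")
  if (n_conflict > 0) {
    inform(paste0(n_conflict, " Mendelian-inconsistent record(s) excluded"))
  }

  singles <- labeled %>%
    filter(.data$site_label %in% c("DE_NOVO", "AR_HOMOZYGOUS",
                                   "X_LINKED_RECESSIVE")) %>%
    mutate(
      mode = .data$site_label,
      parental_origin = case_when(
        .data$mode == "DE_NOVO" ~ "neither",
        .data$mode == "X_LINKED_RECESSIVE" ~ "mother",
        TRUE ~ "ambiguous"
      ),
      call_id = paste(.data$mode, .data$trio_id, .data$gene,
                      paste(.data$chrom, .data$pos, .data$alt, sep = ":"),
                      sep = "/")
    )

  comp <- find_compound_hets(labeled)

  calls <- bind_rows(singles, comp) %>%
    select(-"site_label") %>%
    distinct(.data$call_id, .data$chrom, .data$pos, .data$ref, .data$alt,
             .keep_all = TRUE)

  # deterministic order: calls by their first variant, rows within a call
  # by position
  if (nrow(calls) > 0) {
    first_key <- calls %>%
      group_by(.data$call_id) %>%
      summarise(k = min(paste(.data$chrom,
                              formatC(.data$pos, width = 12, flag = "0"),
                              .data$alt, .data$trio_id)),
                .groups = "drop")
    calls <- calls %>%
      left_join(first_key, by = "call_id") %>%
      arrange(.data$k, .data$chrom, .data$pos, .data$alt) %>%
      select(-"k")
  }
  attr(calls, "n_mendelian_conflict") <- n_conflict
  calls
}
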