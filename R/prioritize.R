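#' Intersect loss-of-function variants with the disease gene list
#'
#' Given LOF-classified variants, returns the distinct genes flagged on the
#' configured CHD gene list that harbor at least one LOF variant, together
#' with the retained variant rows. Gene symbols are compared after
#' upper-casing; a variant whose gene is absent from the resource is
#' treated as non-CHD, with a warning. Output is invariant under input
#' order and duplicated rows.
#'
#' @param lof_variants Tibble of LOF variants (columns `gene` plus the
#'   variant key; a `trio_id` column is carried through when present).
#' @param resource Gene resource tibble from [read_gene_resource()].
#' @return A list with `genes` (sorted character vector) and `variants`
#'   (the retained, deduplicated rows).
#' @export
intersect_chd_lof <- function(lof_variants, resource) {
  if (nrow(lof_variants) == 0) {
    return(list(genes = character(), variants = lof_variants))
  }
  lv <- mutate(lof_variants, gene = toupper(.data$gene))
  unknown <- setdiff(unique(lv$gene), resource$gene)
  if (length(unknown)) {
    warn(paste0(length(unknown), " gene(s) absent from the gene resource, ",
                "treated as non-CHD: ",
                paste(head(sort(unknown), 5), collapse = ", ")))
  }
  chd <- resource$gene[resource$is_chd_gene]
  kept <- lv %>%
    filter(.data$gene %in% chd) %>%
    distinct() %>%
    arrange(.data$chrom, .data$pos, .data$alt)
  list(genes = sort(unique(kept$gene)), variants = kept)
}

#' Rank genes by loss-of-function constraint
#'
#' Sorts genes ascending by LOEUF (most constrained first; missing scores
#' last, ties broken lexicographically by symbol) and flags genes with
#' LOEUF strictly below the threshold as prioritized. The full list is
#' always returned: the constraint scores are continuous metrics and the
#' cutoff is a reading aid, not a filter.
#'
#' @param genes Character vector of gene symbols.
#' @param resource Gene resource tibble.
#' @param threshold LOEUF cutoff (default 0.6, the recommended threshold
#'   for interpreting Mendelian disease cases).
#' @return A tibble with columns `gene`, `loeuf`, `oe`, `is_cilia_gene`,
#'   `prioritized`, sorted as described.
#' @export
loeuf_prioritize <- function(genes, resource, threshold = 0.6) {
  genes <- toupper(genes)
  res <- resource[match(genes, resource$gene), , drop = FALSE]
  tibble(
    gene = genes,
    loeuf = res$loeuf,
    oe = res$oe,
    is_cilia_gene = res$is_cilia_gene %in% TRUE,
    prioritized = !is.na(res$loeuf) & res$loeuf < threshold
  ) %>%
    arrange(is.na(.data$loeuf), .data$loeuf, .data$gene)
}

#' Fraction of cilia-annotated genes in a gene set
#'
#' @param genes Character vector of gene symbols.
#' @param resource Gene resource tibble (`is_cilia_gene` flags).
#' @return A one-row tibble of class `trio_cilia` with `count_cilia`,
#'   `count_total` and `percent` (1 decimal; an empty set yields 0 with a
#'   warning).
#' @examples
#' res <- tibble::tibble(gene = c("A", "B"), loeuf = NA_real_, oe = NA_real_,
#'                       is_chd_gene = TRUE, is_cilia_gene = c(TRUE, FALSE))
#' cilia_fraction(c("A", "B"), res)
#' @export
cilia_fraction <- function(genes, resource) {
  genes <- unique(toupper(genes))
  total <- length(genes)
  n_cilia <- sum(resource$is_cilia_gene[match(genes, resource$gene)] %in% TRUE)
  if (total == 0) {
    warn("empty gene set; cilia fraction reported as 0")
    pct <- 0
  } else {
    pct <- round(100 * n_cilia / total, 1)
  }
  out <- tibble(count_cilia = n_cilia, count_total = total, percent = pct)
  class(out) <- c("trio_cilia", class(out))
  out
}

#' Per-proband candidate-gene burden
#'
#' Counts, for every proband, the distinct genes implicated either by an
#' inheritance-mode call or by a retained CHD-LOF variant, and buckets
#' probands into `none` (0 genes), `single` (1) and `multiple` (>= 2).
#' Compound-het pairs count their gene once. Percentages are over all
#' probands in the pedigree, to 2 decimals, and category counts always sum
#' to the cohort size.
#'
#' @param calls Inheritance-call tibble from [classify_cohort()] (may be
#'   empty).
#' @param chd_lof_variants Retained CHD-LOF variant tibble with `trio_id`
#'   and `gene` columns (may be `NULL`).
#' @param pedigree Pedigree tibble defining the cohort.
#' @return A list with `burden` (tibble: `trio_id`, `n_genes`, `category`)
#'   and `summary` (tibble of class `trio_burden`: `category`, `count`,
#'   `percent`).
#' @export
gene_burden <- function(calls, chd_lof_variants = NULL, pedigree) {
  pick <- function(d) {
    if (is.null(d) || nrow(d) == 0) {
      tibble(trio_id = character(), gene = character())
    } else {
      tibble(trio_id = d$trio_id, gene = toupper(d$gene))
    }
  }
  implicated <- bind_rows(pick(calls), pick(chd_lof_variants)) %>%
    distinct()
  per_trio <- implicated %>% count(.data$trio_id, name = "n_genes")
  burden <- tibble(trio_id = pedigree$trio_id) %>%
    left_join(per_trio, by = "trio_id") %>%
    mutate(n_genes = ifelse(is.na(.data$n_genes), 0L, .data$n_genes),
           category = case_when(.data$n_genes == 0 ~ "none",
                                .data$n_genes == 1 ~ "single",
                                TRUE ~ "multiple"))
  n_total <- nrow(pedigree)
  summary <- tibble(category = c("single", "multiple", "none")) %>%
    left_join(count(burden, .data$category), by = "category") %>%
    mutate(count = ifelse(is.na(.data$n), 0L, .data$n),
           percent = round(100 * .data$count / n_total, 2)) %>%
    select("category", "count", "percent")
  class(summary) <- c("trio_burden", class(summary))
  list(burden = burden, summary = summary)
}
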