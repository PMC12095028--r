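#' Allele-count Fisher report for candidate variants
#'
#' For every distinct candidate variant, builds the case/reference
#' allele-count table (probands vs a reference population) and computes
#' the one-sided Fisher exact p-value. Proband and parental carrier
#' alleles are counted from the cohort genotypes (males contribute one X
#' allele); allele numbers follow the trio arithmetic of
#' [cohort_allele_numbers()]. Variants absent from a reference database
#' fall back to a configurable allele number for that database. The
#' annotated reference counts (with the parental addition) are always
#' displayed; whether parental alleles enter the tested table is
#' controlled by `include_parents` (default off, which reproduces the
#' published de novo p-value exactly).
#'
#' @param variants Tibble of candidate variants (`chrom`, `pos`, `ref`,
#'   `alt`, `gene`, optionally `mode`).
#' @param genotypes Full cohort genotype tibble.
#' @param pedigree Pedigree tibble.
#' @param ref_counts Reference-count tibble (`chrom`, `pos`, `ref`, `alt`,
#'   `db_name`, `ac`, `an`); absent rows mean the locus is undocumented.
#' @param fallback_an Named vector of fallback allele numbers per database
#'   (defaults: 10904 for a gnomAD-scale extract, 5998 for a Han-scale
#'   extract).
#' @param include_parents Pool parental alleles into the reference side of
#'   the tested table?
#' @param alternative Sidedness of the Fisher test.
#' @return A tibble with one row per (variant, database): identification
#'   columns, `case_display`, `ref_display`, `p_value` (4 decimals) and
#'   `p_full`.
#' @export
allele_count_report <- function(variants, genotypes, pedigree, ref_counts,
                                fallback_an = c(gnomad_eas = 10904,
                                                han = 5998),
                                include_parents = FALSE,
                                alternative = "greater") {
  variants <- distinct(variants, .data$chrom, .data$pos, .data$ref,
                       .data$alt, .keep_all = TRUE)
  n_trios <- nrow(pedigree)
  dbs <- union(unique(ref_counts$db_name), names(fallback_an))
  rows <- purrr::map(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    g <- filter(genotypes, .data$chrom == v$chrom, .data$pos == v$pos,
                .data$ref == v$ref, .data$alt == v$alt)
    case_carriers <- sum(gt_dosage(g$proband_gt), na.rm = TRUE)
    parental_carriers <- sum(gt_dosage(g$father_gt), na.rm = TRUE) +
      sum(gt_dosage(g$mother_gt), na.rm = TRUE)
    an <- cohort_allele_numbers(
      n_trios,
      chrom_class = if (is_x_chrom(v$chrom)) "X" else "autosomal",
      proband_sexes = pedigree$proband_sex
    )
    purrr::map(dbs, function(db) {
      hit <- filter(ref_counts, .data$db_name == db,
                    .data$chrom == v$chrom, .data$pos == v$pos,
                    .data$ref == v$ref, .data$alt == v$alt)
      fb <- unname(fallback_an[db])
      if (nrow(hit) == 0 && (is.null(fb) || is.na(fb))) {
        warn(paste0("no fallback allele number for database '", db,
                    "'; variant ", v$chrom, ":", v$pos, " skipped"))
        return(NULL)
      }
      tab <- build_allele_table(
        case_carriers = case_carriers, case_total = an$proband_an,
        db_ac = if (nrow(hit)) hit$ac[1] else NA,
        db_an = if (nrow(hit)) hit$an[1] else NA,
        fallback_an = fb,
        parental_carriers = parental_carriers, parent_an = an$parent_an,
        include_parents = include_parents
      )
      fr <- fisher_one_sided(tab, alternative = alternative)
      tibble(
        gene = v$gene, chrom = v$chrom, pos = v$pos, ref = v$ref,
        alt = v$alt,
        mode = if ("mode" %in% names(v)) v$mode else NA_character_,
        case_display = paste0(case_carriers, "/", an$proband_an),
        db_name = db,
        ref_display = tab$ref_display,
        ref_provenance = tab$ref_provenance,
        p_value = round(fr$p_one_sided, 4),
        p_full = fr$p_one_sided
      )
    }) %>% purrr::compact() %>% bind_rows()
  })
  bind_rows(rows) %>%
    arrange(.data$chrom, .data$pos, .data$alt, .data$db_name)
}

#' Run the full trio prioritization pipeline
#'
#' Orchestrates the stages over an in-memory cohort (from
#' [generate_cohort()] or assembled from the readers): variant-level
#' filtering, inheritance-mode classification, evidence assignment and
#' five-tier classification, LOF/disease-gene intersection with LOEUF and
#' cilia annotation, per-proband gene burden, phenotype summary and the
#' allele-count Fisher report. Deterministic at fixed inputs.
#'
#' @param cohort A `trio_cohort` list (elements `pedigree`, `genotypes`,
#'   `annotation`, `gene_resource`; optionally `ref_counts`,
#'   `phenotypes`).
#' @param config A [filter_config()].
#' @param fallback_an,include_parents,alternative Passed to
#'   [allele_count_report()].
#' @param domain_intervals Optional critical-domain intervals for PM1 (see
#'   [assign_evidence()]).
#' @param loeuf_threshold LOEUF prioritization cutoff.
#' @return A list of class `trio_run` with elements `cascade`, `calls`,
#'   `candidates`, `chd_lof`, `gene_table`, `cilia`, `burden`,
#'   `phenotype_summary`, `sex_ratio`, `fisher_report`, `stage_log`.
#' @export
trio_run <- function(cohort, config = filter_config(),
                     fallback_an = c(gnomad_eas = 10904, han = 5998),
                     include_parents = FALSE, alternative = "greater",
                     domain_intervals = NULL, loeuf_threshold = 0.6) {
  for (el in c("pedigree", "genotypes", "annotation", "gene_resource")) {
    if (is.null(cohort[[el]])) abort(paste0("cohort lacks element '", el, "'"))
  }
  stage <- list()

  cascade <- cascade_counts(cohort$annotation, config)
  filtered <- filter_cascade(cohort$genotypes, cohort$annotation, config)
  stage$filter <- c(records_in = nrow(cohort$genotypes),
                    records_out = nrow(filtered))

  calls <- classify_cohort(filtered, cohort$pedigree)
  stage$classify <- c(records_in = nrow(filtered), calls_out = nrow(calls))

  candidates <- if (nrow(calls) > 0) {
    assign_evidence(calls, config, domain_intervals = domain_intervals)
  } else calls

  lof_carried <- filtered %>%
    filter(.data$variant_class == "LOF",
           gt_dosage(.data$proband_gt) >= 1)
  chd_lof <- intersect_chd_lof(lof_carried, cohort$gene_resource)
  gene_table <- loeuf_prioritize(chd_lof$genes, cohort$gene_resource,
                                 threshold = loeuf_threshold)
  cilia <- cilia_fraction(chd_lof$genes, cohort$gene_resource)
  stage$prioritize <- c(lof_in = nrow(lof_carried),
                        genes_out = length(chd_lof$genes))

  burden <- gene_burden(calls, chd_lof$variants, cohort$pedigree)

  phenotype_summary <- if (!is.null(cohort$phenotypes)) {
    summarize_phenotypes(cohort$phenotypes)
  } else NULL

  fisher_report <- if (!is.null(cohort$ref_counts) && nrow(candidates) > 0) {
    allele_count_report(candidates, cohort$genotypes, cohort$pedigree,
                        cohort$ref_counts, fallback_an = fallback_an,
                        include_parents = include_parents,
                        alternative = alternative)
  } else NULL

  structure(list(
    cascade = cascade, calls = calls, candidates = candidates,
    chd_lof = chd_lof, gene_table = gene_table, cilia = cilia,
    burden = burden, phenotype_summary = phenotype_summary,
    sex_ratio = sex_ratio(cohort$pedigree),
    fisher_report = fisher_report,
    stage_log = stage,
    n_mendelian_conflict = attr(calls, "n_mendelian_conflict") %||% 0L,
    config = config
  ), class = "trio_run")
}

#' Write a run's report bundle
#'
#' Emits the run results as plain tab-separated tables mirroring the
#' published table shapes (candidate table, allele-count test report, gene
#' table, burden table, phenotype summary, cascade counts), plus a run log
#' with the package version, configuration and per-stage record counts.
#' Byte-identical across reruns of the same run object.
#'
#' @param run A `trio_run`.
#' @param dir Output directory.
#' @return Named vector of paths, invisibly.
#' @export
write_report_bundle <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(candidates = file.path(dir, "candidate_table.tsv"),
             cascade = file.path(dir, "cascade_counts.tsv"),
             gene_table = file.path(dir, "gene_table.tsv"),
             burden = file.path(dir, "burden_table.tsv"),
             phenotypes = file.path(dir, "phenotype_summary.tsv"),
             fisher = file.path(dir, "allele_count_tests.tsv"),
             log = file.path(dir, "run_log.txt"))
  write_candidate_table(run$candidates, paths["candidates"])
  readr::write_tsv(as_tibble(run$cascade), paths["cascade"],
                   progress = FALSE)
  gt <- run$gene_table
  names(gt) <- c("GENE", "LOEUF", "OE", "CILIA", "PRIORITIZED")
  readr::write_tsv(gt, paths["gene_table"], progress = FALSE)
  readr::write_tsv(run$burden$summary, paths["burden"], progress = FALSE)
  if (!is.null(run$phenotype_summary)) {
    readr::write_tsv(as_tibble(run$phenotype_summary), paths["phenotypes"],
                     progress = FALSE)
  }
  if (!is.null(run$fisher_report)) {
    readr::write_tsv(select(run$fisher_report, -"p_full"), paths["fisher"],
                     progress = FALSE)
  }
  cfg <- run$config
  writeLines(c(
    paste0("trioprio ", as.character(utils::packageVersion("trioprio"))),
    paste0("af_threshold=", cfg$af_threshold),
    paste0("cadd_threshold=", cfg$cadd_threshold),
    paste0("min_depth=", cfg$min_depth),
    paste0("lof_classes=", paste(cfg$lof_classes, collapse = ",")),
    paste0("mendelian_conflicts=", run$n_mendelian_conflict),
    vapply(names(run$stage_log), function(s) {
      paste0("stage ", s, ": ",
             paste(names(run$stage_log[[s]]), run$stage_log[[s]],
                   sep = "=", collapse = " "))
    }, character(1))
  ), paths["log"], useBytes = TRUE)
  invisible(paths)
}

#' @export
print.trio_run <- function(x, ...) {
  cat("Trio prioritization run\n")
  cat(sprintf("  variants: %d total, %d rare, %d rare deleterious (%d DNS + %d LOF)\n",
              x$cascade$total, x$cascade$rare, x$cascade$rare_deleterious,
              x$cascade$rare_dns, x$cascade$rare_lof))
  cat(sprintf("  inheritance calls: %d row(s), %d distinct call(s)\n",
              nrow(x$calls), length(unique(x$calls$call_id))))
  cat(sprintf("  CHD-LOF: %d variant(s) in %d gene(s); cilia %0.1f%% (%d/%d)\n",
              nrow(x$chd_lof$variants), length(x$chd_lof$genes),
              x$cilia$percent, x$cilia$count_cilia, x$cilia$count_total))
  b <- x$burden$summary
  cat(sprintf("  burden: single %d (%.2f%%), multiple %d (%.2f%%), none %d (%.2f%%)\n",
              b$count[1], b$percent[1], b$count[2], b$percent[2],
              b$count[3], b$percent[3]))
  invisible(x)
}
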