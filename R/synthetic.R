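#' Specification for a synthetic trio cohort
#'
#' Describes a cohort of affected-proband trios with planted
#' inheritance-mode variants, loss-of-function variants in disease-listed
#' genes, and background common variation, together with the annotation and
#' gene-resource tables the pipeline consumes. The defaults emulate the
#' study conditions of a 52-trio CHD/laterality-defect cohort: 31 male
#' probands, one planted variant per inheritance mode, 48 LOF variants
#' across 46 disease-listed genes of which 12 are cilia-flagged, a
#' 1786-gene disease list with 134 cilia flags, and a per-proband burden
#' split of 20 single-gene, 16 multi-gene and 16 gene-free probands. With
#' those defaults every printed marginal count of the emulated study is
#' realized exactly and simultaneously.
#'
#' Burden bookkeeping: each inheritance-mode plant implicates one gene in
#' its (single-gene) trio; the remaining single-gene trios receive one
#' CHD-LOF variant each and every multi-gene trio receives two, in two
#' distinct genes. This forces
#' `n_chd_lof = (burden_single - n_inherit) + 2 * burden_multiple`;
#' an inconsistent request is rejected rather than silently adjusted.
#'
#' @param seed Master seed; every file type draws from its own stream
#'   derived from it, so outputs are byte-identical at fixed seed.
#' @param n_trios Number of trios.
#' @param male_fraction Fraction of male probands (deterministic count,
#'   `round(male_fraction * n_trios)`).
#' @param n_de_novo,n_ar_hom,n_comp_het,n_xlr Planted inheritance-mode
#'   calls (compound het counts pairs). Each goes to its own trio.
#' @param n_chd_lof,n_chd_lof_genes Planted LOF variants in disease-listed
#'   genes and the number of distinct genes they land in.
#' @param n_cilia_in_lof How many of those LOF genes carry the cilia flag.
#' @param n_chd_genes,n_cilia_genes Size of the disease gene list and its
#'   total cilia-flagged count.
#' @param n_background Common benign background variants (allele frequency
#'   above the rarity threshold, low CADD), fully removed by the rarity
#'   filter.
#' @param burden_single,burden_multiple Probands with exactly one / two or
#'   more implicated genes (`NULL` disables burden-exact allocation and
#'   spreads LOF plants cyclically).
#' @param phenotype_counts Named integer vector of per-category flag
#'   counts for the phenotype table; flags are assigned deterministically
#'   so summaries match these margins exactly. Defaults mirror the main
#'   anatomical categories of the emulated cohort.
#' @param af_threshold Rarity threshold the planted frequencies straddle.
#' @param depth_range Sampled read-depth range for all genotype cells.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_trios = 52L,
                           male_fraction = 31 / 52,
                           n_de_novo = 1L, n_ar_hom = 1L,
                           n_comp_het = 1L, n_xlr = 1L,
                           n_chd_lof = 48L, n_chd_lof_genes = 46L,
                           n_cilia_in_lof = 12L,
                           n_chd_genes = 1786L, n_cilia_genes = 134L,
                           n_background = 100L,
                           burden_single = 20L, burden_multiple = 16L,
                           phenotype_counts = c(
                             dextrocardia = 30L,
                             bilateral_superior_vena_cava = 23L,
                             atrial_septal_defect = 32L,
                             ventricular_septal_defect = 26L,
                             right_aortic_arch = 30L,
                             left_sided_liver = 20L,
                             right_sided_spleen = 24L,
                             lung_invert = 13L
                           ),
                           af_threshold = 0.001,
                           depth_range = c(20L, 60L)) {
  spec <- list(seed = as.integer(seed), n_trios = as.integer(n_trios),
               male_fraction = male_fraction,
               n_de_novo = n_de_novo, n_ar_hom = n_ar_hom,
               n_comp_het = n_comp_het, n_xlr = n_xlr,
               n_chd_lof = n_chd_lof, n_chd_lof_genes = n_chd_lof_genes,
               n_cilia_in_lof = n_cilia_in_lof,
               n_chd_genes = n_chd_genes, n_cilia_genes = n_cilia_genes,
               n_background = n_background,
               burden_single = burden_single,
               burden_multiple = burden_multiple,
               phenotype_counts = phenotype_counts,
               af_threshold = af_threshold,
               depth_range = depth_range)
  n_inherit <- n_de_novo + n_ar_hom + n_comp_het + n_xlr
  if (n_chd_lof_genes > n_chd_lof) {
    abort("n_chd_lof_genes cannot exceed n_chd_lof")
  }
  if (n_cilia_in_lof > n_cilia_genes || n_chd_lof_genes > n_chd_genes ||
      n_cilia_in_lof > n_chd_lof_genes ||
      (n_cilia_genes - n_cilia_in_lof) > (n_chd_genes - n_chd_lof_genes)) {
    abort("cilia/disease gene counts are inconsistent")
  }
  if (!is.null(burden_single)) {
    if (is.null(burden_multiple)) abort("burden targets must both be set")
    if (n_inherit > burden_single) {
      abort("inheritance plants exceed the single-gene burden target")
    }
    if (burden_single + burden_multiple > n_trios) {
      abort("burden targets exceed the cohort size")
    }
    need <- (burden_single - n_inherit) + 2L * burden_multiple
    if (need != n_chd_lof) {
      abort(paste0("burden targets require ", need,
                   " CHD-LOF variants but n_chd_lof = ", n_chd_lof))
    }
    if (burden_multiple > 0 && n_chd_lof_genes < 2) {
      abort("multi-gene trios need at least 2 distinct LOF genes")
    }
  }
  if (any(unlist(phenotype_counts) > n_trios)) {
    abort("phenotype counts cannot exceed the cohort size")
  }
  structure(spec, class = "synthetic_spec")
}

# Component-specific sub-seed, kept below 2^31.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k * 9973) %% 2147483647L)
}

#' Generate a synthetic trio cohort
#'
#' Realizes a [synthetic_spec()] as in-memory tables: pedigree, per-trio
#' genotype records, variant annotation, gene resource, reference-database
#' allele counts, deterministic phenotype flags, and a truth table of every
#' planted call. Positions are drawn collision-free on two synthetic
#' contigs (`chr1` and `chrX`); no reference sequence is required. All
#' planted variants are rare or undocumented with mode-consistent trio
#' genotypes and depths at or above typical filter settings; background
#' variants are common, Mendelian-consistent and benign, so the filter
#' cascade removes exactly them.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `trio_cohort` with elements `pedigree`,
#'   `genotypes`, `annotation`, `gene_resource`, `ref_counts`,
#'   `phenotypes`, `truth` and `spec`. The truth table has one row per
#'   planted variant: `trio_id`, `mode`, `gene`, `chrom`, `pos`, `ref`,
#'   `alt` (compound-het pairs span two rows).
#' @export
generate_cohort <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_trios
  trio_ids <- sprintf("T%03d", seq_len(n))

  # --- pedigree & sexes -------------------------------------------------
  n_male <- round(spec$male_fraction * n)
  sexes <- withr::with_seed(sub_seed(spec$seed, 1), {
    s <- rep("female", n)
    s[sample.int(n, n_male)] <- "male"
    s
  })
  pedigree <- tibble(
    trio_id = trio_ids,
    proband_id = paste0(trio_ids, "_P"),
    father_id = paste0(trio_ids, "_F"),
    mother_id = paste0(trio_ids, "_M"),
    proband_sex = sexes,
    affected = TRUE
  )

  # --- trio allocation --------------------------------------------------
  n_inherit <- spec$n_de_novo + spec$n_ar_hom + spec$n_comp_het + spec$n_xlr
  alloc <- withr::with_seed(sub_seed(spec$seed, 2), {
    ord <- sample(trio_ids)
    males <- ord[sexes[match(ord, trio_ids)] == "male"]
    if (length(males) < spec$n_xlr) {
      abort("infeasible spec: not enough male probands for X-linked plants")
    }
    xlr <- males[seq_len(spec$n_xlr)]
    rest <- setdiff(ord, xlr)
    dn <- head(rest, spec$n_de_novo); rest <- setdiff(rest, dn)
    ar <- head(rest, spec$n_ar_hom); rest <- setdiff(rest, ar)
    ch <- head(rest, spec$n_comp_het); rest <- setdiff(rest, ch)
    if (!is.null(spec$burden_single)) {
      n_lof_single <- spec$burden_single - n_inherit
      lof_single <- head(rest, n_lof_single); rest <- setdiff(rest, lof_single)
      lof_multi <- head(rest, spec$burden_multiple)
      rest <- setdiff(rest, lof_multi)
      lof_trios <- c(lof_single, rep(lof_multi, each = 2))
    } else {
      pool <- setdiff(ord, c(xlr, dn, ar, ch))
      if (length(pool) == 0) pool <- ord
      lof_trios <- rep(pool, length.out = spec$n_chd_lof)
    }
    list(de_novo = dn, ar_hom = ar, comp_het = ch, xlr = xlr,
         lof_trios = lof_trios)
  })

  # --- genes ------------------------------------------------------------
  lof_genes <- sprintf("LOFG%04d", seq_len(spec$n_chd_lof_genes))
  filler_chd <- sprintf("CHDG%04d",
                        seq_len(spec$n_chd_genes - spec$n_chd_lof_genes))
  cand_genes <- c(
    if (spec$n_de_novo > 0) sprintf("DNVG%03d", seq_len(spec$n_de_novo)),
    if (spec$n_ar_hom > 0) sprintf("ARHG%03d", seq_len(spec$n_ar_hom)),
    if (spec$n_comp_het > 0) sprintf("CPHG%03d", seq_len(spec$n_comp_het)),
    if (spec$n_xlr > 0) sprintf("XLRG%03d", seq_len(spec$n_xlr))
  )
  bg_genes <- sprintf("BKGG%04d", seq_len(max(1, spec$n_background %/% 4)))

  cilia_flags <- c(rep(TRUE, spec$n_cilia_in_lof),
                   rep(FALSE, spec$n_chd_lof_genes - spec$n_cilia_in_lof),
                   rep(TRUE, spec$n_cilia_genes - spec$n_cilia_in_lof),
                   rep(FALSE, length(filler_chd) -
                         (spec$n_cilia_genes - spec$n_cilia_in_lof)))
  all_genes <- c(lof_genes, filler_chd, cand_genes, bg_genes)
  gene_resource <- withr::with_seed(sub_seed(spec$seed, 3), tibble(
    gene = all_genes,
    loeuf = round(runif(length(all_genes), 0.05, 1.6), 3),
    oe = NA_real_,
    is_chd_gene = c(rep(TRUE, spec$n_chd_genes),
                    rep(FALSE, length(cand_genes) + length(bg_genes))),
    is_cilia_gene = c(cilia_flags,
                      rep(FALSE, length(cand_genes) + length(bg_genes)))
  ) %>%
    mutate(oe = round(.data$loeuf * runif(length(all_genes), 0.5, 1.0), 3)))
  # a few missing constraint scores, as in real resources
  gene_resource$loeuf[seq(1, nrow(gene_resource), by = 97)] <- NA_real_
  gene_resource$oe[is.na(gene_resource$loeuf)] <- NA_real_

  # --- planted variant layout ------------------------------------------
  n_comp_vars <- 2L * spec$n_comp_het
  n_plant_auto <- spec$n_de_novo + spec$n_ar_hom + n_comp_vars +
    spec$n_chd_lof
  n_plant_x <- spec$n_xlr
  n_bg <- spec$n_background

  draws <- withr::with_seed(sub_seed(spec$seed, 4), {
    auto_pos <- sort(sample.int(99000000L, n_plant_auto + n_bg))
    x_pos <- sort(sample.int(150000000L, max(1, n_plant_x)))
    bases <- c("A", "C", "G", "T")
    nvar <- n_plant_auto + n_bg + n_plant_x
    ref <- sample(bases, nvar, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    list(auto_pos = auto_pos, x_pos = x_pos, ref = ref, alt = alt)
  })

  plant_rows <- list()
  ann_rows <- list()
  vi <- 0L  # index into ref/alt
  ai <- 0L  # index into autosomal positions
  xi <- 0L

  next_auto <- function() {
    ai <<- ai + 1L; vi <<- vi + 1L
    list(chrom = "chr1", pos = draws$auto_pos[ai],
         ref = draws$ref[vi], alt = draws$alt[vi])
  }
  next_x <- function() {
    xi <<- xi + 1L; vi <<- vi + 1L
    list(chrom = "chrX", pos = draws$x_pos[xi],
         ref = draws$ref[vi], alt = draws$alt[vi])
  }

  ann_values <- withr::with_seed(sub_seed(spec$seed, 5), {
    k <- n_plant_auto + n_plant_x + 10L
    list(
      af_missing = runif(k) < 0.5,
      af_rare = signif(runif(k, 1e-6, spec$af_threshold * 0.9), 3),
      cadd_dns = round(runif(k, 21, 38), 1),
      cadd_lof = round(runif(k, 15, 45), 1),
      cadd_lof_missing = runif(k) < 0.4,
      lof_cons = sample(c("stopgain", "frameshift", "splicing", "stoploss"),
                        k, replace = TRUE, prob = c(.35, .35, .2, .1)),
      db_present = runif(k) < 0.5,
      db_ac = sample(1:5, k, replace = TRUE),
      db_an = sample(18000:21000, k, replace = TRUE)
    )
  })

  pk <- 0L  # planted-variant counter, indexes ann_values
  add_plant <- function(mode, gene, loc, trio, p_gt, f_gt, m_gt,
                        consequence, cadd) {
    pk <<- pk + 1L
    af <- if (ann_values$af_missing[pk]) NA_real_ else ann_values$af_rare[pk]
    plant_rows[[length(plant_rows) + 1L]] <<- tibble(
      trio_id = trio, mode = mode, gene = gene, chrom = loc$chrom,
      pos = loc$pos, ref = loc$ref, alt = loc$alt,
      proband_gt = p_gt, father_gt = f_gt, mother_gt = m_gt
    )
    ann_rows[[length(ann_rows) + 1L]] <<- tibble(
      chrom = loc$chrom, pos = loc$pos, ref = loc$ref, alt = loc$alt,
      gene = gene,
      transcript = paste0("NM_", sprintf("%06d", 100000 + pk)),
      hgvs_c = paste0("c.", loc$pos %% 10000 + 1, loc$ref, ">", loc$alt),
      hgvs_p = paste0("p.V", pk, "M"),
      consequence = consequence, af_ref = af, cadd = cadd,
      db_present = ann_values$db_present[pk],
      db_ac = ann_values$db_ac[pk], db_an = ann_values$db_an[pk]
    )
  }

  for (t in alloc$de_novo) {
    add_plant("DE_NOVO", cand_genes[grepl("^DNVG", cand_genes)][
      match(t, alloc$de_novo)], next_auto(), t,
      "0/1", "0/0", "0/0", "missense", ann_values$cadd_dns[pk + 1L])
  }
  for (t in alloc$ar_hom) {
    add_plant("AR_HOMOZYGOUS", cand_genes[grepl("^ARHG", cand_genes)][
      match(t, alloc$ar_hom)], next_auto(), t,
      "1/1", "0/1", "0/1", "missense", ann_values$cadd_dns[pk + 1L])
  }
  for (t in alloc$comp_het) {
    g <- cand_genes[grepl("^CPHG", cand_genes)][match(t, alloc$comp_het)]
    add_plant("COMPOUND_HET", g, next_auto(), t,
              "0/1", "0/0", "0/1", "missense", ann_values$cadd_dns[pk + 1L])
    add_plant("COMPOUND_HET", g, next_auto(), t,
              "0/1", "0/1", "0/0", "missense", ann_values$cadd_dns[pk + 1L])
  }
  for (t in alloc$xlr) {
    add_plant("X_LINKED_RECESSIVE", cand_genes[grepl("^XLRG", cand_genes)][
      match(t, alloc$xlr)], next_x(), t,
      "1", "0", "0/1", "missense", ann_values$cadd_dns[pk + 1L])
  }
  if (spec$n_chd_lof > 0) {
    lof_gene_seq <- lof_genes[((seq_len(spec$n_chd_lof) - 1L) %%
                                 spec$n_chd_lof_genes) + 1L]
    for (j in seq_len(spec$n_chd_lof)) {
      from_father <- j %% 2L == 0L
      cadd <- if (ann_values$cadd_lof_missing[pk + 1L]) NA_real_ else
        ann_values$cadd_lof[pk + 1L]
      add_plant("CHD_LOF", lof_gene_seq[j], next_auto(),
                alloc$lof_trios[j], "0/1",
                if (from_father) "0/1" else "0/0",
                if (from_father) "0/0" else "0/1",
                ann_values$lof_cons[pk + 1L], cadd)
    }
  }
  plants <- bind_rows(plant_rows)
  plant_ann <- bind_rows(ann_rows)

  # --- background common variants --------------------------------------
  bg <- withr::with_seed(sub_seed(spec$seed, 6), {
    if (n_bg == 0) return(NULL)
    idx <- seq_len(n_bg)
    pos <- draws$auto_pos[ai + idx]
    ref <- draws$ref[vi + idx]
    alt <- draws$alt[vi + idx]
    af <- signif(runif(n_bg, spec$af_threshold * 1.5, 0.5), 3)
    list(ann = tibble(
      chrom = "chr1", pos = pos, ref = ref, alt = alt,
      gene = sample(bg_genes, n_bg, replace = TRUE),
      transcript = paste0("NM_", sprintf("%06d", 900000 + idx)),
      hgvs_c = paste0("c.", idx, ref, ">", alt),
      hgvs_p = "p.=",
      consequence = sample(c("synonymous", "missense", "other"), n_bg,
                           replace = TRUE, prob = c(.5, .3, .2)),
      af_ref = af,
      cadd = round(runif(n_bg, 0, 12), 1),
      db_present = TRUE,
      db_ac = pmax(1L, as.integer(af * 20000)),
      db_an = 20000L
    ), af = af)
  })

  # --- genotype grid ----------------------------------------------------
  annotation <- bind_rows(plant_ann, if (!is.null(bg)) bg$ann)
  variants <- annotation %>% select("chrom", "pos", "ref", "alt")

  plant_key <- paste(plants$chrom, plants$pos, plants$ref, plants$alt,
                     sep = "\r")
  var_key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt,
                   sep = "\r")

  geno <- withr::with_seed(sub_seed(spec$seed, 7), {
    purrr::map(seq_len(nrow(variants)), function(i) {
      v <- variants[i, ]
      on_x <- is_x_chrom(v$chrom)
      p_gt <- ifelse(on_x & sexes == "male", "0", "0/0")
      f_gt <- if (on_x) rep("0", n) else rep("0/0", n)
      m_gt <- rep("0/0", n)
      j <- match(var_key[i], plant_key)
      if (!is.na(j)) {
        hit <- which(plant_key == var_key[i])
        for (h in hit) {
          ti <- match(plants$trio_id[h], trio_ids)
          p_gt[ti] <- plants$proband_gt[h]
          f_gt[ti] <- plants$father_gt[h]
          m_gt[ti] <- plants$mother_gt[h]
        }
      } else {
        # background: Mendelian-consistent draws at the population frequency
        af <- bg$af[i - nrow(plant_ann)]
        fd <- stats::rbinom(n, 2, af)
        md <- stats::rbinom(n, 2, af)
        tf <- stats::rbinom(n, 1, fd / 2)   # transmitted paternal allele
        tm <- stats::rbinom(n, 1, md / 2)
        p_gt <- gt_string(tf + tm, 2L)
        f_gt <- gt_string(fd, 2L)
        m_gt <- gt_string(md, 2L)
      }
      dp <- matrix(sample(spec$depth_range[1]:spec$depth_range[2], 3L * n,
                          replace = TRUE), ncol = 3)
      tibble(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
             trio_id = trio_ids,
             proband_gt = p_gt, father_gt = f_gt, mother_gt = m_gt,
             proband_dp = dp[, 1], father_dp = dp[, 2], mother_dp = dp[, 3],
             proband_sex = sexes)
    }) %>% bind_rows()
  })
  geno <- arrange(geno, .data$chrom, .data$pos, .data$alt, .data$trio_id)

  # --- reference-database counts ---------------------------------------
  ref_counts <- annotation %>%
    filter(.data$db_present) %>%
    mutate(db_name = "gnomad_eas") %>%
    select("chrom", "pos", "ref", "alt", "db_name",
           ac = "db_ac", an = "db_an")
  annotation <- select(annotation, -"db_present", -"db_ac", -"db_an")

  # --- phenotypes (deterministic margins) -------------------------------
  phen <- tibble(trio_id = trio_ids)
  counts <- spec$phenotype_counts
  for (k in seq_along(counts)) {
    flags <- rep(FALSE, n)
    cnt <- counts[[k]]
    if (cnt > 0) {
      idx <- ((k - 1L + seq_len(cnt) - 1L) %% n) + 1L
      flags[idx] <- TRUE
    }
    phen[[names(counts)[k]]] <- flags
  }

  truth <- plants %>%
    select("trio_id", "mode", "gene", "chrom", "pos", "ref", "alt") %>%
    arrange(.data$chrom, .data$pos, .data$alt, .data$trio_id)

  structure(list(pedigree = pedigree, genotypes = geno,
                 annotation = annotation, gene_resource = gene_resource,
                 ref_counts = ref_counts, phenotypes = phen,
                 truth = truth, spec = spec),
            class = "trio_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Emits the cohort as the file formats the pipeline reads: a multi-sample
#' VCF, a 6-column PED, tab-separated annotation, gene-resource,
#' reference-count, phenotype and truth tables. All writers emit UTF-8
#' with LF line endings; repeated writes of the same cohort are
#' byte-identical.
#'
#' @param cohort A `trio_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_trio_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             ped = file.path(dir, "cohort.ped"),
             annotation = file.path(dir, "annotation.tsv"),
             gene_resource = file.path(dir, "gene_resource.tsv"),
             ref_counts = file.path(dir, "ref_counts.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_cohort_vcf(cohort$genotypes, cohort$pedigree, paths["vcf"])
  write_pedigree(cohort$pedigree, paths["ped"])
  write_annotation_table(cohort$annotation, paths["annotation"])
  write_gene_resource(cohort$gene_resource, paths["gene_resource"])
  readr::write_tsv(setNames(cohort$ref_counts,
                            c("CHROM", "POS", "REF", "ALT", "DB_NAME",
                              "AC", "AN")),
                   paths["ref_counts"], progress = FALSE)
  readr::write_tsv(cohort$phenotypes, paths["phenotypes"], progress = FALSE)
  readr::write_tsv(setNames(cohort$truth,
                            c("TRIO", "MODE", "GENE", "CHROM", "POS",
                              "REF", "ALT")),
                   paths["truth"], progress = FALSE)
  invisible(paths)
}

#' Degrade a synthetic cohort with genotype noise
#'
#' Reproducibly perturbs a generated cohort to stress-test the filter and
#' classification stages: random genotype dropout, depth collapse below
#' typical filter settings, and injected Mendelian inconsistencies (the
#' proband made homozygous alternate while both parents are made
#' homozygous reference). Mendelian errors are injected only at planted
#' variant records, which are the records that reach classification. A
#' sidecar log lists every perturbed cell.
#'
#' @param cohort A `trio_cohort`.
#' @param missing_gt_rate Per (record, member) probability of genotype
#'   dropout.
#' @param low_depth_rate Per record probability of collapsing all three
#'   depths below `low_depth_below`.
#' @param mendelian_error_rate Per planted-record probability of a
#'   Mendelian inconsistency.
#' @param seed Seed for the perturbation stream.
#' @param low_depth_below Depths are redrawn in `[0, low_depth_below)`
#'   (default 8).
#' @return The degraded cohort; the perturbation log is in element
#'   `degrade_log` (columns `kind`, `chrom`, `pos`, `ref`, `alt`,
#'   `trio_id`, `member`).
#' @export
degrade_cohort <- function(cohort, missing_gt_rate = 0, low_depth_rate = 0,
                           mendelian_error_rate = 0, seed = 1L,
                           low_depth_below = 8L) {
  stopifnot(missing_gt_rate >= 0, missing_gt_rate <= 1,
            low_depth_rate >= 0, low_depth_rate <= 1,
            mendelian_error_rate >= 0, mendelian_error_rate <= 1)
  g <- cohort$genotypes
  log_rows <- list()
  push_log <- function(kind, rows, member) {
    if (length(rows) == 0) return()
    log_rows[[length(log_rows) + 1L]] <<- tibble(
      kind = kind, chrom = g$chrom[rows], pos = g$pos[rows],
      ref = g$ref[rows], alt = g$alt[rows], trio_id = g$trio_id[rows],
      member = member
    )
  }
  withr::with_seed(as.integer(seed), {
    if (missing_gt_rate > 0) {
      for (member in c("proband", "father", "mother")) {
        col <- paste0(member, "_gt")
        hit <- which(runif(nrow(g)) < missing_gt_rate)
        g[[col]][hit] <- NA_character_
        push_log("missing_gt", hit, member)
      }
    }
    if (low_depth_rate > 0) {
      hit <- which(runif(nrow(g)) < low_depth_rate)
      for (member in c("proband", "father", "mother")) {
        col <- paste0(member, "_dp")
        g[[col]][hit] <- sample.int(low_depth_below, length(hit),
                                    replace = TRUE) - 1L
      }
      push_log("low_depth", hit, "all")
    }
    if (mendelian_error_rate > 0) {
      tk <- paste(cohort$truth$chrom, cohort$truth$pos, cohort$truth$ref,
                  cohort$truth$alt, cohort$truth$trio_id, sep = "\r")
      gk <- paste(g$chrom, g$pos, g$ref, g$alt, g$trio_id, sep = "\r")
      planted <- which(gk %in% tk)
      hit <- planted[runif(length(planted)) < mendelian_error_rate]
      male_x <- is_x_chrom(g$chrom[hit]) & g$proband_sex[hit] == "male"
      fem_x <- is_x_chrom(g$chrom[hit]) & !male_x
      # conflicting pattern per chromosome context: proband all-alt with
      # parents who cannot have supplied the allele
      g$proband_gt[hit] <- ifelse(male_x, "1", "1/1")
      g$father_gt[hit] <- ifelse(male_x, "1", ifelse(fem_x, "0", "0/0"))
      g$mother_gt[hit] <- "0/0"
      push_log("mendelian_error", hit, "trio")
    }
  })
  cohort$genotypes <- g
  cohort$degrade_log <- if (length(log_rows)) bind_rows(log_rows) else
    tibble(kind = character(), chrom = character(), pos = integer(),
           ref = character(), alt = character(), trio_id = character(),
           member = character())
  cohort
}

#' Disease gene-list fixture with the published marginal counts
#'
#' Builds, in code, a synthetic stand-in for a 1786-gene congenital heart
#' disease gene list with 134 cilia-flagged members — the marginal counts
#' of the published list, with synthetic symbols. Deterministic.
#'
#' @param n_genes,n_cilia List size and number of cilia flags.
#' @return A gene-resource tibble.
#' @export
chd_gene_fixture <- function(n_genes = 1786L, n_cilia = 134L) {
  withr::with_seed(20260101L, tibble(
    gene = sprintf("CHDG%04d", seq_len(n_genes)),
    loeuf = round(runif(n_genes, 0.05, 1.6), 3),
    oe = round(runif(n_genes, 0.05, 1.2), 3),
    is_chd_gene = TRUE,
    is_cilia_gene = seq_len(n_genes) <= n_cilia
  ))
}
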