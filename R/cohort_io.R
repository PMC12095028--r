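#' Read a six-column pedigree (PED) file
#'
#' Parses the standard whitespace-separated PED format (family, individual,
#' father, mother, sex, phenotype) and extracts one row per family trio.
#' Rows whose father and mother fields are both `"0"` are founders and
#' contribute only their own ids; every non-founder row defines a proband.
#'
#' @param path Path to a PED file (6 whitespace-separated columns; sex coded
#'   1 = male, 2 = female; phenotype coded 2 = affected).
#' @return A tibble with columns `trio_id`, `proband_id`, `father_id`,
#'   `mother_id`, `proband_sex` (`"male"`/`"female"`) and `affected`.
#' @export
read_pedigree <- function(path) {
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           col.names = c("family", "individual", "father",
                                         "mother", "sex", "phenotype"))
  probands <- raw[raw$father != "0" & raw$mother != "0", , drop = FALSE]
  ped <- tibble(
    trio_id = probands$family,
    proband_id = probands$individual,
    father_id = probands$father,
    mother_id = probands$mother,
    proband_sex = ifelse(probands$sex == "1", "male", "female"),
    affected = probands$phenotype == "2"
  )
  bad <- ped$proband_id == ped$father_id | ped$proband_id == ped$mother_id |
    ped$father_id == ped$mother_id
  if (any(bad)) {
    abort(paste0("pedigree trio(s) with non-distinct member ids: ",
                 paste(ped$trio_id[bad], collapse = ", ")))
  }
  known <- raw$individual
  ref_ids <- unique(c(ped$father_id, ped$mother_id))
  if (!all(ref_ids %in% known)) {
    abort(paste0("pedigree references unknown individual(s): ",
                 paste(setdiff(ref_ids, known), collapse = ", ")))
  }
  ped
}

#' @rdname read_pedigree
#' @param pedigree A pedigree tibble as returned by [read_pedigree()].
#' @export
write_pedigree <- function(pedigree, path) {
  founders <- unique(c(pedigree$father_id, pedigree$mother_id))
  founder_sex <- ifelse(founders %in% pedigree$father_id, "1", "2")
  # founder family ids must match their trio's family id
  fam_of <- c(setNames(pedigree$trio_id, pedigree$father_id),
              setNames(pedigree$trio_id, pedigree$mother_id))
  lines <- c(
    paste(fam_of[founders], founders, "0", "0", founder_sex, "1", sep = "\t"),
    paste(pedigree$trio_id, pedigree$proband_id, pedigree$father_id,
          pedigree$mother_id, ifelse(pedigree$proband_sex == "male", "1", "2"),
          ifelse(pedigree$affected, "2", "1"), sep = "\t")
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a joint cohort VCF into per-trio genotype records
#'
#' Reads a multi-sample VCF (4.x, with `GT` and optionally `DP` FORMAT
#' fields), splits multi-allelic sites into one record per alternate allele,
#' and returns one row per (site, alternate allele, trio). When splitting,
#' alleles equal to the record's alternate count as carried and every other
#' called allele (reference or a different alternate) as not carried, so
#' allele observations are conserved across the split records.
#'
#' Male genotypes on the X chromosome are normalized to ploidy 1
#' (`"0"`/`"1"`); a diploid-written heterozygous male X call cannot be
#' haploidized and becomes missing, with a warning. Pseudoautosomal regions
#' are not modeled.
#'
#' @param path Path to a VCF file.
#' @param pedigree Pedigree tibble from [read_pedigree()]; all member ids
#'   must be present as VCF sample columns (fatal otherwise).
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `trio_id`,
#'   `proband_gt`, `father_gt`, `mother_gt`, `proband_dp`, `father_dp`,
#'   `mother_dp`, `proband_sex`.
#' @export
read_cohort_vcf <- function(path, pedigree) {
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  empty <- tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), trio_id = character(),
    proband_gt = character(), father_gt = character(), mother_gt = character(),
    proband_dp = integer(), father_dp = integer(), mother_dp = integer(),
    proband_sex = character()
  )
  if (nrow(vcf@fix) == 0) return(empty)

  samples <- colnames(vcf@gt)[-1]
  need <- unique(c(pedigree$proband_id, pedigree$father_id, pedigree$mother_id))
  absent <- setdiff(need, samples)
  if (length(absent)) {
    abort(paste0("pedigree sample id(s) missing from VCF: ",
                 paste(absent, collapse = ", ")))
  }

  GT <- vcfR::extract.gt(vcf, element = "GT")
  DP <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP",
                                          as.numeric = TRUE))
  if (is.null(dim(GT))) GT <- matrix(GT, nrow = nrow(vcf@fix),
                                     dimnames = list(NULL, samples))
  if (is.null(DP) || is.null(dim(DP))) {
    DP <- matrix(NA_real_, nrow = nrow(GT), ncol = ncol(GT),
                 dimnames = dimnames(GT))
  }

  fix <- vcf@fix
  alts_per_site <- strsplit(fix[, "ALT"], ",", fixed = TRUE)

  recs <- vector("list", sum(lengths(alts_per_site)))
  ri <- 0L
  for (i in seq_len(nrow(fix))) {
    for (k in seq_along(alts_per_site[[i]])) {
      dosage <- setNames(recode_gt_dosage(GT[i, ], k), samples)
      ploidy <- setNames(raw_gt_ploidy(GT[i, ]), samples)
      ri <- ri + 1L
      recs[[ri]] <- list(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts_per_site[[i]][k],
        dosage = dosage, ploidy = ploidy, dp = DP[i, ]
      )
    }
  }

  n_het_male_x <- 0L
  rows <- purrr::map(recs, function(r) {
    on_x <- is_x_chrom(r$chrom)
    per_member <- function(ids, male) {
      d <- r$dosage[ids]
      p <- r$ploidy[ids]
      male <- rep_len(male, length(d))
      if (on_x && any(male)) {
        # haploidize males: diploid hom -> single allele; diploid het ->
        # missing (cannot be het on a haploid chromosome)
        het <- male & !is.na(d) & !is.na(p) & p == 2L & d == 1L
        n_het_male_x <<- n_het_male_x + sum(het)
        d[het] <- NA_integer_
        hom <- male & !is.na(d) & d == 2L
        d[hom] <- 1L
        out <- gt_string(d, 2L)
        out[male] <- gt_string(d[male], 1L)
        out
      } else {
        gt_string(d, 2L)
      }
    }
    tibble(
      chrom = r$chrom, pos = r$pos, ref = r$ref, alt = r$alt,
      trio_id = pedigree$trio_id,
      proband_gt = per_member(pedigree$proband_id,
                              pedigree$proband_sex == "male"),
      father_gt = per_member(pedigree$father_id, TRUE),
      mother_gt = per_member(pedigree$mother_id, FALSE),
      proband_dp = as.integer(r$dp[pedigree$proband_id]),
      father_dp = as.integer(r$dp[pedigree$father_id]),
      mother_dp = as.integer(r$dp[pedigree$mother_id]),
      proband_sex = pedigree$proband_sex
    )
  })
  if (n_het_male_x > 0) {
    warn(paste0(n_het_male_x, " diploid heterozygous male X genotype(s) ",
                "set to missing during haploidization"))
  }
  out <- bind_rows(rows)
  out$proband_gt[out$proband_gt %in% c("./.", ".")] <- NA_character_
  out$father_gt[out$father_gt %in% c("./.", ".")] <- NA_character_
  out$mother_gt[out$mother_gt %in% c("./.", ".")] <- NA_character_
  arrange(out, .data$chrom, .data$pos, .data$alt, .data$trio_id)
}

#' Write per-trio genotype records as a multi-sample VCF
#'
#' Inverse of [read_cohort_vcf()]: emits one VCF line per distinct
#' (chrom, pos, ref, alt) record with `GT:DP` columns for every pedigree
#' member, suitable for round-tripping synthetic cohorts. Output is VCF 4.2,
#' UTF-8, LF line endings, deterministic row and sample order.
#'
#' @param genotypes Genotype tibble as returned by [read_cohort_vcf()].
#' @param pedigree Pedigree tibble.
#' @param path Output path.
#' @export
write_cohort_vcf <- function(genotypes, pedigree, path) {
  sample_ids <- as.vector(rbind(pedigree$proband_id, pedigree$father_id,
                                pedigree$mother_id))
  sites <- genotypes %>%
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt) %>%
    arrange(.data$chrom, .data$pos, .data$alt)

  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = "\r")
  gsplit <- split(genotypes, key(genotypes))

  fmt_gt <- function(gt, dp) {
    g <- ifelse(is.na(gt), "./.", gt)
    d <- ifelse(is.na(dp), ".", as.character(dp))
    paste0(g, ":", d)
  }
  body <- vapply(seq_len(nrow(sites)), function(i) {
    g <- gsplit[[key(sites[i, ])]]
    g <- g[match(pedigree$trio_id, g$trio_id), , drop = FALSE]
    cells <- as.vector(rbind(fmt_gt(g$proband_gt, g$proband_dp),
                             fmt_gt(g$father_gt, g$father_dp),
                             fmt_gt(g$mother_gt, g$mother_dp)))
    paste(c(sites$chrom[i], sites$pos[i], ".", sites$ref[i], sites$alt[i],
            ".", "PASS", ".", "GT:DP", cells), collapse = "\t")
  }, character(1))

  contigs <- unique(sites$chrom)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=trioprio",
    paste0("##contig=<ID=", contigs, ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read a variant annotation table
#'
#' Consumes the tab-separated per-allele annotation shape produced by a
#' standard exome annotation run: one row per normalized
#' (chrom, pos, ref, alt) with gene, transcript, coding/protein change,
#' consequence class, reference-population allele frequency and a
#' PHRED-scaled deleteriousness (CADD) score. Empty frequency or CADD cells
#' mean missing, which is distinct from zero. Duplicate keys keep the last
#' row, with a warning.
#'
#' @param path Path to a tab-separated table with header columns `CHROM`,
#'   `POS`, `REF`, `ALT`, `GENE`, `TRANSCRIPT`, `HGVS_C`, `HGVS_P`,
#'   `CONSEQUENCE`, the frequency column named by `af_column`, and `CADD`.
#' @param af_column Name of the reference-population allele-frequency column
#'   used for rarity (default `"AF_EAS"`, the East Asian frequency).
#' @return A tibble keyed by `chrom`, `pos`, `ref`, `alt` with columns
#'   `gene`, `transcript`, `hgvs_c`, `hgvs_p`, `consequence`, `af_ref`,
#'   `cadd`.
#' @export
read_annotation_table <- function(path, af_column = "AF_EAS") {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("CHROM", "POS", "REF", "ALT", "GENE", "TRANSCRIPT",
                "HGVS_C", "HGVS_P", "CONSEQUENCE", af_column, "CADD")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    abort(paste0("annotation table missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  num_or_na <- function(x) {
    x[x %in% c("", ".", "-", "—", "NA")] <- NA_character_
    suppressWarnings(as.numeric(x))
  }
  out <- tibble(
    chrom = tab$CHROM,
    pos = as.integer(tab$POS),
    ref = tab$REF,
    alt = tab$ALT,
    gene = tab$GENE,
    transcript = tab$TRANSCRIPT,
    hgvs_c = tab$HGVS_C,
    hgvs_p = tab$HGVS_P,
    consequence = tolower(tab$CONSEQUENCE),
    af_ref = num_or_na(tab[[af_column]]),
    cadd = num_or_na(tab$CADD)
  )
  k <- paste(out$chrom, out$pos, out$ref, out$alt, sep = "\r")
  if (anyDuplicated(k)) {
    warn(paste0(sum(duplicated(k)), " duplicate annotation key(s); ",
                "keeping the last row for each"))
    out <- out[!duplicated(k, fromLast = TRUE), , drop = FALSE]
  }
  out
}

#' @rdname read_annotation_table
#' @param annotation Annotation tibble to write.
#' @export
write_annotation_table <- function(annotation, path, af_column = "AF_EAS") {
  fmt <- function(x) ifelse(is.na(x), "", as.character(x))
  tab <- tibble(
    CHROM = annotation$chrom, POS = annotation$pos, REF = annotation$ref,
    ALT = annotation$alt, GENE = annotation$gene,
    TRANSCRIPT = annotation$transcript, HGVS_C = annotation$hgvs_c,
    HGVS_P = annotation$hgvs_p, CONSEQUENCE = annotation$consequence,
    AF = fmt(annotation$af_ref), CADD = fmt(annotation$cadd)
  )
  names(tab)[names(tab) == "AF"] <- af_column
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read a gene resource table
#'
#' The gene resource carries per-gene loss-of-function constraint scores
#' (LOEUF and observed/expected) and two membership flags: whether the gene
#' is on the configured disease (CHD) gene list and whether it is annotated
#' as cilia-related. Symbols are upper-cased; one row per symbol.
#'
#' @param path Tab-separated table with columns `GENE`, `LOEUF`, `OE`,
#'   `CHD_FLAG`, `CILIA_FLAG`. Empty score cells mean missing; flags are 0/1.
#' @return A tibble with columns `gene`, `loeuf`, `oe`, `is_chd_gene`,
#'   `is_cilia_gene`.
#' @export
read_gene_resource <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("GENE", "LOEUF", "OE", "CHD_FLAG", "CILIA_FLAG")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    abort(paste0("gene resource missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  parse_score <- function(x, what) {
    blank <- x %in% c("", ".", "NA") | is.na(x)
    val <- suppressWarnings(as.numeric(x))
    bad <- which(!blank & is.na(val))
    if (length(bad)) {
      abort(paste0("non-numeric ", what, " at row(s) ",
                   paste(head(bad, 5), collapse = ", "), ": '",
                   x[bad[1]], "'"))
    }
    val[blank] <- NA_real_
    val
  }
  out <- tibble(
    gene = toupper(tab$GENE),
    loeuf = parse_score(tab$LOEUF, "LOEUF"),
    oe = parse_score(tab$OE, "OE"),
    is_chd_gene = tab$CHD_FLAG == "1",
    is_cilia_gene = tab$CILIA_FLAG == "1"
  )
  out[!duplicated(out$gene, fromLast = TRUE), , drop = FALSE]
}

#' @rdname read_gene_resource
#' @param resource Gene resource tibble to write.
#' @export
write_gene_resource <- function(resource, path) {
  fmt <- function(x) ifelse(is.na(x), "", as.character(x))
  readr::write_tsv(tibble(
    GENE = resource$gene, LOEUF = fmt(resource$loeuf), OE = fmt(resource$oe),
    CHD_FLAG = as.integer(resource$is_chd_gene),
    CILIA_FLAG = as.integer(resource$is_cilia_gene)
  ), path, progress = FALSE)
  invisible(path)
}

# Display names for inheritance modes, mirroring the candidate-table shape.
mode_label <- function(mode) {
  c(DE_NOVO = "de novo",
    AR_HOMOZYGOUS = "AR homozygous",
    COMPOUND_HET = "compound heterozygous",
    X_LINKED_RECESSIVE = "X-linked recessive",
    CHD_LOF = "CHD-LOF")[mode]
}

#' Write the candidate-variant table
#'
#' Emits the tab-separated candidate table: one row per called variant with
#' its gene, position, coding change, consequence, frequency, CADD,
#' inheritance mode, five-tier classification and evidence codes, plus the
#' trio genotypes that support the call. Row order is deterministic
#' (chrom, pos, alt, trio).
#'
#' @param calls Inheritance-call tibble from [classify_cohort()], optionally
#'   augmented with `acmg_class` and `evidence` columns.
#' @param path Output path.
#' @export
write_candidate_table <- function(calls, path) {
  cols <- c("Gene", "Position", "Variant", "Category", "AF", "CADD", "Mode",
            "ACMG class", "Evidence", "Proband GT", "Father GT", "Mother GT")
  if (nrow(calls) == 0) {
    writeLines(paste(cols, collapse = "\t"), path, useBytes = TRUE)
    return(invisible(path))
  }
  get0c <- function(nm, default = "") {
    if (nm %in% names(calls)) {
      x <- calls[[nm]]
      ifelse(is.na(x), "", as.character(x))
    } else rep(default, nrow(calls))
  }
  variant <- paste(get0c("transcript"), get0c("hgvs_c"), get0c("hgvs_p"),
                   sep = ":")
  variant <- sub(":+$", "", variant)
  out <- tibble(
    Gene = calls$gene,
    Position = paste0(calls$chrom, ":", calls$pos),
    Variant = variant,
    Category = get0c("consequence"),
    AF = get0c("af_ref"),
    CADD = get0c("cadd"),
    Mode = mode_label(calls$mode),
    `ACMG class` = get0c("acmg_class"),
    Evidence = get0c("evidence"),
    `Proband GT` = get0c("proband_gt"),
    `Father GT` = get0c("father_gt"),
    `Mother GT` = get0c("mother_gt"),
    .chrom = calls$chrom, .pos = calls$pos, .alt = calls$alt,
    .trio = calls$trio_id
  ) %>%
    arrange(.data$.chrom, .data$.pos, .data$.alt, .data$.trio) %>%
    select(-".chrom", -".pos", -".alt", -".trio")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
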