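# Small builders shared across test files. Everything is generated in code;
# no fixture files.

# One genotype row with sensible defaults, overridable per field.
gt_row <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                   trio_id = "T001", proband_gt = "0/1",
                   father_gt = "0/0", mother_gt = "0/0",
                   proband_dp = 30L, father_dp = 30L, mother_dp = 30L,
                   proband_sex = "male") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 trio_id = trio_id, proband_gt = proband_gt,
                 father_gt = father_gt, mother_gt = mother_gt,
                 proband_dp = as.integer(proband_dp),
                 father_dp = as.integer(father_dp),
                 mother_dp = as.integer(mother_dp),
                 proband_sex = proband_sex)
}

# One annotation row.
ann_row <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                    gene = "GENE1", consequence = "missense",
                    af_ref = NA_real_, cadd = 25) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 gene = gene, transcript = "NM_000001",
                 hgvs_c = "c.1A>T", hgvs_p = "p.K1*",
                 consequence = consequence, af_ref = af_ref, cadd = cadd)
}

# A minimal gene resource.
resource_tbl <- function(genes, chd = TRUE, cilia = FALSE, loeuf = 0.5,
                         oe = 0.4) {
  tibble::tibble(gene = toupper(genes),
                 loeuf = rep_len(loeuf, length(genes)),
                 oe = rep_len(oe, length(genes)),
                 is_chd_gene = rep_len(chd, length(genes)),
                 is_cilia_gene = rep_len(cilia, length(genes)))
}

# A small but complete synthetic spec exercising all four modes with
# burden-exact allocation: 4 inheritance trios + 2 single-LOF + 1 double-LOF
# trio -> 4 CHD-LOF variants in 3 genes; 1 trio with nothing.
small_spec <- function(seed, n_trios = 8L) {
  synthetic_spec(seed = seed, n_trios = n_trios, male_fraction = 0.5,
                 n_de_novo = 1L, n_ar_hom = 1L, n_comp_het = 1L, n_xlr = 1L,
                 n_chd_lof = 4L, n_chd_lof_genes = 3L, n_cilia_in_lof = 1L,
                 n_chd_genes = 10L, n_cilia_genes = 3L, n_background = 20L,
                 burden_single = 6L, burden_multiple = 1L,
                 phenotype_counts = c(dextrocardia = 3L, asd = 5L))
}

# Write a VCF from raw lines with a standard header.
write_test_vcf <- function(body, samples, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##contig=<ID=chrX>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  path
}

# Pedigree for a single test trio.
one_trio_ped <- function(sex = "male") {
  tibble::tibble(trio_id = "T001", proband_id = "P1", father_id = "F1",
                 mother_id = "M1", proband_sex = sex, affected = TRUE)
}

# An empty call tibble with the columns the writers expect.
call_row_prototype_for_test <- function() {
  tibble::tibble(call_id = character(), trio_id = character(),
                 gene = character(), mode = character(), chrom = character(),
                 pos = integer(), ref = character(), alt = character(),
                 parental_origin = character())
}

# The call identity used for truth-table comparisons.
call_key <- function(d) {
  sort(paste(d$trio_id, d$mode, toupper(d$gene), d$chrom, d$pos, d$ref,
             d$alt, sep = "|"))
}
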