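test_that("multi-allelic sites split into one record per alt and conserve alleles", {
  ped <- one_trio_ped()
  vcf <- write_test_vcf(
    "chr1\t500\t.\tA\tT,G\t.\tPASS\t.\tGT:DP\t1/2:30\t0/1:25\t0/2:40",
    samples = c("P1", "F1", "M1")
  )
  g <- read_cohort_vcf(vcf, ped)
  expect_equal(nrow(g), 2)
  expect_setequal(g$alt, c("T", "G"))
  # proband 1/2 -> one alt allele against each record; other-alt counts as 0
  expect_equal(sort(g$proband_gt), c("0/1", "0/1"))
  # total alt dosage across split records equals the site's non-ref count
  expect_equal(sum(gt_dosage(g$proband_gt)), 2)
  expect_equal(sum(gt_dosage(g$father_gt)), 1)
  expect_equal(sum(gt_dosage(g$mother_gt)), 1)
})

test_that("male X genotypes are normalized to ploidy 1", {
  ped <- one_trio_ped(sex = "male")
  vcf <- write_test_vcf(
    c("chrX\t1000\t.\tC\tT\t.\tPASS\t.\tGT:DP\t1:30\t0:25\t0/1:40",
      "chrX\t2000\t.\tG\tA\t.\tPASS\t.\tGT:DP\t1/1:30\t0/0:25\t0/0:40"),
    samples = c("P1", "F1", "M1")
  )
  g <- read_cohort_vcf(vcf, ped)
  expect_equal(g$proband_gt[g$pos == 1000], "1")
  expect_equal(g$father_gt[g$pos == 1000], "0")
  expect_equal(g$mother_gt[g$pos == 1000], "0/1")
  # diploid-written male hom calls haploidize
  expect_equal(g$proband_gt[g$pos == 2000], "1")
  expect_equal(g$father_gt[g$pos == 2000], "0")
  expect_true(all(gt_ploidy(g$proband_gt) == 1))
})

test_that("diploid heterozygous male X calls become missing, never het", {
  ped <- one_trio_ped(sex = "male")
  vcf <- write_test_vcf(
    "chrX\t1000\t.\tC\tT\t.\tPASS\t.\tGT:DP\t0/1:30\t0:25\t0/1:40",
    samples = c("P1", "F1", "M1")
  )
  expect_warning(g <- read_cohort_vcf(vcf, ped), "haploidization")
  expect_true(is.na(g$proband_gt))
})

test_that("empty VCF body yields an empty record set without error", {
  ped <- one_trio_ped()
  vcf <- write_test_vcf(character(0), samples = c("P1", "F1", "M1"))
  g <- read_cohort_vcf(vcf, ped)
  expect_equal(nrow(g), 0)
  expect_true(all(c("chrom", "pos", "proband_gt") %in% names(g)))
})

test_that("a pedigree sample missing from the VCF is fatal", {
  ped <- one_trio_ped()
  vcf <- write_test_vcf(
    "chr1\t500\t.\tA\tT\t.\tPASS\t.\tGT:DP\t0/1:30\t0/0:25\t0/0:40",
    samples = c("P1", "F1", "OTHER")
  )
  expect_error(read_cohort_vcf(vcf, ped), "M1")
})

test_that("annotation table parses frequencies, missing cells and duplicates", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "CHROM\tPOS\tREF\tALT\tGENE\tTRANSCRIPT\tHGVS_C\tHGVS_P\tCONSEQUENCE\tAF_EAS\tCADD",
    "chr17\t7726926\tC\tT\tDNAH2\tNM_020877\tc.C11309T\tp.P3770L\tmissense\t5.01E-05\t26.5",
    "chrX\t153578474\tG\tA\tFLNA\tNM_001456\tc.G7234A\tp.V2412I\tmissense\t\t28.5",
    "chr17\t7726926\tC\tT\tDNAH2\tNM_020877\tc.C11309T\tp.P3770L\tmissense\t6.00E-05\t26.5"
  ), path)
  expect_warning(ann <- read_annotation_table(path), "duplicate")
  expect_equal(nrow(ann), 2)
  # duplicate key: last row wins
  expect_equal(ann$af_ref[ann$chrom == "chr17"], 6e-5)
  # empty AF cell means undocumented, not zero
  expect_true(is.na(ann$af_ref[ann$chrom == "chrX"]))
  expect_equal(ann$cadd[ann$chrom == "chrX"], 28.5)
})

test_that("annotation table with a missing mandatory column is fatal", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("CHROM\tPOS\tREF\tALT\tGENE", "chr1\t1\tA\tT\tG1"), path)
  expect_error(read_annotation_table(path), "CONSEQUENCE")
})

test_that("gene resource parses flags and rejects non-numeric scores", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("GENE\tLOEUF\tOE\tCHD_FLAG\tCILIA_FLAG",
               "dnah11\t0.31\t0.28\t1\t1",
               "OTHER\t\t\t0\t0"), path)
  res <- read_gene_resource(path)
  expect_equal(res$gene, c("DNAH11", "OTHER"))  # case-normalized
  expect_true(res$is_chd_gene[1] && res$is_cilia_gene[1])
  expect_true(is.na(res$loeuf[2]))

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("GENE\tLOEUF\tOE\tCHD_FLAG\tCILIA_FLAG",
               "G1\tlow\t0.2\t1\t0"), bad)
  expect_error(read_gene_resource(bad), "non-numeric LOEUF")
})

test_that("gene-list fixture realizes the published marginal counts", {
  res <- chd_gene_fixture()
  expect_equal(nrow(res), 1786)
  expect_equal(sum(res$is_cilia_gene), 134)
  # and round-trips through the resource format
  path <- tempfile(fileext = ".tsv")
  write_gene_resource(res, path)
  back <- read_gene_resource(path)
  expect_equal(as.data.frame(back), as.data.frame(res))
})

test_that("candidate table writer is deterministic and handles empty input", {
  empty <- tempfile()
  write_candidate_table(call_row_prototype_for_test(), empty)
  lines <- readLines(empty)
  expect_length(lines, 1)
  expect_match(lines, "^Gene\tPosition")

  calls <- tibble::tibble(
    call_id = "DE_NOVO/T001/DNAH2/chr17:7726926:T",
    trio_id = "T001", gene = "DNAH2", mode = "DE_NOVO",
    chrom = "chr17", pos = 7726926L, ref = "C", alt = "T",
    parental_origin = "neither", proband_gt = "0/1",
    father_gt = "0/0", mother_gt = "0/0",
    consequence = "missense", af_ref = 5.01e-5, cadd = 26.5,
    transcript = "NM_020877", hgvs_c = "c.C11309T", hgvs_p = "p.P3770L"
  )
  f1 <- tempfile(); f2 <- tempfile()
  write_candidate_table(calls, f1)
  write_candidate_table(calls, f2)
  expect_identical(readLines(f1), readLines(f2))
  row <- strsplit(readLines(f1)[2], "\t")[[1]]
  expect_equal(row[1], "DNAH2")
  expect_equal(row[2], "chr17:7726926")
  expect_equal(row[7], "de novo")
})

test_that("full cohort round-trip reproduces genotypes and annotations exactly", {
  co <- generate_cohort(small_spec(seed = 11))
  dir <- tempfile()
  paths <- write_trio_cohort(co, dir)
  ped <- read_pedigree(paths[["ped"]])
  expect_equal(as.data.frame(ped), as.data.frame(co$pedigree))
  g <- read_cohort_vcf(paths[["vcf"]], ped)
  want <- dplyr::arrange(co$genotypes, chrom, pos, alt, trio_id)
  expect_identical(as.data.frame(g), as.data.frame(want))
  ann <- dplyr::arrange(read_annotation_table(paths[["annotation"]]),
                        chrom, pos, alt)
  want_ann <- dplyr::arrange(co$annotation, chrom, pos, alt)
  expect_equal(as.data.frame(ann), as.data.frame(want_ann))
})
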