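#' Genotype string helpers
#'
#' Genotype calls are carried as canonical strings: `"0/0"`, `"0/1"`, `"1/1"`
#' for diploid calls and `"0"`, `"1"` for haploid (male X) calls, with `NA`
#' for missing. These helpers convert between strings and allele dosages.
#'
#' @param gt Character vector of genotype strings.
#' @return `gt_dosage()`: integer count of alternate alleles (`NA` for
#'   missing); `gt_ploidy()`: integer 1 or 2 (`NA` for missing).
#' @examples
#' gt_dosage(c("0/0", "0/1", "1/1", "1", NA))
#' gt_ploidy(c("0/1", "1", NA))
#' @export
gt_dosage <- function(gt) {
  alleles <- strsplit(gt, "[/|]")
  vapply(seq_along(alleles), function(i) {
    a <- alleles[[i]]
    if (length(a) == 0 || is.na(gt[i]) || any(a == ".")) return(NA_integer_)
    if (!all(a %in% c("0", "1"))) return(NA_integer_)
    sum(a == "1")
  }, integer(1))
}

#' @rdname gt_dosage
#' @export
gt_ploidy <- function(gt) {
  n <- lengths(strsplit(gt, "[/|]"))
  n[is.na(gt)] <- NA_integer_
  as.integer(n)
}

#' Chromosome name normalization
#'
#' Chromosome names are compared case-insensitively with and without the
#' `"chr"` prefix, so `"chrX"`, `"X"` and `"chrx"` all denote the X
#' chromosome. Pseudoautosomal regions are not modeled: every X call in a
#' male is treated as haploid.
#'
#' @param chrom Character vector of chromosome names.
#' @return `norm_chrom()`: upper-cased names without the `chr` prefix;
#'   `is_x_chrom()`: logical vector.
#' @export
norm_chrom <- function(chrom) {
  sub("^CHR", "", toupper(chrom))
}

#' @rdname norm_chrom
#' @export
is_x_chrom <- function(chrom) {
  norm_chrom(chrom) == "X"
}

# Canonical genotype string from an alt-allele dosage and ploidy.
gt_string <- function(dosage, ploidy) {
  dplyr::case_when(
    is.na(dosage) & ploidy == 1 ~ ".",
    is.na(dosage) ~ "./.",
    ploidy == 1 & dosage == 0 ~ "0",
    ploidy == 1 ~ "1",
    dosage == 0 ~ "0/0",
    dosage == 1 ~ "0/1",
    TRUE ~ "1/1"
  )
}

# Recode one raw VCF genotype string against a 1-based alt-allele index:
# alleles equal to `alt_index` count as 1, every other called allele
# (reference or another alt) as 0. Returns NA for missing or malformed.
recode_gt_dosage <- function(gt, alt_index) {
  out <- rep(NA_integer_, length(gt))
  ok <- !is.na(gt)
  if (!any(ok)) return(out)
  parts <- strsplit(gt[ok], "[/|]")
  out[ok] <- vapply(parts, function(a) {
    if (length(a) == 0 || any(a == "." | a == "")) return(NA_integer_)
    suppressWarnings(ai <- as.integer(a))
    if (any(is.na(ai))) return(NA_integer_)
    sum(ai == alt_index)
  }, integer(1))
  out
}

# Raw ploidy (number of allele fields) of a VCF genotype string.
raw_gt_ploidy <- function(gt) {
  p <- lengths(strsplit(gt, "[/|]"))
  p[is.na(gt)] <- NA_integer_
  as.integer(p)
}
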