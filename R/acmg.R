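acmg_code_vocabulary <- function() {
  c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
    "BA1", paste0("BS", 1:4), paste0("BP", 1:7))
}

#' Combine ACMG evidence codes into a five-tier class
#'
#' Applies the standard evidence-combining rules of the ACMG/AMP sequence
#' variant interpretation guidelines to a set of evidence codes, producing
#' one of `P` (pathogenic), `LP` (likely pathogenic), `VUS` (uncertain
#' significance), `LB` (likely benign), `B` (benign). A set matching both a
#' pathogenic and a benign arm, or neither, is `VUS`. Unknown codes are
#' fatal.
#'
#' @param codes Character vector of evidence codes (e.g.
#'   `c("PM1", "PM2", "PP3")`); duplicates are ignored.
#' @return A single classification string.
#' @examples
#' acmg_combine(c("PM1"))               # "VUS"
#' acmg_combine(c("PVS1", "PS1"))       # "P"
#' acmg_combine(c("PM1", "PM2", "PM3")) # "LP"
#' @export
acmg_combine <- function(codes) {
  codes <- unique(as.character(codes %||% character(0)))
  bad <- setdiff(codes, acmg_code_vocabulary())
  if (length(bad)) {
    abort(paste0("unknown ACMG evidence code(s): ",
                 paste(bad, collapse = ", ")))
  }
  n <- function(prefix) sum(startsWith(codes, prefix))
  pvs <- sum(codes == "PVS1")
  ps <- n("PS")
  pm <- n("PM")
  pp <- n("PP")
  ba <- sum(codes == "BA1")
  bs <- n("BS")
  bp <- n("BP")

  pathogenic <-
    (pvs >= 1 && (ps >= 1 || pm >= 2 || (pm == 1 && pp == 1) || pp >= 2)) ||
    ps >= 2 ||
    (ps == 1 && (pm >= 3 || (pm == 2 && pp >= 2) || (pm == 1 && pp >= 4)))
  likely_pathogenic <-
    (pvs >= 1 && pm >= 1) ||
    (ps == 1 && pm >= 1 && pm <= 2) ||
    (ps == 1 && pp >= 2) ||
    pm >= 3 ||
    (pm == 2 && pp >= 2) ||
    (pm == 1 && pp >= 4)
  benign <- ba >= 1 || bs >= 2
  likely_benign <- (bs == 1 && bp >= 1) || bp >= 2

  path_side <- pathogenic || likely_pathogenic
  benign_side <- benign || likely_benign
  if (path_side && benign_side) return("VUS")
  if (pathogenic) return("P")
  if (likely_pathogenic) return("LP")
  if (benign) return("B")
  if (likely_benign) return("LB")
  "VUS"
}

#' Auto-assign ACMG evidence codes to variants
#'
#' Only three codes are derivable from the data this pipeline carries, and
#' only those are ever auto-assigned:
#'
#' * `PM2` — absent from (or below the rarity threshold in) the reference
#'   population, and absent from the supplied control table;
#' * `PP3` — computational evidence of deleteriousness, CADD strictly
#'   greater than the configured threshold;
#' * `PM1` — located in a user-supplied critical-domain interval (no
#'   interval file means PM1 is never assigned: domain knowledge cannot be
#'   derived from the variant table).
#'
#' @param variants Variant tibble (columns `chrom`, `pos`, `af_ref`,
#'   `cadd`).
#' @param config A [filter_config()].
#' @param control_table Optional tibble of variants recorded in a control
#'   cohort (columns `chrom`, `pos`, `ref`, `alt`); presence vetoes PM2.
#' @param domain_intervals Optional tibble of critical-domain intervals
#'   (columns `chrom`, `start`, `end`, 1-based inclusive).
#' @param auto_pm2,auto_pp3 Toggles for the frequency and computational
#'   codes (both default `TRUE`).
#' @return The input with list-column `evidence` (character vector of codes
#'   per row), `evidence_str` (e.g. `"PM1; PM2; PP3"`), and `acmg_class`.
#' @export
assign_evidence <- function(variants, config = filter_config(),
                            control_table = NULL, domain_intervals = NULL,
                            auto_pm2 = TRUE, auto_pp3 = TRUE) {
  n <- nrow(variants)
  pm1 <- rep(FALSE, n)
  if (!is.null(domain_intervals) && nrow(domain_intervals) > 0) {
    vc <- norm_chrom(variants$chrom)
    ic <- norm_chrom(domain_intervals$chrom)
    for (i in seq_len(nrow(domain_intervals))) {
      pm1 <- pm1 | (vc == ic[i] &
                      variants$pos >= domain_intervals$start[i] &
                      variants$pos <= domain_intervals$end[i])
    }
  }
  pm2 <- rep(FALSE, n)
  if (auto_pm2) {
    rare <- is_rare(variants$af_ref, config)
    in_controls <- rep(FALSE, n)
    if (!is.null(control_table) && nrow(control_table) > 0) {
      vkey <- paste(norm_chrom(variants$chrom), variants$pos,
                    variants$ref, variants$alt, sep = "\r")
      ckey <- paste(norm_chrom(control_table$chrom), control_table$pos,
                    control_table$ref, control_table$alt, sep = "\r")
      in_controls <- vkey %in% ckey
    }
    pm2 <- rare & !in_controls
  }
  pp3 <- rep(FALSE, n)
  if (auto_pp3) {
    pp3 <- !is.na(variants$cadd) & variants$cadd > config$cadd_threshold
  }
  evidence <- purrr::pmap(list(pm1, pm2, pp3), function(a, b, c) {
    c("PM1", "PM2", "PP3")[c(a, b, c)]
  })
  variants %>%
    mutate(
      evidence = evidence,
      evidence_str = purrr::map_chr(evidence, paste, collapse = "; "),
      acmg_class = purrr::map_chr(evidence, acmg_combine)
    )
}
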