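#' Tidy a one-sided Fisher test result
#'
#' @param x A `trio_fisher` object.
#' @param ... Unused.
#' @return A one-row tibble with the table cells, the p-value, method and
#'   alternative.
#' @method tidy trio_fisher
#' @export
tidy.trio_fisher <- function(x, ...) {
  tibble(
    case_carriers = x$table$case_carriers,
    case_total = x$table$case_total,
    ref_carriers = x$table$ref_carriers,
    ref_total = x$table$ref_total,
    p.value = x$p_one_sided,
    method = x$method,
    alternative = x$alternative
  )
}

#' @rdname tidy.trio_fisher
#' @method glance trio_fisher
#' @export
glance.trio_fisher <- function(x, ...) {
  tibble(p.value = x$p_one_sided, method = x$method,
         alternative = x$alternative)
}

#' Tidy the candidate calls of a pipeline run
#'
#' @param x A `trio_run` object.
#' @param ... Unused.
#' @return `tidy()`: the candidate call tibble (one row per called
#'   variant). `glance()`: a one-row run summary with cascade counts, call
#'   and gene tallies, the cilia percentage and the burden split.
#' @method tidy trio_run
#' @export
tidy.trio_run <- function(x, ...) {
  as_tibble(x$candidates)
}

#' @rdname tidy.trio_run
#' @method glance trio_run
#' @export
glance.trio_run <- function(x, ...) {
  b <- x$burden$summary
  tibble(
    n_variants = x$cascade$total,
    n_rare = x$cascade$rare,
    n_rare_deleterious = x$cascade$rare_deleterious,
    n_rare_dns = x$cascade$rare_dns,
    n_rare_lof = x$cascade$rare_lof,
    n_calls = length(unique(x$calls$call_id)),
    n_chd_lof_genes = length(x$chd_lof$genes),
    cilia_percent = x$cilia$percent,
    burden_single_percent = b$percent[b$category == "single"],
    burden_multiple_percent = b$percent[b$category == "multiple"],
    burden_none_percent = b$percent[b$category == "none"]
  )
}
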