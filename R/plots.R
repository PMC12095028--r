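#' Plot the variant filtering cascade
#'
#' Bar chart of the cascade tallies: total, rare, rare deleterious, and
#' the damaging-nonsynonymous / loss-of-function split.
#'
#' @param object A `trio_cascade` tibble from [cascade_counts()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trio_cascade
#' @export
autoplot.trio_cascade <- function(object, ...) {
  d <- tibble(
    stage = factor(c("total", "rare", "rare deleterious", "rare DNS",
                     "rare LOF"),
                   levels = c("total", "rare", "rare deleterious",
                              "rare DNS", "rare LOF")),
    count = c(object$total, object$rare, object$rare_deleterious,
              object$rare_dns, object$rare_lof)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "variants",
                  title = "Variant filtering cascade") +
    ggplot2::theme_minimal()
}

#' Plot the per-proband gene-burden split
#'
#' @param object A `trio_burden` summary tibble from [gene_burden()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trio_burden
#' @export
autoplot.trio_burden <- function(object, ...) {
  d <- mutate(as_tibble(object),
              category = factor(.data$category,
                                levels = c("single", "multiple", "none")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$count)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d (%.2f%%)", .data$count, .data$percent)),
      vjust = -0.4, size = 3) +
    ggplot2::labs(x = "implicated candidate genes per proband",
                  y = "probands",
                  title = "Candidate-gene burden") +
    ggplot2::theme_minimal()
}

#' Plot a cilia-gene fraction
#'
#' @param object A `trio_cilia` tibble from [cilia_fraction()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trio_cilia
#' @export
autoplot.trio_cilia <- function(object, ...) {
  d <- tibble(
    class = factor(c("cilia", "other"), levels = c("cilia", "other")),
    count = c(object$count_cilia,
              object$count_total - object$count_cilia)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = "", y = .data$count,
                                  fill = .data$class)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::labs(fill = NULL, x = NULL, y = NULL,
                  title = sprintf("Cilia-related genes: %.1f%% (%d/%d)",
                                  object$percent, object$count_cilia,
                                  object$count_total)) +
    ggplot2::theme_void()
}

#' Plot a phenotype summary
#'
#' @param object A `trio_phenotypes` tibble from [summarize_phenotypes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trio_phenotypes
#' @export
autoplot.trio_phenotypes <- function(object, ...) {
  d <- mutate(as_tibble(object),
              category = factor(.data$category,
                                levels = rev(object$category)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$percent, y = .data$category)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d (%.2f%%)", .data$count, .data$percent)),
      hjust = -0.05, size = 3) +
    ggplot2::xlim(0, max(object$percent) * 1.25) +
    ggplot2::labs(x = "% of probands", y = NULL,
                  title = "Cohort phenotype summary") +
    ggplot2::theme_minimal()
}
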