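## ggplot2 views of the main result types. Each function returns the plot
## object so callers can theme or save it.

#' Plot the multi-source provenance distribution
#'
#' Bar chart of the non-empty source combinations from [venn_counts()],
#' multi-source combinations highlighted.
#'
#' @param counts Output of [venn_counts()].
#' @return A ggplot object.
#' @export
plot_source_overlap <- function(counts) {
  df <- counts |>
    filter(.data$n > 0L) |>
    mutate(combo = stats::reorder(.data$combo, .data$n),
           multi = .data$n_sources >= 2L)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$combo,
                                   fill = .data$multi)) +
    ggplot2::geom_col(show.legend = TRUE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "#2c7fb8"),
                               labels = c(`FALSE` = "single source",
                                          `TRUE` = "multi-source"),
                               name = NULL) +
    ggplot2::labs(x = "genes / proteins", y = NULL,
                  title = "Evidence-source membership of the unified gene set")
}

#' Plot the cascade attrition funnel
#'
#' Drug counts per pipeline stage, from mapping to final selection.
#'
#' @param x A `pipeline_report` or a stage-count tibble
#'   (`stage`, `drugs`, `targets`).
#' @return A ggplot object.
#' @export
plot_cascade <- function(x) {
  counts <- if (inherits(x, "pipeline_report")) x$stage_counts else x
  df <- counts |>
    filter(!is.na(.data$drugs)) |>
    mutate(stage = factor(.data$stage, levels = unique(.data$stage)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$drugs)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::geom_text(ggplot2::aes(label = .data$drugs), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "drugs retained",
                  title = "Candidate attrition through the repurposing cascade")
}

#' @describeIn plot_cascade Autoplot method for pipeline reports.
#' @param object,... Passed through.
#' @method autoplot pipeline_report
#' @export
autoplot.pipeline_report <- function(object, ...) plot_cascade(object)

#' @method autoplot connectivity_results
#' @export
autoplot.connectivity_results <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mean, y = .data$enrichment,
                                       size = .data$n_instances)) +
    ggplot2::geom_point(alpha = 0.6, colour = "#2c7fb8") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::scale_size_continuous(name = "instances") +
    ggplot2::labs(x = "mean connectivity", y = "instance enrichment",
                  title = "Drug-level connectivity against the query signature")
}

#' @method autoplot metnet
#' @export
autoplot.metnet <- function(object, ...) {
  deg <- igraph::degree(object)
  cls <- igraph::V(object)$class
  df <- tibble(degree = as.integer(deg), class = cls)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, fill = .data$class)) +
    ggplot2::geom_histogram(bins = 30, position = "dodge") +
    ggplot2::scale_fill_manual(values = c(metabolite = "#d95f02",
                                          protein = "#1b9e77")) +
    ggplot2::labs(x = "node degree", y = "nodes",
                  title = "Degree distribution of the metabolite-protein network")
}
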