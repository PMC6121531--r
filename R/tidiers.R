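#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy and summarize pipeline results
#'
#' `tidy()` on a pipeline run returns the association battery (Table-1
#' shape); `glance()` returns the one-row run summary.
#'
#' @param x A `heataa_run` from [run_pipeline()] or a
#'   `heataa_compartments` from [compartment_battery()].
#' @param ... Unused.
#' @return A tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.heataa_run <- function(x, ...) {
  as_tibble(x$associations)
}

#' @rdname tidy.heataa_run
#' @export
#' @exportS3Method generics::glance
glance.heataa_run <- function(x, ...) {
  as_tibble(x$summary[setdiff(names(x$summary), "config_hash")]) |>
    mutate(config_hash = x$summary$config_hash)
}

#' @rdname tidy.heataa_run
#' @export
#' @exportS3Method generics::tidy
tidy.heataa_compartments <- function(x, ...) {
  as_tibble(x$by_compartment)
}

#' @rdname tidy.heataa_run
#' @export
#' @exportS3Method generics::glance
glance.heataa_compartments <- function(x, ...) {
  as_tibble(x$sign_tests)
}

#' Plot an association battery
#'
#' Dot-and-segment plot of Spearman rho per feature, faceted by control
#' regime, with significant associations (q < 0.05 for amino acids,
#' p < 0.05 otherwise) filled.
#'
#' @param object A `heataa_associations` tibble from
#'   [association_battery()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.heataa_associations <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(feature = factor(.data$feature, levels = unique(.data$feature)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$rho)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$feature, yend = 0),
                          linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(fill = .data$significant),
                        shape = 21, size = 2) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::facet_wrap(~control, ncol = 1) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "white")) +
    ggplot2::labs(x = NULL, y = "Spearman rho with R",
                  fill = "significant") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a group comparison
#'
#' Induced vs repressed medians per feature, with significance marked.
#'
#' @param object A `heataa_groups` tibble from [group_comparison()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.heataa_groups <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(c("median_induced", "median_repressed"),
                        names_to = "group", names_prefix = "median_",
                        values_to = "median")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$median,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "median (%)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a compartment battery
#'
#' Tile map of the compartment-by-feature Spearman correlations, with
#' significant cells outlined.
#'
#' @param object A `heataa_compartments` from [compartment_battery()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.heataa_compartments <- function(object, ...) {
  df <- as_tibble(object$by_compartment)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature,
                                   y = .data$compartment)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$rho)) +
    ggplot2::geom_tile(data = df |> filter(.data$significant),
                       fill = NA, colour = "black", linewidth = 0.5) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "rho") +
    ggplot2::theme_minimal()
}

#' Histogram of the heat-response statistic
#'
#' @param gene_response A tibble from [gene_responses()].
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_response_distribution <- function(gene_response, bins = 60) {
  ggplot2::ggplot(gene_response, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70",
                            colour = "grey30", linewidth = 0.1) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "R = log2(E24,37 / E24,22)", y = "genes") +
    ggplot2::theme_minimal()
}
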