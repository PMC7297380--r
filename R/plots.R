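# ggplot2 visualisations of run results.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_col
#'   geom_hline facet_wrap labs scale_fill_viridis_c theme_minimal
NULL

#' Plot per-MIP representation across samples
#'
#' Heatmap of relative abundance per probe and sample — the quickest way
#' to see the imbalanced capture and spot failed probes or samples.
#'
#' @param object A `mip_stats` tibble from [compute_mip_stats()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mip_stats
#' @export
autoplot.mip_stats <- function(object, ...) {
  ggplot(object, aes(x = .data$mip_id, y = .data$sample_id,
                     fill = .data$rel_abundance)) +
    geom_tile() +
    scale_fill_viridis_c(name = "rel. abundance") +
    labs(x = "MIP probe", y = "Sample",
         title = "MIP representation per sample") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Plot per-region coverage by sample
#'
#' @param coverage [profile_coverage()] result.
#' @param min_call_depth Depth threshold drawn as a reference line
#'   (default 8).
#' @return A ggplot object.
#' @export
plot_coverage <- function(coverage, min_call_depth = 8) {
  ggplot(coverage, aes(x = .data$sample_id, y = .data$mean_coverage)) +
    geom_col(fill = "steelblue") +
    geom_hline(yintercept = min_call_depth, linetype = "dashed") +
    facet_wrap(~.data$region) +
    labs(x = "Sample", y = "Mean coverage",
         title = "Target region coverage") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a pipeline run
#'
#' The MIP representation heatmap of the run's statistics.
#'
#' @param object A `mip_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mip_run
#' @export
autoplot.mip_run <- function(object, ...) {
  autoplot.mip_stats(object$stats)
}
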