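#' @importFrom ggplot2 ggplot aes geom_col geom_line geom_point labs
#'   autoplot theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot the z-score probability distribution functions of a topology report
#'
#' Density histograms of the z-scored degree, CCS and betweenness
#' distributions over the candidate set, the view used to pick selection
#' thresholds.
#'
#' @param object A `topology_report`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot topology_report
#' @export
autoplot.topology_report <- function(object, bins = 20, ...) {
  long <- bind_rows(lapply(c("z_degree", "z_ccs", "z_betweenness"),
                           function(idx) {
    mutate(pdf_plot_data(object[[idx]], bins), index = idx)
  }))
  ggplot(long, aes(x = .data$mid, y = .data$density)) +
    geom_col(width = long$width, fill = "steelblue", colour = "grey30") +
    facet_wrap(~index, scales = "free") +
    labs(x = "z-score", y = "density",
         title = "PDF of z-scored topology indices") +
    theme_minimal()
}

#' Plot pathway enrichment results
#'
#' Bar chart of -log10 p-values for the tested pathways, colored by
#' pathway class; selected pathways carry a filled bar.
#'
#' @param object An `enrichment_result`.
#' @param top Show at most this many pathways (smallest p first).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, top = 20, ...) {
  df <- utils::head(as_tibble(object), top)
  df$pathway <- factor(df$pathway, levels = rev(df$pathway))
  ggplot(df, aes(x = -log10(.data$p_value), y = .data$pathway,
                 fill = .data$class, alpha = .data$selected)) +
    geom_col() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                guide = "none") +
    labs(x = expression(-log[10](p)), y = NULL,
         title = "Pathway enrichment") +
    theme_minimal()
}

#' Plot the path-score distribution of a cross-pathway run
#'
#' Histogram of path-score z-scores with the importance cut at z = 1.
#'
#' @param object A scored `crosspath_result`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot crosspath_result
#' @export
autoplot.crosspath_result <- function(object, bins = 20, ...) {
  stopifnot("z" %in% names(object))
  df <- pdf_plot_data(object$z, bins)
  ggplot(df, aes(x = .data$mid, y = .data$density)) +
    geom_col(width = df$width, fill = "darkorange", colour = "grey30") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    labs(x = "path-score z", y = "density",
         title = "Cross-pathway path scores (important: z >= 1)") +
    theme_minimal()
}

#' Bar chart of Venn region counts
#'
#' @param overlap Output of [overlap_report()] or [path_overlap()].
#' @return A ggplot object.
#' @export
plot_overlap <- function(overlap) {
  ggplot(overlap, aes(x = .data$region, y = .data$count)) +
    geom_col(fill = "seagreen") +
    labs(x = "Venn region", y = "count", title = "Set overlap") +
    theme_minimal()
}
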