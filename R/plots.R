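#' Plot helpers
#'
#' Static ggplot2 renderings of the workflow's plot-ready tables: per-marker
#' box plots, sample profile lines, the SE/SP bubble chart and ROC curves.
#' Each returns a ggplot object the caller can theme or save.
#'
#' @param dataset A [marker_dataset()].
#' @return A ggplot object.
#' @name panel_plots
NULL

#' @rdname panel_plots
#' @export
marker_boxplot <- function(dataset) {
  profile_table(dataset) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$marker, y = .data$value,
                                 fill = .data$class)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "signal") +
    ggplot2::theme_minimal()
}

#' @rdname panel_plots
#' @export
marker_profile_plot <- function(dataset) {
  profile_table(dataset) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$marker, y = .data$value,
                                 group = .data$sample, colour = .data$class)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = NULL, y = "signal") +
    ggplot2::theme_minimal()
}

#' @rdname panel_plots
#' @param combos Output of [combinatorial_analysis()].
#' @param se_min,sp_min Gold-filter minima in percent.
#' @export
bubble_plot <- function(combos, se_min = 0, sp_min = 0) {
  bubble_table(combos, se_min, sp_min) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$sp, y = .data$se,
                                 size = .data$size, colour = .data$gold)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue",
                                            `TRUE` = "goldenrod")) +
    ggplot2::lims(x = c(0, 100), y = c(0, 100)) +
    ggplot2::labs(x = "specificity (%)", y = "sensitivity (%)") +
    ggplot2::theme_minimal()
}

#' @rdname panel_plots
#' @param report Output of [roc_report()] (one curve per row).
#' @export
roc_plot <- function(report) {
  curves <- dplyr::bind_rows(lapply(seq_len(nrow(report)), function(i)
    dplyr::mutate(report$roc[[i]]$curve, combo_id = report$combo_id[i])))
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                       colour = .data$combo_id)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  colour = "combination") +
    ggplot2::theme_minimal()
}
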