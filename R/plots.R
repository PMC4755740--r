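# ggplot2 views of the main result types.

#' Scatter plot of knockdown response versus differentiation change
#'
#' The classic quadrant view: each point is a cassette event; events in the
#' upper-right quadrant gain inclusion both on regulator knockdown and with
#' differentiation (regulator-repressed neuronal exons), the lower-left
#' quadrant holds regulator-activated neuronally skipped exons.
#'
#' @param quadrants Tibble from [classify_quadrant()].
#' @param threshold Cutoff lines drawn on both axes (percent points).
#' @return A ggplot object.
#' @export
plot_quadrants <- function(quadrants, threshold = 15) {
  ggplot2::ggplot(quadrants,
                  ggplot2::aes(x = .data$delta_psi_kd,
                               y = .data$delta_psi_diff,
                               colour = .data$quadrant)) +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold),
                        linetype = "dashed", colour = "grey70") +
    ggplot2::geom_vline(xintercept = c(-threshold, threshold),
                        linetype = "dashed", colour = "grey70") +
    ggplot2::geom_point(alpha = 0.7, size = 1.5) +
    ggplot2::scale_colour_manual(values = c(
      repressed_neuronal = "#c0392b", activated_neuronal = "#2980b9",
      other = "grey60")) +
    ggplot2::labs(x = "ΔPSI, knockdown − control (%)",
                  y = "ΔPSI, differentiated − progenitor (%)",
                  colour = NULL) +
    ggplot2::theme_classic()
}

#' Ranked pentamer Z-scores
#'
#' @param motifs Tibble from [pentamer_zscores()].
#' @param n_label Number of top pentamers to label.
#' @return A ggplot object.
#' @export
plot_pentamer_zscores <- function(motifs, n_label = 5) {
  d <- motifs |>
    arrange(desc(.data$z)) |>
    mutate(rank = seq_len(n()),
           label = ifelse(.data$rank <= n_label, .data$pentamer, NA))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$z)) +
    ggplot2::geom_point(size = 0.8, colour = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), na.rm = TRUE,
                       hjust = -0.2, vjust = 0.3, size = 3) +
    ggplot2::labs(x = "pentamer rank", y = "enrichment Z-score") +
    ggplot2::theme_classic()
}

#' @describeIn run_pipeline Quadrant scatter of a pipeline run, with direct
#'   targets emphasised.
#' @param object A `clip_pipeline` object.
#' @param ... Unused.
#' @method autoplot clip_pipeline
#' @export
autoplot.clip_pipeline <- function(object, ...) {
  d <- tidy(object)
  plot_quadrants(select(d, "event_id", "delta_psi_kd", "delta_psi_diff",
                        "quadrant")) +
    ggplot2::geom_point(data = filter(d, .data$direct_target),
                        ggplot2::aes(x = .data$delta_psi_kd,
                                     y = .data$delta_psi_diff),
                        shape = 21, colour = "black", size = 2.4,
                        inherit.aes = FALSE)
}
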