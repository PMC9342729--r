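# ggplot2 views of the main result types.

#' Dotplot of an anchor map
#'
#' @param anchors A [build_anchor_map()] result.
#' @return A ggplot object: reference vs query anchor positions, colored
#'   by orientation (inverted runs appear as anti-diagonals).
#' @export
plot_anchor_map <- function(anchors) {
  ggplot2::ggplot(anchors,
                  ggplot2::aes(x = .data$ref_pos, y = .data$query_pos,
                               colour = .data$orientation)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::scale_colour_manual(values = c(same = "#2166ac",
                                            inverted = "#b2182b")) +
    ggplot2::labs(x = "reference position (bp)", y = "query position (bp)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Junction-context plot (IRscope-style summary)
#'
#' @param jr A [junction_report()] result.
#' @return A ggplot object showing, per junction, the flanking genes and
#'   their distances (spanning genes at distance zero).
#' @export
plot_junctions <- function(jr) {
  df <- mutate(jr,
               signed = ifelse(.data$side == "upstream", -.data$distance,
                               .data$distance))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$signed, y = .data$junction,
                                   label = .data$gene,
                                   colour = .data$side)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "distance to junction (bp)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Ranked hypervariable-locus plot
#'
#' Point-range view of the pairwise K2p distances per locus, ordered by
#' the ranking statistic, mirroring the usual presentation of
#' hypervariable-region scans.
#'
#' @param object A `locus_divergence` object (ideally from
#'   [rank_hypervariable()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.locus_divergence <- function(object, ...) {
  long <- tidy.locus_divergence(object)
  ord <- object$locus[order(-object$summary_max)]
  long$locus <- factor(long$locus, levels = rev(ord))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$locus, y = .data$d)) +
    ggplot2::stat_summary(fun.min = min, fun.max = max, fun = mean,
                          geom = "pointrange", na.rm = TRUE) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "K2p distance (per 100 sites)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
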