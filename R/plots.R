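#' Feature importance bar chart
#'
#' @param importance named numeric vector from [feature_importance()].
#' @param main plot title.
#' @return invisibly, the bar midpoints.
#' @export
plot_importance <- function(importance, main = "Feature importance") {
  imp <- sort(importance)
  graphics::barplot(imp, horiz = TRUE, las = 1, col = "steelblue",
                    xlab = "normalized information gain", main = main)
}

#' Attribution summary plot
#'
#' One horizontal strip per feature (ordered by mean absolute
#' attribution), each sample drawn at its attribution value and shaded by
#' the sample's feature value (dark = low, bright = high) -- the compact
#' way to see both how much a feature moves the model and in which
#' direction high/low values push it.
#'
#' @param attr a `fach_attribution` from [attribution_summary()].
#' @param table the explained samples (for feature values).
#' @param main plot title.
#' @export
plot_attribution_summary <- function(attr, table,
                                     main = "Additive attributions (dramatic)") {
  phi <- attr$attributions
  ord <- order(colMeans(abs(phi)))
  phi <- phi[, ord, drop = FALSE]
  d <- ncol(phi)
  pal <- grDevices::hcl.colors(100, "Viridis")
  graphics::plot(NULL, xlim = range(phi), ylim = c(0.5, d + 0.5),
                 yaxt = "n", xlab = "attribution to P(dramatic)",
                 ylab = "", main = main)
  graphics::abline(v = 0, col = "grey70")
  graphics::axis(2, at = seq_len(d), labels = colnames(phi), las = 1)
  for (j in seq_len(d)) {
    v <- table[[colnames(phi)[j]]]
    shade <- pal[pmax(1, ceiling(99 * (rank(v) / length(v))) )]
    graphics::points(phi[, j],
                     j + stats::runif(nrow(phi), -0.18, 0.18),
                     pch = 16, cex = 0.5, col = shade)
  }
}

#' Correlation heat map of a feature table
#'
#' @param feature_table data.frame whose numeric columns are correlated.
#' @param main plot title.
#' @export
plot_correlation_heatmap <- function(feature_table,
                                     main = "Feature correlations") {
  m <- correlation_matrix(feature_table)
  d <- ncol(m)
  pal <- grDevices::hcl.colors(61, "Blue-Red 2")
  graphics::image(seq_len(d), seq_len(d), t(m[d:1, , drop = FALSE]),
                  zlim = c(-1, 1), col = pal, axes = FALSE, xlab = "",
                  ylab = "", main = main)
  graphics::axis(1, at = seq_len(d), labels = colnames(m), las = 2,
                 cex.axis = 0.8)
  graphics::axis(2, at = seq_len(d), labels = rev(rownames(m)), las = 1,
                 cex.axis = 0.8)
}
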