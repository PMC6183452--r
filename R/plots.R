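#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a covariate raster
#' @param object A [cov_raster()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cov_raster <- function(object, ...) {
  df <- as_tibble.cov_raster(object)
  fill <- if (!is.null(object$levels)) "label" else "value"
  ggplot2::ggplot(df[df$mask, ],
                  ggplot2::aes(x = .data$x / 1000, y = .data$y / 1000,
                               fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)", fill = object$name,
                  title = object$name) +
    ggplot2::theme_minimal()
}

#' Plot a correlogram with its permutation envelope
#' @param object A [genetic_correlogram()] result.
#' @param ... Unused.
#' @return A ggplot of r(h) with the 95% envelope and bootstrap CI.
#' @exportS3Method ggplot2::autoplot
autoplot.correlogram <- function(object, ...) {
  df <- object$classes
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$midpoint / 1000)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$L, ymax = .data$U),
                         fill = "grey80") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$boot_lo,
                                        ymax = .data$boot_hi), width = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$r)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$r)) +
    ggplot2::labs(x = "distance class midpoint (km)",
                  y = "autocorrelation r") +
    ggplot2::theme_minimal()
  if (!is.na(object$u_intercept)) {
    p <- p + ggplot2::geom_vline(xintercept = object$u_intercept / 1000,
                                 linetype = 3)
  }
  p
}

#' Plot a predicted density surface
#' @param object A [predict_density()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.density_surface <- function(object, ...) {
  autoplot.cov_raster(object$density) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(fill = "ind/ha", title = "Predicted density")
}

#' Plot a resistance surface with significance and power outlines
#' @param object A [dresd()] result.
#' @param ... Unused.
#' @return A ggplot; significant cells outlined, sufficient-power cells
#'   dotted.
#' @exportS3Method ggplot2::autoplot
autoplot.resistance_surface <- function(object, ...) {
  df <- tidy.resistance_surface(object)
  df <- df[df$mask, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x / 1000, y = .data$y / 1000)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_tile(data = df[df$significant, ], fill = NA,
                       colour = "darkgreen", linewidth = 0.4) +
    ggplot2::geom_tile(data = df[df$sufficient_power, ], fill = NA,
                       colour = "red", linewidth = 0.2, linetype = 3) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)", fill = "IBD residual",
                  title = "Dispersal resistance (positive) / corridors (negative)") +
    ggplot2::theme_minimal()
}

#' Plot genotype PCA scores
#' @param object A [gen_pca()] result.
#' @param ... Unused.
#' @return A ggplot of PC1 vs PC2.
#' @exportS3Method ggplot2::autoplot
autoplot.gen_pca <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])
    ) +
    ggplot2::theme_minimal()
}
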