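# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_segment geom_line
#'   geom_col geom_errorbar geom_text labs theme_minimal facet_wrap
#'   position_dodge
#' @export
ggplot2::autoplot

# Axis-aligned 1-SD ellipse path around a centroid.
ellipse_path <- function(cx, cy, rx, ry, n = 120) {
  th <- seq(0, 2 * pi, length.out = n)
  tibble(x = cx + rx * cos(th), y = cy + ry * sin(th))
}

#' Ordination biplot of a cover PCA
#'
#' Plot scores on the first two axes, coloured by site, with axis-aligned
#' 1-SD ellipses around each site centroid and loading arrows whose length is
#' proportional to the variable-axis correlation.
#'
#' @param object A `cover_pca`.
#' @param arrow_scale Multiplier applied to loadings for display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cover_pca
#' @export
autoplot.cover_pca <- function(object, arrow_scale = NULL, ...) {
  scores <- object$scores
  if (!all(c("PC1", "PC2") %in% names(scores))) {
    abort("autoplot.cover_pca: fewer than two axes available",
          class = "galeria_domain_error")
  }
  arrow_scale <- arrow_scale %||%
    (0.9 * max(abs(c(scores$PC1, scores$PC2))))
  L <- object$loadings
  arrows <- tibble(variable = rownames(L),
                   x = L[, 1] * arrow_scale, y = L[, 2] * arrow_scale)
  p <- ggplot(scores, aes(x = .data$PC1, y = .data$PC2))
  if (!is.null(object$group_summary)) {
    ell <- object$group_summary |>
      mutate(path = purrr::pmap(list(.data$centroid_pc1, .data$centroid_pc2,
                                     .data$sd_pc1, .data$sd_pc2),
                                ellipse_path)) |>
      select("site_id", "path") |>
      tidyr::unnest("path")
    p <- p + ggplot2::geom_path(data = ell,
                                aes(x = .data$x, y = .data$y,
                                    colour = .data$site_id),
                                linetype = 2)
  }
  p +
    geom_point(aes(colour = .data$site_id), size = 2) +
    geom_segment(data = arrows,
                 aes(x = 0, y = 0, xend = .data$x, yend = .data$y),
                 arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                 colour = "grey40") +
    geom_text(data = arrows,
              aes(x = .data$x * 1.08, y = .data$y * 1.08,
                  label = .data$variable),
              size = 3, colour = "grey30") +
    labs(x = sprintf("PC1 (%.0f%%)", 100 * object$variance_fraction[1]),
         y = sprintf("PC2 (%.0f%%)", 100 * object$variance_fraction[2]),
         colour = "site",
         title = sprintf("%s-layer cover ordination", object$layer)) +
    theme_minimal()
}

#' Species-accumulation curve plot
#'
#' Expected richness against the number of pooled 15-minute segments, with
#' error bars showing the analytic SD, one line per site.
#'
#' @param object An `accumulation_curve` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot accumulation_curve
#' @export
autoplot.accumulation_curve <- function(object, ...) {
  df <- as_tibble(object)
  if (!"site_id" %in% names(df)) df$site_id <- "all"
  ggplot(df, aes(x = .data$k, y = .data$expected_richness,
                 colour = .data$site_id)) +
    geom_errorbar(aes(ymin = .data$expected_richness - .data$sd,
                      ymax = .data$expected_richness + .data$sd),
                  width = 0.2, alpha = 0.5) +
    geom_line() + geom_point(size = 1.5) +
    labs(x = "survey segments pooled", y = "expected species richness",
         colour = "site") +
    theme_minimal()
}

#' Natural Regeneration bar chart
#'
#' Per-class NR percentages by group, faceted by site.
#'
#' @param object An `nr_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nr_table
#' @export
autoplot.nr_table <- function(object, ...) {
  comp <- tidy(object)
  ggplot(comp, aes(x = .data$class, y = .data$nr_pct, fill = .data$group)) +
    geom_col(position = position_dodge()) +
    facet_wrap(~site_id) +
    labs(x = "height class", y = "NR (%)", fill = "group") +
    theme_minimal()
}

#' Size-class distribution plot
#'
#' Mean stems per hectare by band and group, faceted by site, with SD error
#' bars.
#'
#' @param dist A tibble from [class_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_class_distribution <- function(dist, ...) {
  df <- as_tibble(dist) |>
    mutate(band = factor(.data$band, levels = unique(.data$band[
      order(!.data$acaulescent, .data$band_lower)])))
  ggplot(df, aes(x = .data$band, y = .data$mean_count_per_ha,
                 fill = .data$group_class)) +
    geom_col(position = position_dodge()) +
    geom_errorbar(aes(ymin = pmax(.data$mean_count_per_ha - .data$sd, 0),
                      ymax = .data$mean_count_per_ha + .data$sd),
                  position = position_dodge(width = 0.9), width = 0.3) +
    facet_wrap(~site_id) +
    labs(x = "size band", y = "stems per ha", fill = "group") +
    theme_minimal()
}
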