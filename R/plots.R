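#' @importFrom ggplot2 autoplot ggplot aes geom_boxplot geom_jitter geom_tile
#'   geom_text facet_wrap labs scale_fill_gradient2 theme_minimal
#'   position_jitter
#' @export
ggplot2::autoplot

#' Plot per-ROI densities by compartment and group
#'
#' Boxplots of cell density (cells/mm^2) per tissue compartment, split by
#' treatment group and facetted by phenotype — the standard way density
#' profiles across tumor core, invasion margin and normal tissue are shown.
#'
#' @param object A `tme_density` tibble from [density_table()].
#' @param metric Column to plot: `"density"`, `"count"` or `"proportion"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tme_density <- function(object, metric = "density", ...) {
  df <- as_tibble(object)
  df$region <- factor(df$region, levels = tme_regions)
  ggplot(df, aes(x = region, y = .data[[metric]], fill = group)) +
    geom_boxplot(outlier.shape = NA, alpha = 0.7,
                 position = ggplot2::position_dodge(width = 0.8)) +
    geom_jitter(position = position_jitter(width = 0.12), size = 0.8,
                alpha = 0.6) +
    facet_wrap(~phenotype, scales = "free_y") +
    labs(x = "tissue compartment",
         y = switch(metric, density = "cells / mm²", metric)) +
    theme_minimal()
}

#' Plot per-ROI neighborhood metrics
#'
#' Boxplots of the effective score (or average pair distance) per tissue
#' compartment for each central--target pairing; undefined rows (ROIs with
#' no central cells) are dropped.
#'
#' @param object A `tme_neighborhood` tibble from [roi_neighborhood_table()].
#' @param metric `"effective_score"` or `"average_distance_um"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tme_neighborhood <- function(object, metric = "effective_score", ...) {
  df <- as_tibble(object)
  df <- df[df$defined & !is.na(df[[metric]]), ]
  df$region <- factor(df$region, levels = tme_regions)
  df$pairing <- paste(df$central, "→", df$target)
  ggplot(df, aes(x = region, y = .data[[metric]], fill = group)) +
    geom_boxplot(outlier.shape = NA, alpha = 0.7,
                 position = ggplot2::position_dodge(width = 0.8)) +
    geom_jitter(position = position_jitter(width = 0.12), size = 0.8,
                alpha = 0.6) +
    facet_wrap(~pairing, scales = "free_y") +
    labs(x = "tissue compartment",
         y = switch(metric,
                    effective_score = "effective score (pairs / central cell)",
                    average_distance_um = "average pair distance (µm)",
                    metric)) +
    theme_minimal()
}

#' Plot a correlation network as an r heatmap
#'
#' Tile map of pairwise Pearson r between phenotype counts; significant
#' edges are starred. Undefined edges are left blank.
#'
#' @param object A `tme_corr` tibble from [pearson_network()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tme_corr <- function(object, ...) {
  df <- as_tibble(object)
  df2 <- dplyr::bind_rows(
    df,
    dplyr::rename(df, phenotype_a = phenotype_b, phenotype_b = phenotype_a))
  df2$star <- ifelse(!is.na(df2$significant) & df2$significant, "*", "")
  ggplot(df2, aes(x = phenotype_a, y = phenotype_b, fill = r)) +
    geom_tile(color = "grey85") +
    geom_text(aes(label = ifelse(is.na(r), "", sprintf("%.2f%s", r, star))),
              size = 3) +
    scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                         limits = c(-1, 1), na.value = "grey95") +
    labs(x = NULL, y = NULL, fill = "Pearson r") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
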