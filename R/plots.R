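#' Diagnostic plots
#'
#' ggplot2 views of the main result tables.
#'
#' @name plots
NULL

#' Plot the four diversity metrics against depth
#'
#' @param diversity The per-station diversity tibble from [run_pipeline()]
#'   (columns \code{depth_m}, \code{fric_norm}, \code{fdiv},
#'   \code{size_diversity}, \code{richness}).
#' @return A faceted ggplot.
#' @export
plot_diversity_profiles <- function(diversity) {
  metrics <- intersect(c("fric_norm", "fdiv", "size_diversity", "richness"),
                       names(diversity))
  as_tibble(diversity) |>
    tidyr::pivot_longer(all_of(metrics), names_to = "metric",
                        values_to = "value") |>
    filter(!is.na(.data$value)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$depth_m, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "gam",
                         formula = y ~ s(x, bs = "cr", k = 10)) +
    ggplot2::facet_wrap("metric", scales = "free_y") +
    ggplot2::labs(x = "Depth (m)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot guild biomass composition by depth band
#'
#' @param composition Output of [guild_composition()].
#' @return A stacked ggplot of percentage biomass per guild and band.
#' @export
plot_guild_composition <- function(composition) {
  as_tibble(composition) |>
    mutate(band = sprintf("%d-%d", as.integer(.data$band_lower),
                          as.integer(.data$band_upper))) |>
    ggplot2::ggplot(ggplot2::aes(x = stats::reorder(.data$band,
                                                    .data$band_lower),
                                 y = .data$pct, fill = .data$guild)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Depth band (m)", y = "% of trait-subset biomass",
                  fill = "Feeding guild") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
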