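#' Spatial map of a spot-level variable
#'
#' Scatter of spots at their array coordinates colored by any column —
#' counts, dominant type, plasticity. Coordinates are micrometres and drawn
#' at a fixed aspect ratio.
#'
#' @param spots Spot tibble with `x`, `y`.
#' @param fill Column to color by (tidy-eval).
#' @param size Point size.
#' @return A ggplot object.
#' @export
plot_spot_map <- function(spots, fill, size = 0.8) {
  ggplot2::ggplot(spots,
                  ggplot2::aes(.data$x, .data$y,
                               colour = {{ fill }})) +
    ggplot2::geom_point(size = size) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_spot_map Spatial map of per-spot summed plasticity.
#' @param object A `spot_plasticity` result.
#' @param spots Spot tibble with `spot_id`, `x`, `y` to place the scores.
#' @param ... Unused.
#' @export
autoplot.spot_plasticity <- function(object, spots, ...) {
  df <- dplyr::inner_join(spots, object$by_spot, by = "spot_id")
  plot_spot_map(df, .data$plasticity) +
    ggplot2::scale_colour_viridis_c(limits = c(0, NA)) +
    ggplot2::labs(colour = "plasticity")
}

#' Layer-profile ribbon plot
#'
#' Mean dominant-type proportion per transmural layer bin with the
#' 2.5-97.5 percentile band across axial segments, one facet-free ribbon
#' per cell type — the standard outer-to-inner wall profile figure.
#'
#' @param object A `layer_profile` from [binned_profile()].
#' @param types Optional subset of cell types to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.layer_profile <- function(object, types = NULL, ...) {
  df <- object$summary
  if (!is.null(types)) df <- dplyr::filter(df, .data$cell_type %in% types)
  df <- dplyr::mutate(df,
                      layer_mid = (.data$layer_bin - 0.5) / object$n_layer_bins)
  ggplot2::ggplot(df, ggplot2::aes(.data$layer_mid, .data$mean,
                                   colour = .data$cell_type,
                                   fill = .data$cell_type)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "layer position (0 = outer, 1 = inner)",
                  y = "proportion of spots") +
    ggplot2::theme_minimal()
}

#' ARI sweep plot
#'
#' ARI against candidate cluster number with the qualifying stable run and
#' the chosen k highlighted.
#'
#' @param object An `ari_selection` from [select_k_by_ari()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ari_selection <- function(object, ...) {
  ggplot2::ggplot(object$sweep, ggplot2::aes(.data$k, .data$ari)) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2,
                        colour = "grey50") +
    ggplot2::geom_line(colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$in_run)) +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#2c7fb8")) +
    ggplot2::labs(y = "ARI", colour = "stable run") +
    ggplot2::theme_minimal()
}
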