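#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for plastispot result objects
#'
#' `tidy()` returns the per-observation table of a result object; `glance()`
#' a one-row summary.
#'
#' @param x A result object (`qc_filter`, `smoothed_counts`,
#'   `spot_plasticity`, `layer_profile`, `ari_selection`).
#' @param ... Unused.
#' @return A tibble.
#' @name plastispot_tidiers
NULL

#' @rdname plastispot_tidiers
#' @export
tidy.qc_filter <- function(x, ...) x$removed

#' @rdname plastispot_tidiers
#' @export
glance.qc_filter <- function(x, ...) {
  tibble::tibble(n_retained = nrow(x$spots), n_removed = nrow(x$removed))
}

#' @rdname plastispot_tidiers
#' @export
tidy.spot_plasticity <- function(x, ...) x$by_type

#' @rdname plastispot_tidiers
#' @export
glance.spot_plasticity <- function(x, ...) {
  tibble::tibble(n_spots = nrow(x$by_spot),
                 n_types = length(x$include_types),
                 mean_plasticity = mean(x$by_spot$plasticity))
}

#' @rdname plastispot_tidiers
#' @export
tidy.layer_profile <- function(x, ...) x$summary

#' @rdname plastispot_tidiers
#' @export
glance.layer_profile <- function(x, ...) {
  tibble::tibble(n_layer_bins = x$n_layer_bins,
                 n_axial_bins = x$n_axial_bins,
                 n_types = length(unique(x$summary$cell_type)))
}

#' @rdname plastispot_tidiers
#' @export
tidy.ari_selection <- function(x, ...) x$sweep

#' @rdname plastispot_tidiers
#' @export
glance.ari_selection <- function(x, ...) {
  tibble::tibble(chosen_k = x$chosen_k,
                 range_min = min(x$range_k), range_max = max(x$range_k),
                 threshold = x$threshold, window = x$window)
}

#' @rdname plastispot_tidiers
#' @export
tidy.smoothed_counts <- function(x, ...) {
  dplyr::bind_cols(x$spots,
                   tibble::as_tibble(as.data.frame(x$smoothed)))
}

#' @rdname plastispot_tidiers
#' @export
glance.smoothed_counts <- function(x, ...) {
  tibble::tibble(n_smoothed = nrow(x$smoothed),
                 n_excluded = length(x$excluded),
                 gaussian_sd = x$params$gaussian_sd)
}
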