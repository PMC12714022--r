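#' Region mask for an annotated tissue region
#'
#' Bundles a region's member spots with its four boundary spot lists: the
#' inner (lumen-facing) and outer (epicardial) single-spot layers used for
#' the transmural coordinate, and the upper/bottom layers used for the axial
#' coordinate. Boundaries are inputs — in real data they come from manual
#' annotation of the tissue image; for synthetic shapes
#' [region_mask_from_sim()] derives them analytically.
#'
#' @param region Region name (e.g. `"LV"`).
#' @param members Character vector of member spot ids.
#' @param inner,outer,upper,bottom Boundary spot-id vectors; each must be
#'   non-empty and a subset of `members`, and `inner` and `outer` must be
#'   disjoint.
#' @param provenance `"manual"` or `"synthetic"`.
#' @return A `region_mask` list.
#' @export
region_mask <- function(region, members, inner, outer,
                        upper = character(0), bottom = character(0),
                        provenance = c("manual", "synthetic")) {
  provenance <- match.arg(provenance)
  if (length(inner) == 0L || length(outer) == 0L) {
    rlang::abort("Inner and outer boundaries must be non-empty.")
  }
  for (b in list(inner, outer, upper, bottom)) {
    if (!all(b %in% members)) {
      rlang::abort("Boundary lists must be subsets of the member spots.")
    }
  }
  if (length(intersect(inner, outer)) > 0L) {
    rlang::abort("Inner and outer boundaries must be disjoint.")
  }
  structure(
    list(region = region, members = members, inner = inner, outer = outer,
         upper = upper, bottom = bottom, provenance = provenance),
    class = "region_mask"
  )
}

#' @rdname region_mask
#' @param sim A `spot_sim` from [sim_spots()].
#' @export
region_mask_from_sim <- function(sim, region = "synthetic_region") {
  stopifnot(inherits(sim, "spot_sim"))
  members <- sim$spots$spot_id[!sim$spots$is_smear]
  region_mask(region, members,
              inner = sim$boundaries$inner, outer = sim$boundaries$outer,
              upper = sim$boundaries$upper, bottom = sim$boundaries$bottom,
              provenance = "synthetic")
}

# shared distance-ratio position used by both axes
boundary_position <- function(spots, near_zero_ids, near_one_ids,
                              zero_name, one_name) {
  check_spot_coords(spots)
  if (length(near_zero_ids) == 0L || length(near_one_ids) == 0L) {
    rlang::abort("Both boundary lists must be non-empty.")
  }
  both <- intersect(near_zero_ids, near_one_ids)
  if (length(both) > 0L) {
    rlang::abort(paste0("Spot(s) in both boundaries: ",
                        paste(utils::head(both, 3), collapse = ", ")))
  }
  bz <- dplyr::filter(spots, .data$spot_id %in% near_zero_ids)
  bo <- dplyr::filter(spots, .data$spot_id %in% near_one_ids)
  if (nrow(bz) == 0L || nrow(bo) == 0L) {
    rlang::abort("Boundary spot ids must be present in `spots`.")
  }
  d0 <- nearest_boundary_dist(spots$x, spots$y, bz$x, bz$y)
  d1 <- nearest_boundary_dist(spots$x, spots$y, bo$x, bo$y)
  degen <- d0 == 0 & d1 == 0
  if (any(degen)) {
    rlang::abort("Spot(s) at zero distance to both boundaries.")
  }
  out <- spots
  out[[paste0("dist_", zero_name)]] <- d0
  out[[paste0("dist_", one_name)]] <- d1
  out
}

#' Normalized transmural layer position
#'
#' For each member spot, computes the Euclidean distance to the nearest
#' outer-boundary spot and nearest inner-boundary spot, and the normalized
#' position `dist_outer / (dist_outer + dist_inner)`: 0 on the outer
#' boundary, 1 on the inner boundary, capturing the transmural gradient
#' across the wall. The ratio is invariant to rigid motions of the
#' coordinates.
#'
#' @param spots Tibble of member spots (`spot_id`, `x`, `y`).
#' @param inner,outer Boundary spot-id vectors (or a [region_mask()] passed
#'   as `inner`, in which case `outer` is ignored).
#' @return `spots` with `dist_outer`, `dist_inner`, `layer_position`.
#' @export
layer_position <- function(spots, inner, outer = NULL) {
  if (inherits(inner, "region_mask")) {
    mask <- inner
    inner <- mask$inner
    outer <- mask$outer
    n_outside <- sum(!spots$spot_id %in% mask$members)
    if (n_outside > 0L) {
      rlang::warn(paste0(n_outside, " spot(s) outside the region mask ignored."))
    }
    spots <- dplyr::filter(spots, .data$spot_id %in% mask$members)
  }
  out <- boundary_position(spots, outer, inner, "outer", "inner")
  dplyr::mutate(out,
                layer_position = .data$dist_outer /
                  (.data$dist_outer + .data$dist_inner))
}

#' Normalized upper-bottom (axial) position
#'
#' Same distance-ratio construction as [layer_position()] along the
#' orthogonal axis: 0 on the upper boundary, 1 on the bottom boundary.
#'
#' @param spots Tibble of member spots (`spot_id`, `x`, `y`).
#' @param upper,bottom Boundary spot-id vectors (or a [region_mask()] passed
#'   as `upper`).
#' @return `spots` with `dist_upper`, `dist_bottom`, `axial_position`.
#' @export
axial_position <- function(spots, upper, bottom = NULL) {
  if (inherits(upper, "region_mask")) {
    mask <- upper
    upper <- mask$upper
    bottom <- mask$bottom
    n_outside <- sum(!spots$spot_id %in% mask$members)
    if (n_outside > 0L) {
      rlang::warn(paste0(n_outside, " spot(s) outside the region mask ignored."))
    }
    spots <- dplyr::filter(spots, .data$spot_id %in% mask$members)
  }
  out <- boundary_position(spots, upper, bottom, "upper", "bottom")
  dplyr::mutate(out,
                axial_position = .data$dist_upper /
                  (.data$dist_upper + .data$dist_bottom))
}

#' Binned cell-type profile across the ventricular wall
#'
#' Discretizes the layer position into `n_layer_bins` equal-width bins and
#' the axial position into `n_axial_bins` segments (half-open bins, last bin
#' closed at 1). Within each axial segment, the proportion of each dominant
#' type per layer bin is the spot count of that type over the total spots in
#' the bin. Per-bin profiles are then summarized across segments: the
#' unweighted mean of per-segment fractions and a 95% interval from the
#' 2.5th/97.5th percentiles (linear-interpolation percentiles). Bins empty
#' in a segment contribute nothing to that bin's mean or interval.
#'
#' @param positions Tibble with `spot_id`, `layer_position`,
#'   `axial_position`, `dominant_type` (e.g. [layer_position()] +
#'   [axial_position()] joined with [assign_dominant()] output).
#' @param n_layer_bins,n_axial_bins Bin counts (defaults 10 and 5).
#' @return A `layer_profile` list: `per_segment` (tibble: segment,
#'   layer_bin, cell_type, n_spots, n_bin_total, proportion) and `summary`
#'   (tibble: layer_bin, cell_type, mean, ci_low, ci_high, n_segments).
#' @export
binned_profile <- function(positions, n_layer_bins = 10, n_axial_bins = 5) {
  need <- c("spot_id", "layer_position", "axial_position", "dominant_type")
  if (!all(need %in% names(positions))) {
    rlang::abort(paste0("`positions` must have columns: ",
                        paste(need, collapse = ", ")))
  }
  if (n_layer_bins < 1L || n_axial_bins < 1L) {
    rlang::abort("Bin counts must be at least 1.")
  }
  df <- dplyr::mutate(
    positions,
    layer_bin = position_bin(.data$layer_position, n_layer_bins),
    segment = position_bin(.data$axial_position, n_axial_bins)
  )
  all_types <- sort(unique(df$dominant_type))

  per_segment <- df |>
    dplyr::count(.data$segment, .data$layer_bin, .data$dominant_type,
                 name = "n_spots") |>
    # complete types within each occupied (segment, bin) cell so absent
    # types contribute an explicit 0 to the cross-segment summary
    tidyr::complete(
      tidyr::nesting(!!rlang::sym("segment"), !!rlang::sym("layer_bin")),
      dominant_type = all_types,
      fill = list(n_spots = 0L)
    ) |>
    dplyr::group_by(.data$segment, .data$layer_bin) |>
    dplyr::mutate(n_bin_total = sum(.data$n_spots),
                  proportion = .data$n_spots / .data$n_bin_total) |>
    dplyr::ungroup() |>
    dplyr::rename(cell_type = "dominant_type")

  summary <- per_segment |>
    dplyr::group_by(.data$layer_bin, .data$cell_type) |>
    dplyr::summarise(
      mean = mean(.data$proportion),
      ci_low = stats::quantile(.data$proportion, 0.025, type = 7,
                               names = FALSE),
      ci_high = stats::quantile(.data$proportion, 0.975, type = 7,
                                names = FALSE),
      n_segments = dplyr::n(),
      .groups = "drop"
    )

  structure(
    list(per_segment = per_segment, summary = summary,
         n_layer_bins = n_layer_bins, n_axial_bins = n_axial_bins),
    class = "layer_profile"
  )
}

#' @export
print.layer_profile <- function(x, ...) {
  cat("<layer_profile>", x$n_layer_bins, "layer bins x", x$n_axial_bins,
      "segments,", length(unique(x$summary$cell_type)), "types\n")
  print(utils::head(x$summary, 5))
  invisible(x)
}
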