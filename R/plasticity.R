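#' Scaled velocity magnitude per cell
#'
#' Computes the Euclidean (L2) norm of each cell's velocity vector in the
#' 2-D visualization embedding and min-max scales the norms to `[0, 1]`.
#' The magnitude proxies the speed of transcriptional change: fast-moving
#' cells are in dynamic states, slow ones in stable states. Velocities must
#' be 2-D (the embedding projection); higher-dimensional velocity fields
#' must be projected upstream, not silently normed here.
#'
#' @param velocities Tibble with `cell_id`, `vx`, `vy`.
#' @return The input tibble with `magnitude` (raw norm) and
#'   `scaled_magnitude` (min-max scaled; all 0 when norms are constant).
#' @export
#' @examples
#' velocity_magnitude(tibble::tibble(cell_id = "c1", vx = 3, vy = 4))
velocity_magnitude <- function(velocities) {
  need <- c("cell_id", "vx", "vy")
  if (!all(need %in% names(velocities))) {
    rlang::abort("`velocities` must have columns cell_id, vx, vy.")
  }
  extra_dims <- intersect(c("vz", "v3"), names(velocities))
  if (length(extra_dims) > 0L) {
    rlang::abort("Velocity vectors must be 2-D (embedding projection).")
  }
  if (nrow(velocities) < 1L) rlang::abort("Need at least one cell.")
  if (!all(is.finite(velocities$vx)) || !all(is.finite(velocities$vy))) {
    rlang::abort("Velocity components must be finite.")
  }
  dplyr::mutate(velocities,
                magnitude = sqrt(.data$vx^2 + .data$vy^2),
                scaled_magnitude = minmax_scale(.data$magnitude))
}

#' Net transcriptional flow per cell
#'
#' From a directed cell-by-cell transition-probability matrix, each cell's
#' outflow mean is the mean of the nonzero entries in its row and its inflow
#' mean the mean of the nonzero entries in its column (zero entries are
#' excluded so unconnected cells do not bias the means; a cell with no
#' nonzero entries gets 0). Self-transitions on the diagonal carry no
#' state-transition information and are ignored. The raw net flow
#' `outflow_mean - inflow_mean` is then min-max scaled to `[0, 1]`: high
#' values mark sources (cells feeding transitions), low values sinks.
#'
#' @param transition Square nonnegative matrix (dense or sparse), optionally
#'   with cell-id dimnames.
#' @return Tibble: `cell_id`, `outflow_mean`, `inflow_mean`, `netflow`,
#'   `scaled_netflow`.
#' @export
net_flow <- function(transition) {
  m <- as_sparse(transition)
  if (nrow(m) != ncol(m)) {
    rlang::abort("Transition matrix must be square.")
  }
  if (any(m@x < 0)) {
    rlang::abort("Transition probabilities must be nonnegative.")
  }
  Matrix::diag(m) <- 0
  m <- Matrix::drop0(m)
  n <- nrow(m)

  row_sum <- Matrix::rowSums(m)
  row_nnz <- Matrix::rowSums(m != 0)
  col_sum <- Matrix::colSums(m)
  col_nnz <- Matrix::colSums(m != 0)
  out_mean <- ifelse(row_nnz > 0, row_sum / row_nnz, 0)
  in_mean <- ifelse(col_nnz > 0, col_sum / col_nnz, 0)
  raw <- out_mean - in_mean

  ids <- rownames(m)
  if (is.null(ids)) ids <- sprintf("cell_%04d", seq_len(n))
  tibble::tibble(
    cell_id = ids,
    outflow_mean = as.numeric(out_mean),
    inflow_mean = as.numeric(in_mean),
    netflow = as.numeric(raw),
    scaled_netflow = minmax_scale(as.numeric(raw))
  )
}

#' Cell-level plasticity score
#'
#' The plasticity score of a cell is the product of its scaled velocity
#' magnitude and scaled net flow: a cell is plastic when it both moves fast
#' in expression space and acts as a transition source. Both inputs live in
#' `[0, 1]`, so the product does too.
#'
#' @param magnitudes Tibble from [velocity_magnitude()] (needs `cell_id`,
#'   `scaled_magnitude`).
#' @param flows Tibble from [net_flow()] (needs `cell_id`,
#'   `scaled_netflow`).
#' @return Tibble: `cell_id`, `scaled_magnitude`, `scaled_netflow`,
#'   `plasticity`.
#' @export
cell_plasticity <- function(magnitudes, flows) {
  if (nrow(magnitudes) != nrow(flows)) {
    rlang::abort("Magnitude and flow tables must cover the same cells.")
  }
  joined <- dplyr::inner_join(
    dplyr::select(magnitudes, "cell_id", "scaled_magnitude"),
    dplyr::select(flows, "cell_id", "scaled_netflow"),
    by = "cell_id"
  )
  if (nrow(joined) != nrow(magnitudes)) {
    rlang::abort("Cell ids do not match between magnitudes and flows.")
  }
  rng <- range(joined$scaled_magnitude, joined$scaled_netflow)
  if (rng[1] < 0 || rng[2] > 1) {
    rlang::abort("Scaled inputs must lie in [0, 1].")
  }
  dplyr::mutate(joined,
                plasticity = .data$scaled_magnitude * .data$scaled_netflow)
}

#' Cell-type-level plasticity score
#'
#' Averages cell-level plasticity within each annotated cell type, then
#' min-max scales the per-type means across types so the most plastic type
#' scores 1 and the most stable 0 (all 0 when types do not differ).
#'
#' @param cell_scores Tibble from [cell_plasticity()] (needs `cell_id`,
#'   `plasticity`).
#' @param annotations Tibble with `cell_id` and `cell_type`; every scored
#'   cell must be annotated.
#' @return Tibble: `cell_type`, `mean_plasticity`, `plasticity` (scaled).
#' @export
celltype_plasticity <- function(cell_scores, annotations) {
  if (!all(c("cell_id", "cell_type") %in% names(annotations))) {
    rlang::abort("`annotations` must have cell_id and cell_type columns.")
  }
  joined <- dplyr::left_join(
    dplyr::select(cell_scores, "cell_id", "plasticity"),
    dplyr::select(annotations, "cell_id", "cell_type"),
    by = "cell_id"
  )
  if (anyNA(joined$cell_type)) {
    rlang::abort("Every scored cell must carry a cell-type annotation.")
  }
  if (is.factor(annotations$cell_type)) {
    empty <- setdiff(levels(annotations$cell_type),
                     unique(as.character(joined$cell_type)))
    if (length(empty) > 0L) {
      rlang::abort(paste0("Cell type(s) with no cells: ",
                          paste(empty, collapse = ", ")))
    }
  }
  out <- dplyr::summarise(
    dplyr::group_by(joined, cell_type = as.character(.data$cell_type)),
    mean_plasticity = mean(.data$plasticity), .groups = "drop"
  )
  dplyr::mutate(out, plasticity = minmax_scale(.data$mean_plasticity))
}

#' Project cell-type plasticity onto spatial spots
#'
#' The spatial plasticity contribution of type `C` in spot `s` is
#' `plasticity[C] * proportion[C, s]`; the per-spot score is the sum of
#' these contributions over `include_types` (no renormalization over the
#' subset, so a spot only partially covered by the included types is scored
#' by that partial coverage).
#'
#' @param props Proportion tibble ([abundance_to_proportion()] /
#'   [assign_dominant()] output); rows flagged `excluded` are dropped.
#' @param type_scores Tibble from [celltype_plasticity()] (`cell_type`,
#'   `plasticity`); must cover `include_types`.
#' @param include_types Character subset of types to sum over; default all
#'   scored types present in `props`.
#' @return A `spot_plasticity` list: `by_type` (long tibble: spot_id,
#'   cell_type, proportion, type_plasticity, plasticity) and `by_spot`
#'   (tibble: spot_id, plasticity = summed score).
#' @export
spot_plasticity <- function(props, type_scores, include_types = NULL) {
  types_in_props <- setdiff(names(props),
                            c("spot_id", "dominant_type", "excluded"))
  if (is.null(include_types)) {
    include_types <- intersect(types_in_props, type_scores$cell_type)
  }
  unknown <- setdiff(include_types,
                     intersect(types_in_props, type_scores$cell_type))
  if (length(unknown) > 0L) {
    rlang::abort(paste0("Type(s) not covered by proportions and scores: ",
                        paste(unknown, collapse = ", ")))
  }
  if ("excluded" %in% names(props)) {
    props <- dplyr::filter(props, !.data$excluded)
  }
  long <- tidyr::pivot_longer(
    dplyr::select(props, "spot_id", dplyr::all_of(include_types)),
    -"spot_id", names_to = "cell_type", values_to = "proportion"
  )
  long <- dplyr::left_join(
    long,
    dplyr::select(type_scores, "cell_type", type_plasticity = "plasticity"),
    by = "cell_type"
  )
  long <- dplyr::mutate(long,
                        plasticity = .data$type_plasticity * .data$proportion)
  by_spot <- dplyr::summarise(dplyr::group_by(long, .data$spot_id),
                              plasticity = sum(.data$plasticity),
                              .groups = "drop")
  structure(list(by_type = long, by_spot = by_spot,
                 include_types = include_types),
            class = "spot_plasticity")
}

#' @export
print.spot_plasticity <- function(x, ...) {
  cat("<spot_plasticity>", nrow(x$by_spot), "spots x",
      length(x$include_types), "types\n")
  print(utils::head(x$by_spot, 5))
  invisible(x)
}
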