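#' Convert deconvolution abundances to per-spot proportions
#'
#' Each spot's cell-type abundances (nonnegative reals, as emitted by a
#' spatial deconvolution tool) are divided by their row total:
#' `Proportion[C, s] = Abundance[C, s] / sum_C Abundance[C, s]`. Spots whose
#' abundances are all zero reflect a deconvolution failure rather than
#' biology; they are dropped and reported via the `"dropped"` attribute.
#'
#' @param abundance Tibble with a `spot_id` column and one numeric column per
#'   cell type, or a numeric matrix with spot rownames.
#' @return A tibble of the same shape with rows summing to 1, with attribute
#'   `dropped` holding the ids of zero-total spots.
#' @export
#' @examples
#' ab <- tibble::tibble(spot_id = "s1", A = 2, B = 3, C = 5)
#' abundance_to_proportion(ab)
abundance_to_proportion <- function(abundance) {
  if (is.matrix(abundance)) {
    abundance <- dplyr::bind_cols(
      tibble::tibble(spot_id = rownames(abundance)),
      tibble::as_tibble(as.data.frame(abundance))
    )
  }
  if (!"spot_id" %in% names(abundance)) {
    rlang::abort("`abundance` must have a `spot_id` column.")
  }
  types <- setdiff(names(abundance), "spot_id")
  if (length(types) == 0L) rlang::abort("No cell-type columns found.")
  if (anyDuplicated(types)) rlang::abort("Cell-type names must be unique.")
  mat <- as.matrix(abundance[, types])
  if (!all(is.finite(mat))) rlang::abort("Abundances must be finite.")
  if (any(mat < 0)) rlang::abort("Abundances must be nonnegative.")

  tot <- rowSums(mat)
  zero <- tot == 0
  dropped <- abundance$spot_id[zero]
  if (any(zero)) {
    rlang::inform(paste0(sum(zero),
                         " spot(s) with zero total abundance dropped."))
  }
  props <- mat[!zero, , drop = FALSE] / tot[!zero]
  out <- dplyr::bind_cols(
    tibble::tibble(spot_id = abundance$spot_id[!zero]),
    tibble::as_tibble(as.data.frame(props))
  )
  attr(out, "dropped") <- dropped
  out
}

#' Assign each spot its dominant cell type
#'
#' The dominant type is the argmax over the proportion columns, with ties
#' broken by lexicographically smallest type name (deterministic and
#' seed-free). Spots whose dominant type is in `exclude_types` — by default
#' erythrocytes, i.e. residual blood signal — are flagged `excluded = TRUE`
#' so downstream analyses can omit them.
#'
#' @param props Proportion tibble from [abundance_to_proportion()].
#' @param exclude_types Character vector of type names whose dominant spots
#'   are flagged for exclusion. Unknown names draw a warning, not an error.
#' @return `props` with `dominant_type` and logical `excluded` columns.
#' @export
assign_dominant <- function(props, exclude_types = "Erythrocytes") {
  if (!"spot_id" %in% names(props)) {
    rlang::abort("`props` must have a `spot_id` column.")
  }
  types <- setdiff(names(props), c("spot_id", "dominant_type", "excluded"))
  mat <- as.matrix(props[, types])
  unknown <- setdiff(exclude_types, types)
  if (length(unknown) > 0L) {
    rlang::warn(paste0("Exclude list names unknown type(s): ",
                       paste(unknown, collapse = ", ")))
  }
  ord <- order(types)  # lexicographic tie-break: scan types in sorted order
  sorted_types <- types[ord]
  dominant <- sorted_types[apply(mat[, ord, drop = FALSE], 1L, which.max)]
  dplyr::mutate(props,
                dominant_type = dominant,
                excluded = dominant %in% exclude_types)
}
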