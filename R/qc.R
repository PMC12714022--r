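#' Count spatial neighbors within a radius
#'
#' For each spot, counts the other spots whose Euclidean distance is at most
#' `radius` (the spot itself is excluded). Uses grid bucketing, so the dense
#' pairwise distance matrix is never formed.
#'
#' @param spots Tibble with `spot_id`, `x`, `y` (micrometres).
#' @param radius Neighborhood radius in micrometres.
#' @return The input tibble with an integer `n_neighbors` column appended.
#' @export
#' @examples
#' spots <- tibble::tibble(spot_id = c("a", "b", "c"),
#'                         x = c(0, 90, 180), y = 0)
#' count_neighbors(spots, radius = 100)$n_neighbors # 1, 2, 1
count_neighbors <- function(spots, radius = 100) {
  check_spot_coords(spots)
  if (radius <= 0) rlang::abort("`radius` must be positive.")
  n <- nrow(spots)
  counts <- integer(n)
  if (n > 1L) {
    pairs <- radius_pairs(spots$x, spots$y, radius)
    counts <- tabulate(c(pairs$i, pairs$j), nbins = n)
  }
  dplyr::mutate(spots, n_neighbors = as.integer(counts))
}

#' Remove off-tissue smear spots
#'
#' Bead arrays accumulate low-count "smear" signal outside the tissue
#' section. A spot is flagged as smear when it is both low-count
#' (`total_counts < min_counts`) and sparsely neighbored
#' (`n_neighbors <= min_neighbors` within `radius`); spots failing only one
#' criterion are kept, since dense low-count spots are real tissue and
#' isolated high-count spots carry signal. The `polarity = "literal"` variant
#' instead retains exactly the low-count, densely neighbored spots.
#'
#' When smears are spatially separated from the tissue (the usual case, and
#' the regime the synthetic generator emulates) the filter is idempotent:
#' re-running it on its own output with neighbor counts recomputed removes
#' nothing further, since high-count spots are retained regardless of
#' neighbor loss and in-tissue neighborhoods stay dense.
#'
#' @param spots Tibble with `spot_id`, `x`, `y`, `total_counts`.
#' @param min_counts Count threshold.
#' @param min_neighbors Neighbor-count threshold.
#' @param radius Neighborhood radius in micrometres.
#' @param polarity `"remove_sparse_low"` (default) or `"literal"` (retain
#'   only spots with low counts and many neighbors).
#' @return A `qc_filter` list: `spots` (retained tibble, with `n_neighbors`),
#'   `removed` (tibble: spot_id, total_counts, n_neighbors, reason).
#' @export
filter_smears <- function(spots, min_counts = 100, min_neighbors = 15,
                          radius = 100,
                          polarity = c("remove_sparse_low", "literal")) {
  polarity <- match.arg(polarity)
  if (min_counts < 0 || min_neighbors < 0) {
    rlang::abort("Thresholds must be nonnegative.")
  }
  if (nrow(spots) == 0L) {
    rlang::warn("Empty spot table; nothing to filter.")
    return(structure(
      list(spots = spots,
           removed = tibble::tibble(spot_id = character(0),
                                    total_counts = integer(0),
                                    n_neighbors = integer(0),
                                    reason = character(0))),
      class = "qc_filter"
    ))
  }
  if (!"total_counts" %in% names(spots)) {
    rlang::abort("`spots` must have a `total_counts` column.")
  }
  spots <- count_neighbors(spots, radius)
  low <- spots$total_counts < min_counts
  sparse <- spots$n_neighbors <= min_neighbors
  drop <- if (polarity == "remove_sparse_low") {
    low & sparse
  } else {
    !(low & !sparse)  # literal reading: retain low-count, dense spots only
  }
  removed <- dplyr::transmute(
    spots[drop, , drop = FALSE],
    .data$spot_id, .data$total_counts, .data$n_neighbors,
    reason = paste0("counts=", .data$total_counts, "<", min_counts,
                    " & neighbors=", .data$n_neighbors, "<=", min_neighbors)
  )
  structure(
    list(spots = spots[!drop, , drop = FALSE], removed = removed),
    class = "qc_filter"
  )
}

#' @export
print.qc_filter <- function(x, ...) {
  cat("<qc_filter> retained", nrow(x$spots), "spots, removed",
      nrow(x$removed), "\n")
  invisible(x)
}

#' Gaussian smoothing parameters
#'
#' @param gaussian_sd Kernel standard deviation in micrometres. The default
#'   46.37 um matches the bead-array pitch scale used throughout.
#' @param min_spots_under_gaussian Minimum number of spots (including the
#'   spot itself) that must fall within `truncation_radius` for a spot to be
#'   smoothed; spots with sparser coverage are excluded from the output.
#' @param truncation_radius Kernel support cutoff; defaults to
#'   `3 * gaussian_sd`, beyond which the kernel mass is negligible.
#' @return A `smoothing_params` list.
#' @export
smoothing_params <- function(gaussian_sd = 46.37,
                             min_spots_under_gaussian = 10,
                             truncation_radius = 3 * gaussian_sd) {
  if (gaussian_sd <= 0) rlang::abort("`gaussian_sd` must be positive.")
  if (min_spots_under_gaussian < 1) {
    rlang::abort("`min_spots_under_gaussian` must be at least 1.")
  }
  if (truncation_radius < gaussian_sd) {
    rlang::abort("`truncation_radius` must be at least `gaussian_sd`.")
  }
  structure(
    list(gaussian_sd = gaussian_sd,
         min_spots_under_gaussian = as.integer(min_spots_under_gaussian),
         truncation_radius = truncation_radius),
    class = "smoothing_params"
  )
}

#' Gaussian kernel smoothing of spot expression
#'
#' Replaces each spot's expression with a truncated-Gaussian weighted average
#' of its neighborhood: `smoothed_s = sum_j w_sj x_j` with
#' `w_sj proportional to exp(-d_sj^2 / (2 sd^2))` over spots within
#' `truncation_radius` (self included, weight 1), normalized to sum to 1.
#' Counts are converted to per-spot proportions (counts per total) before
#' averaging, so depth differences between beads do not bleed into
#' neighbors; raw counts are untouched in the caller's hands. Spots covered
#' by fewer than `min_spots_under_gaussian` spots (themselves included) are
#' excluded from the smoothed output and listed.
#'
#' Smoothing is a convex combination, so each smoothed value lies within the
#' range of the neighborhood's input values and nonnegativity is preserved.
#'
#' @param spots Tibble with `spot_id`, `x`, `y`.
#' @param counts Matrix (spots x genes, possibly sparse) with rownames
#'   matching `spots$spot_id`.
#' @param params A [smoothing_params()] object.
#' @param normalize Divide each spot's counts by its total before averaging
#'   (default TRUE). Set FALSE to smooth the supplied values as-is.
#' @return A `smoothed_counts` list: `smoothed` (dense matrix, included
#'   spots x genes), `excluded` (character vector of spot ids),
#'   `spots` (tibble of included spots), `params`.
#' @export
gaussian_smooth <- function(spots, counts, params = smoothing_params(),
                            normalize = TRUE) {
  check_spot_coords(spots)
  stopifnot(inherits(params, "smoothing_params"))
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) ||
      !all(spots$spot_id %in% rownames(counts))) {
    rlang::abort("`counts` must have rownames covering all spot ids.")
  }
  counts <- counts[spots$spot_id, , drop = FALSE]
  if (normalize) {
    tot <- rowSums(counts)
    tot[tot == 0] <- 1
    counts <- counts / tot
  }

  n <- nrow(spots)
  pairs <- radius_pairs(spots$x, spots$y, params$truncation_radius)
  ii <- c(pairs$i, pairs$j, seq_len(n))
  jj <- c(pairs$j, pairs$i, seq_len(n))
  dd <- c(pairs$d, pairs$d, rep(0, n))
  w <- exp(-dd^2 / (2 * params$gaussian_sd^2))
  wmat <- Matrix::sparseMatrix(i = ii, j = jj, x = w, dims = c(n, n))

  coverage <- tabulate(ii, nbins = n)  # spots under the kernel, self included
  ok <- coverage >= params$min_spots_under_gaussian
  excluded <- spots$spot_id[!ok]

  wmat <- wmat[ok, , drop = FALSE]
  wmat <- wmat / Matrix::rowSums(wmat)
  smoothed <- as.matrix(wmat %*% counts)
  rownames(smoothed) <- spots$spot_id[ok]

  structure(
    list(smoothed = smoothed, excluded = excluded,
         spots = spots[ok, , drop = FALSE], params = params),
    class = "smoothed_counts"
  )
}

#' Single-cell quality-control filter
#'
#' Removes cells failing any of three standard criteria: doublet score above
#' `max_doublet`, detected genes outside `[min_genes, max_genes]`, or
#' mitochondrial fraction above `max_mito`. A cell missing any metric is
#' flagged and removed rather than silently kept.
#'
#' @param cells Tibble with `cell_id`, `doublet_score`, `n_genes`,
#'   `mito_fraction`.
#' @param max_doublet Doublet-score ceiling (default 0.25).
#' @param min_genes,max_genes Detected-gene bounds (defaults 300 and 10000).
#' @param max_mito Mitochondrial-fraction ceiling (default 0.10).
#' @return The input tibble with logical `removed` and character `reason`
#'   columns (comma-separated reasons; `NA` for retained cells).
#' @export
filter_cells <- function(cells, max_doublet = 0.25, min_genes = 300,
                         max_genes = 10000, max_mito = 0.10) {
  need <- c("cell_id", "doublet_score", "n_genes", "mito_fraction")
  missing_cols <- setdiff(need, names(cells))
  if (length(missing_cols) > 0L) {
    rlang::abort(paste0("`cells` is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  reasons <- purrr::pmap_chr(
    cells[, need[-1]],
    function(doublet_score, n_genes, mito_fraction) {
      if (anyNA(c(doublet_score, n_genes, mito_fraction))) {
        return("missing_metric")
      }
      r <- character(0)
      if (doublet_score > max_doublet) r <- c(r, "doublet")
      if (n_genes < min_genes) r <- c(r, "few_genes")
      if (n_genes > max_genes) r <- c(r, "many_genes")
      if (mito_fraction > max_mito) r <- c(r, "high_mito")
      if (length(r) == 0L) NA_character_ else paste(r, collapse = ",")
    }
  )
  dplyr::mutate(cells, removed = !is.na(reasons), reason = reasons)
}
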