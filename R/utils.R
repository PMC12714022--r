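#' Min-max scale a numeric vector to [0, 1]
#'
#' Linear rescaling `(x - min) / (max - min)`. When all values are equal the
#' range is degenerate and every value is mapped to 0: a flat vector carries
#' no ordering information, and downstream scores treat "no variation" as
#' "no evidence".
#'
#' @param x Numeric vector with no missing or infinite values.
#' @return Numeric vector in `[0, 1]`, or all zeros when `max(x) == min(x)`.
#' @export
#' @examples
#' minmax_scale(c(0, 5, 10))
#' minmax_scale(c(2, 2, 2))
minmax_scale <- function(x) {
  stopifnot(is.numeric(x))
  if (length(x) == 0L) return(numeric(0))
  if (anyNA(x) || any(!is.finite(x))) {
    rlang::abort("`x` must be finite and non-missing for min-max scaling.")
  }
  lo <- min(x)
  hi <- max(x)
  if (hi == lo) return(rep(0, length(x)))
  (x - lo) / (hi - lo)
}

# Checks a spot table has the required columns and finite coordinates.
check_spot_coords <- function(spots, call = rlang::caller_env()) {
  if (!is.data.frame(spots)) {
    rlang::abort("`spots` must be a data frame.", call = call)
  }
  missing_cols <- setdiff(c("spot_id", "x", "y"), names(spots))
  if (length(missing_cols) > 0L) {
    rlang::abort(
      paste0("`spots` is missing column(s): ",
             paste(missing_cols, collapse = ", ")),
      call = call
    )
  }
  if (anyDuplicated(spots$spot_id)) {
    rlang::abort("`spots$spot_id` must be unique.", call = call)
  }
  if (!all(is.finite(spots$x)) || !all(is.finite(spots$y))) {
    rlang::abort("Spot coordinates must be finite.", call = call)
  }
  invisible(spots)
}

# All (i, j, d) pairs with d <= radius, i < j, via grid bucketing so large
# inputs never materialise the dense pairwise distance matrix.
radius_pairs <- function(x, y, radius) {
  n <- length(x)
  if (n < 2L) {
    return(tibble::tibble(i = integer(0), j = integer(0), d = numeric(0)))
  }
  cx <- floor(x / radius)
  cy <- floor(y / radius)
  key <- paste(cx, cy, sep = "_")
  cells <- split(seq_len(n), key)
  cell_xy <- do.call(rbind, lapply(strsplit(names(cells), "_", fixed = TRUE),
                                   as.numeric))
  lookup <- stats::setNames(seq_along(cells), names(cells))

  out_i <- vector("list", length(cells))
  for (ci in seq_along(cells)) {
    idx <- cells[[ci]]
    # candidates: this cell plus the 8 surrounding cells
    cand <- idx
    for (dx in -1:1) {
      for (dy in -1:1) {
        if (dx == 0 && dy == 0) next
        nb_key <- paste(cell_xy[ci, 1] + dx, cell_xy[ci, 2] + dy, sep = "_")
        nb <- lookup[nb_key]
        if (!is.na(nb)) cand <- c(cand, cells[[nb]])
      }
    }
    dx2 <- outer(x[idx], x[cand], `-`)
    dy2 <- outer(y[idx], y[cand], `-`)
    dd <- sqrt(dx2^2 + dy2^2)
    hit <- which(dd <= radius, arr.ind = TRUE)
    ii <- idx[hit[, 1]]
    jj <- cand[hit[, 2]]
    keep <- ii < jj
    out_i[[ci]] <- tibble::tibble(
      i = ii[keep], j = jj[keep],
      d = dd[hit][keep]
    )
  }
  res <- dplyr::bind_rows(out_i)
  dplyr::distinct(res, .data$i, .data$j, .keep_all = TRUE)
}

# Distance from each query point to its nearest reference point.
nearest_boundary_dist <- function(qx, qy, bx, by) {
  stopifnot(length(bx) > 0L)
  n <- length(qx)
  out <- numeric(n)
  chunk <- max(1L, floor(2e6 / length(bx)))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    dd <- outer(qx[idx], bx, `-`)^2 + outer(qy[idx], by, `-`)^2
    out[idx] <- sqrt(apply(dd, 1L, min))
  }
  out
}

# Coerce dense or sparse input to a general CsparseMatrix.
as_sparse <- function(x) {
  if (!inherits(x, "Matrix")) x <- Matrix::Matrix(as.matrix(x), sparse = TRUE)
  methods::as(methods::as(x, "generalMatrix"), "CsparseMatrix")
}

# Equal-width bin index on [0, 1]: half-open [a, b) bins, last bin closed at 1.
position_bin <- function(pos, n_bins) {
  stopifnot(n_bins >= 1L)
  if (any(pos < 0 | pos > 1, na.rm = TRUE)) {
    rlang::abort("Positions must lie in [0, 1] for binning.")
  }
  pmin(floor(pos * n_bins), n_bins - 1L) + 1L
}
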