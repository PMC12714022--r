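#' Read and write spot tables, counts, and region masks
#'
#' Plain-text interchange: spot tables as TSV, sparse counts as MatrixMarket
#' (`matrix.mtx` with `barcodes.tsv` / `features.tsv` sidecars), region masks
#' as JSON, simulation parameters as a JSON sidecar.
#'
#' @param spots Spot tibble.
#' @param path File path.
#' @return Readers return tibbles / matrices / `region_mask` objects;
#'   writers return their input invisibly.
#' @name plastispot_io
NULL

#' @rdname plastispot_io
#' @export
write_spot_table <- function(spots, path) {
  readr::write_tsv(spots, path)
  invisible(spots)
}

#' @rdname plastispot_io
#' @export
read_spot_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname plastispot_io
#' @param counts Spots-by-genes matrix (sparse or dense) with dimnames.
#' @param dir Directory receiving `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv`.
#' @export
write_counts_mtx <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- as_sparse(counts)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(counts), file.path(dir, "features.tsv"))
  invisible(counts)
}

#' @rdname plastispot_io
#' @export
read_counts_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  dimnames(m) <- list(readLines(file.path(dir, "barcodes.tsv")),
                      readLines(file.path(dir, "features.tsv")))
  as_sparse(m)
}

#' @rdname plastispot_io
#' @param mask A [region_mask()] object.
#' @export
write_region_mask <- function(mask, path) {
  stopifnot(inherits(mask, "region_mask"))
  jsonlite::write_json(unclass(mask), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(mask)
}

#' @rdname plastispot_io
#' @export
read_region_mask <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  region_mask(x$region, x$members, x$inner, x$outer,
              upper = x$upper %||% character(0),
              bottom = x$bottom %||% character(0),
              provenance = x$provenance %||% "manual")
}

#' @rdname plastispot_io
#' @param sim A `spot_sim` from [sim_spots()].
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "spot_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_spot_table(sim$spots, file.path(dir, "spots.tsv"))
  write_counts_mtx(sim$counts, dir)
  readr::write_tsv(sim$truth, file.path(dir, "ground_truth.tsv"))
  write_region_mask(region_mask_from_sim(sim),
                    file.path(dir, "region_mask.json"))
  jsonlite::write_json(sim$params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(sim)
}
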