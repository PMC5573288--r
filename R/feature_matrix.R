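#' Construct a feature matrix
#'
#' A feature matrix holds the non-negative input `X` of the factorization
#' problem: `m` rows of per-voxel features (MRI parameters, spectral
#' channels, ...) by `n` columns of voxels. Columns that are entirely zero
#' carry no information for an additive mixture model and are dropped at
#' construction time; their original indices are recorded so label maps can
#' be re-expanded.
#'
#' @param data numeric matrix with non-negative entries, features in rows
#'   and voxels in columns.
#' @param grid_shape optional integer pair `c(nrow, ncol)` mapping column
#'   index to a 2-D voxel position (column-major, i.e. column `j` of `X`
#'   sits at grid cell `j` of `matrix(..., nrow = grid_shape[1])`). The
#'   product must be at least `ncol(data)` before zero-column dropping.
#' @param feature_names optional character vector of length `m`.
#' @return An object of class `feature_matrix`: a list with elements
#'   `data`, `grid_shape`, `feature_names` and `dropped_columns` (indices
#'   of zero columns removed from the input).
#' @export
#' @examples
#' X <- feature_matrix(matrix(c(1, 0, 0, 1, 0.5, 0.5), nrow = 2))
#' dim(X$data)
feature_matrix <- function(data, grid_shape = NULL, feature_names = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 1L || ncol(data) < 1L) {
    stop("feature matrix must have at least one row and one column", call. = FALSE)
  }
  if (anyNA(data) || any(!is.finite(data))) {
    stop("feature matrix contains missing or non-finite entries", call. = FALSE)
  }
  if (any(data < 0)) {
    bad <- which(data < 0, arr.ind = TRUE)
    stop(sprintf(
      "feature matrix has %d negative entr%s; first at row %d, column %d",
      nrow(bad), if (nrow(bad) == 1L) "y" else "ies", bad[1L, 1L], bad[1L, 2L]
    ), call. = FALSE)
  }
  if (!is.null(feature_names)) {
    stopifnot(length(feature_names) == nrow(data))
    rownames(data) <- feature_names
  }
  if (!is.null(grid_shape)) {
    grid_shape <- as.integer(grid_shape)
    stopifnot(length(grid_shape) == 2L, all(grid_shape >= 1L))
    if (prod(grid_shape) < ncol(data)) {
      stop("grid_shape is too small for the number of voxel columns", call. = FALSE)
    }
  }
  zero_cols <- which(colSums(data) == 0)
  if (length(zero_cols) > 0L) {
    message(sprintf("dropping %d all-zero voxel column(s): %s",
                    length(zero_cols),
                    paste(utils::head(zero_cols, 10L), collapse = ", ")))
    data <- data[, -zero_cols, drop = FALSE]
    if (ncol(data) == 0L) {
      stop("all voxel columns are zero", call. = FALSE)
    }
  }
  structure(
    list(data = data, grid_shape = grid_shape,
         feature_names = rownames(data),
         dropped_columns = as.integer(zero_cols)),
    class = "feature_matrix"
  )
}

#' Coerce to a feature matrix
#'
#' @param x a `feature_matrix`, a plain numeric matrix, or anything
#'   `as.matrix()` can handle.
#' @param ... passed on to [feature_matrix()].
#' @return A `feature_matrix`.
#' @export
as_feature_matrix <- function(x, ...) {
  if (inherits(x, "feature_matrix")) return(x)
  feature_matrix(x, ...)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d features x %d voxels\n",
              nrow(x$data), ncol(x$data)))
  if (!is.null(x$grid_shape)) {
    cat(sprintf("  grid: %d x %d\n", x$grid_shape[1L], x$grid_shape[2L]))
  }
  if (length(x$dropped_columns)) {
    cat(sprintf("  %d zero columns dropped on load\n", length(x$dropped_columns)))
  }
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$data)

# internal: pull the bare matrix out of either representation
fm_data <- function(x) {
  if (inherits(x, "feature_matrix")) x$data else as.matrix(x)
}

#' Read a feature matrix from delimited text
#'
#' Reads a comma- or tab-separated numeric file with features in rows and
#' voxels in columns. A first row whose fields are not all numeric is
#' taken as feature names. A sidecar JSON file `<path>.json` with a
#' `grid_shape` field is honoured when present (or pass `grid_shape`
#' directly).
#'
#' @param path path to the delimited file.
#' @param grid_shape optional integer pair; overrides any sidecar value.
#' @return A [feature_matrix()].
#' @export
read_feature_matrix <- function(path, grid_shape = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty matrix file: ", path, call. = FALSE)
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  split_all <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(split_all)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[[1L]])[[1L]]
    stop(sprintf("ragged row in %s: line %d has %d fields, expected %d",
                 path, bad, widths[[bad]], widths[[1L]]), call. = FALSE)
  }
  first <- suppressWarnings(as.numeric(split_all[[1L]]))
  feature_names <- NULL
  if (anyNA(first)) {
    feature_names <- trimws(split_all[[1L]])
    split_all <- split_all[-1L]
    if (length(split_all) == 0L) stop("matrix file has only a header row", call. = FALSE)
  }
  num <- vapply(split_all, function(f) {
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) stop("non-numeric field in matrix body of ", path, call. = FALSE)
    v
  }, numeric(widths[[1L]]))
  # vapply stacks fields column-wise (fields x lines); transpose to features x voxels
  mat <- if (is.matrix(num)) t(num) else matrix(num, ncol = 1L)
  if (!is.null(feature_names)) {
    # header listed one name per feature row (stacked as a leading column) or
    # one per row-line; support the common "one name per data row" layout
    if (length(feature_names) == nrow(mat)) rownames(mat) <- feature_names
  }
  if (is.null(grid_shape)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      if (!is.null(meta$grid_shape)) grid_shape <- as.integer(meta$grid_shape)
    }
  }
  feature_matrix(mat, grid_shape = grid_shape,
                 feature_names = rownames(mat))
}

#' Write a feature matrix to delimited text
#'
#' @param x a [feature_matrix()] or numeric matrix.
#' @param path output path; values are written comma-separated at full
#'   double precision so a write/read round trip is exact.
#' @param sidecar write `<path>.json` with the grid shape when one is set.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(x, path, sidecar = TRUE) {
  fm <- as_feature_matrix(x)
  rows <- apply(fm$data, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                      scientific = TRUE),
                                               collapse = ","))
  writeLines(rows, path)
  if (sidecar && !is.null(fm$grid_shape)) {
    jsonlite::write_json(list(grid_shape = fm$grid_shape), paste0(path, ".json"),
                         auto_unbox = FALSE)
  }
  invisible(path)
}

#' Read / write an integer label map grid
#'
#' Label maps are stored as delimited integer grids (one text row per grid
#' row). `read_label_map` returns the labels as an integer vector in
#' column-major voxel order together with the grid shape.
#'
#' @param path file path.
#' @return For `read_label_map`, a list with `labels` (integer vector,
#'   column-major) and `grid_shape`.
#' @export
read_label_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  rows <- lapply(strsplit(lines, sep, fixed = TRUE), as.integer)
  if (length(unique(lengths(rows))) != 1L) stop("ragged label grid: ", path, call. = FALSE)
  grid <- do.call(rbind, rows)
  list(labels = as.integer(grid), grid_shape = dim(grid))
}

#' @param labels integer vector of per-voxel labels (column-major).
#' @param grid_shape integer pair giving the grid layout.
#' @rdname read_label_map
#' @export
write_label_map <- function(labels, grid_shape, path) {
  stopifnot(length(labels) == prod(grid_shape))
  grid <- matrix(as.integer(labels), nrow = grid_shape[1L])
  writeLines(apply(grid, 1L, paste, collapse = ","), path)
  invisible(path)
}
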