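#' Create an omics dataset
#'
#' An `omics_dataset` bundles one omics measurement matrix (features in rows,
#' samples in columns, missing cells allowed) with a features-metadata table
#' and a samples-metadata table, both aligned to the matrix axes. Feature and
#' sample identifiers must be unique; every feature/sample in the matrix gets
#' a metadata row (an empty one is created when no information is available).
#'
#' @param name Character scalar identifying the dataset (e.g. `"rnaseq"`).
#' @param matrix Numeric matrix, features x samples, with row and column
#'   names set to feature and sample identifiers. `NA` marks missing cells.
#' @param features_meta Optional data frame with a `feature_id` column; rows
#'   are reordered to match the matrix. Missing features get all-`NA` rows.
#' @param samples_meta Optional data frame with a `sample_id` column,
#'   handled the same way along the sample axis.
#'
#' @return An object of class `omics_dataset` with elements `name`, `matrix`,
#'   `features_meta`, `samples_meta` and `transforms` (a log of applied
#'   transformations, see [transform_dataset()]).
#' @export
omics_dataset <- function(name, matrix, features_meta = NULL, samples_meta = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("`matrix` must be a numeric matrix (features x samples)", call. = FALSE)
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("`matrix` must have feature IDs as rownames and sample IDs as colnames",
         call. = FALSE)
  }
  check_unique_ids(rownames(matrix), "feature")
  check_unique_ids(colnames(matrix), "sample")

  ds <- structure(
    list(
      name = name,
      matrix = matrix,
      features_meta = align_meta(features_meta, rownames(matrix), "feature_id"),
      samples_meta = align_meta(samples_meta, colnames(matrix), "sample_id"),
      transforms = empty_transform_log()
    ),
    class = "omics_dataset"
  )
  validate_omics_dataset(ds)
}

empty_transform_log <- function() {
  tibble::tibble(dataset = character(), transform = character(),
                 parameters = character())
}

check_unique_ids <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop(sprintf("duplicate %s ID(s): %s", what,
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  invisible(ids)
}

# Reorder a metadata table to the matrix axis, dropping unknown IDs (with a
# warning) and auto-creating empty rows for IDs absent from the table.
align_meta <- function(meta, ids, id_col) {
  if (is.null(meta)) {
    return(tibble::tibble(!!id_col := ids))
  }
  meta <- tibble::as_tibble(meta)
  if (!id_col %in% names(meta)) {
    stop(sprintf("metadata table lacks an `%s` column", id_col), call. = FALSE)
  }
  meta[[id_col]] <- as.character(meta[[id_col]])
  check_unique_ids(meta[[id_col]], sub("_id$", "", id_col))
  unknown <- setdiff(meta[[id_col]], ids)
  if (length(unknown) > 0) {
    warning(sprintf("dropping %d metadata row(s) with IDs absent from the matrix: %s",
                    length(unknown),
                    paste(utils::head(unknown, 5), collapse = ", ")),
            call. = FALSE)
    meta <- meta[!meta[[id_col]] %in% unknown, , drop = FALSE]
  }
  missing_ids <- setdiff(ids, meta[[id_col]])
  if (length(missing_ids) > 0) {
    meta <- dplyr::bind_rows(meta, tibble::tibble(!!id_col := missing_ids))
  }
  meta[match(ids, meta[[id_col]]), , drop = FALSE]
}

validate_omics_dataset <- function(ds) {
  stopifnot(inherits(ds, "omics_dataset"))
  if (!identical(ds$features_meta$feature_id, rownames(ds$matrix))) {
    stop("features metadata out of sync with matrix rows", call. = FALSE)
  }
  if (!identical(ds$samples_meta$sample_id, colnames(ds$matrix))) {
    stop("samples metadata out of sync with matrix columns", call. = FALSE)
  }
  ds
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat(sprintf("<omics_dataset> %s: %d features x %d samples (%.1f%% missing)\n",
              x$name, nrow(x$matrix), ncol(x$matrix),
              100 * mean(is.na(x$matrix))))
  invisible(x)
}

#' Feature and sample identifiers
#'
#' @param ds An `omics_dataset`.
#' @return Character vector of IDs in matrix order.
#' @export
feature_ids <- function(ds) rownames(ds$matrix)

#' @rdname feature_ids
#' @export
sample_ids <- function(ds) colnames(ds$matrix)

#' Load an omics measurement matrix from CSV
#'
#' Reads an RFC-4180 CSV whose first column (and header row) hold identifiers.
#' Regardless of the on-disk orientation the matrix is stored internally as
#' features x samples. Empty cells and the tokens `NA`/`NaN` (case-insensitive)
#' become missing values; any other non-numeric cell is a parse error naming
#' the offending row and column.
#'
#' @param path Path to the CSV file.
#' @param name Dataset name.
#' @param orientation Either `"features_rows"` (default; rows are features) or
#'   `"samples_rows"` (rows are samples; the matrix is transposed on load).
#' @return An [omics_dataset()].
#' @export
load_omics_csv <- function(path, name,
                           orientation = c("features_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  if (ncol(raw) < 2) stop("CSV must have an ID column plus at least one data column",
                          call. = FALSE)
  row_ids <- raw[[1]]
  col_ids <- names(raw)[-1]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- parse_numeric_cells(vals, row_ids, col_ids, path)
  rownames(num) <- row_ids
  if (orientation == "samples_rows") num <- t(num)
  check_unique_ids(rownames(num), "feature")
  check_unique_ids(colnames(num), "sample")
  omics_dataset(name, num)
}

parse_numeric_cells <- function(vals, row_ids, col_ids, path) {
  v <- trimws(as.vector(vals))
  is_missing <- v == "" | tolower(v) %in% c("na", "nan")
  num <- suppressWarnings(as.numeric(v))
  bad <- which(!is_missing & is.na(num))
  if (length(bad) > 0) {
    i <- ((bad[1] - 1) %% length(row_ids)) + 1
    j <- ((bad[1] - 1) %/% length(row_ids)) + 1
    stop(sprintf("non-numeric cell '%s' at row '%s', column '%s' in %s",
                 v[bad[1]], row_ids[i], col_ids[j], path), call. = FALSE)
  }
  num[is_missing] <- NA_real_
  matrix(num, nrow = length(row_ids), dimnames = list(NULL, col_ids))
}

#' Attach a metadata table to an omics dataset
#'
#' Joins a CSV table (or data frame) onto the feature or sample axis by ID.
#' IDs present in the table but absent from the matrix are dropped with a
#' warning; matrix IDs absent from the table receive empty metadata rows.
#'
#' @param ds An `omics_dataset`.
#' @param table Path to a CSV file, or a data frame.
#' @param axis `"features"` or `"samples"`.
#' @param id_column Name of the identifier column in `table`.
#' @return The dataset with the metadata attached (replacing any previous
#'   table on that axis).
#' @export
attach_metadata <- function(ds, table, axis = c("features", "samples"),
                            id_column = NULL) {
  axis <- match.arg(axis)
  validate_omics_dataset(ds)
  if (is.character(table) && length(table) == 1L) {
    if (!file.exists(table)) stop(sprintf("file not found: %s", table), call. = FALSE)
    table <- utils::read.csv(table, check.names = FALSE, fileEncoding = "UTF-8")
  }
  table <- tibble::as_tibble(table)
  target_col <- if (axis == "features") "feature_id" else "sample_id"
  if (is.null(id_column)) id_column <- target_col
  if (!id_column %in% names(table)) {
    stop(sprintf("id_column '%s' not found in metadata table", id_column),
         call. = FALSE)
  }
  names(table)[names(table) == id_column] <- target_col
  if (axis == "features") {
    ds$features_meta <- align_meta(table, feature_ids(ds), "feature_id")
  } else {
    ds$samples_meta <- align_meta(table, sample_ids(ds), "sample_id")
  }
  validate_omics_dataset(ds)
}

#' Write an omics dataset matrix to CSV
#'
#' Features in rows, samples in columns; missing cells written as empty
#' strings so that [load_omics_csv()] round-trips the missing-cell mask.
#'
#' @param ds An `omics_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_omics_csv <- function(ds, path) {
  validate_omics_dataset(ds)
  df <- data.frame(feature_id = feature_ids(ds), ds$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Subset an omics dataset
#'
#' @param ds An `omics_dataset`.
#' @param features,samples Character vectors of IDs to retain (default: all).
#'   Order is preserved as given.
#' @return The subset `omics_dataset`; metadata tables follow.
#' @export
subset_dataset <- function(ds, features = NULL, samples = NULL) {
  validate_omics_dataset(ds)
  features <- features %||% feature_ids(ds)
  samples <- samples %||% sample_ids(ds)
  miss_f <- setdiff(features, feature_ids(ds))
  miss_s <- setdiff(samples, sample_ids(ds))
  if (length(miss_f) > 0) stop(sprintf("unknown feature ID(s): %s",
                                       paste(miss_f, collapse = ", ")), call. = FALSE)
  if (length(miss_s) > 0) stop(sprintf("unknown sample ID(s): %s",
                                       paste(miss_s, collapse = ", ")), call. = FALSE)
  out <- ds
  out$matrix <- ds$matrix[features, samples, drop = FALSE]
  out$features_meta <- ds$features_meta[match(features, ds$features_meta$feature_id), ,
                                        drop = FALSE]
  out$samples_meta <- ds$samples_meta[match(samples, ds$samples_meta$sample_id), ,
                                      drop = FALSE]
  validate_omics_dataset(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
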