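#' Convert an integration result to the standard dimension-reduction format
#'
#' Every integration method, native or adapter-wrapped, reduces to the same
#' two tables: feature weights (one row per feature, dataset and latent
#' dimension; features not selected by a sparse method carry weight 0, they
#' are never omitted) and sample scores (one row per sample and dimension).
#' This common format is what all downstream evaluation, comparison and
#' consensus machinery consumes, and is the recommended dissemination format
#' for integration results.
#'
#' @param raw An `integration_result`.
#' @param method_label Label stored in the result and used to namespace
#'   dimensions during comparison; defaults to the method name.
#' @return A `dimension_reduction` object: `method`, `feature_weights`
#'   (tibble `feature_id`, `dataset`, `dimension`, `weight`), `sample_scores`
#'   (tibble `sample_id`, `dimension`, `score`) and `dimensions` (ordered
#'   labels such as `"Component 1"`).
#' @export
to_standard_output <- function(raw, method_label = NULL) {
  validate_integration_result(raw)
  method_label <- method_label %||% raw$method
  dims <- paste(raw$dim_prefix, seq_len(raw$ncomp))
  if (anyDuplicated(dims)) stop("duplicate dimension labels", call. = FALSE)

  fw <- dplyr::bind_rows(lapply(names(raw$block_loadings), function(nm) {
    L <- raw$block_loadings[[nm]]
    tibble::tibble(
      feature_id = rep(rownames(L), times = ncol(L)),
      dataset = nm,
      dimension = rep(dims, each = nrow(L)),
      weight = as.vector(L)
    )
  }))
  ss <- tibble::tibble(
    sample_id = rep(rownames(raw$sample_scores), times = raw$ncomp),
    dimension = rep(dims, each = nrow(raw$sample_scores)),
    score = as.vector(raw$sample_scores)
  )
  new_dimension_reduction(method_label, fw, ss, dims)
}

new_dimension_reduction <- function(method, feature_weights, sample_scores,
                                    dimensions) {
  if (anyDuplicated(feature_weights[c("feature_id", "dataset", "dimension")])) {
    stop("duplicate (feature, dataset, dimension) rows", call. = FALSE)
  }
  if (anyDuplicated(sample_scores[c("sample_id", "dimension")])) {
    stop("duplicate (sample, dimension) rows", call. = FALSE)
  }
  structure(
    list(method = method, feature_weights = feature_weights,
         sample_scores = sample_scores, dimensions = dimensions),
    class = "dimension_reduction"
  )
}

#' @export
print.dimension_reduction <- function(x, ...) {
  cat(sprintf("<dimension_reduction> %s: %d dimension(s), %d weight rows, %d score rows\n",
              x$method, length(x$dimensions), nrow(x$feature_weights),
              nrow(x$sample_scores)))
  invisible(x)
}

#' Per-feature importance scores
#'
#' For every latent dimension and omics dataset, the importance of feature
#' `i` is `|w_ij| / max_i' |w_i'j|`, the maximum running over features of the
#' same dataset for that dimension — so importances lie in `[0, 1]` and the
#' top feature of each (dataset, dimension) scores exactly 1. A (dataset,
#' dimension) whose weights are all zero yields importance 0 for every
#' feature and is flagged in the `zero_dimensions` attribute.
#'
#' Importance is invariant to rescaling all of a dimension's weights by any
#' non-zero constant and to flipping their signs, which is what makes scores
#' comparable across methods whose raw weights are not.
#'
#' @param dr A `dimension_reduction`.
#' @return An `importance_table`: tibble `feature_id`, `dataset`,
#'   `dimension`, `weight`, `importance`, with attribute `zero_dimensions`.
#' @export
compute_importance <- function(dr) {
  stopifnot(inherits(dr, "dimension_reduction"))
  fw <- dr$feature_weights
  out <- fw |>
    dplyr::group_by(.data$dataset, .data$dimension) |>
    dplyr::mutate(.max_abs = max(abs(.data$weight))) |>
    dplyr::ungroup() |>
    dplyr::mutate(importance = ifelse(.data$.max_abs == 0, 0,
                                      abs(.data$weight) / .data$.max_abs))
  zero_dims <- out |>
    dplyr::distinct(.data$dataset, .data$dimension, .data$.max_abs) |>
    dplyr::filter(.data$.max_abs == 0) |>
    dplyr::select("dataset", "dimension")
  out <- dplyr::select(out, -".max_abs")
  structure(out, class = c("importance_table", class(out)),
            zero_dimensions = zero_dims, method = dr$method)
}

#' Top contributing features for a latent dimension
#'
#' @param imp An `importance_table` (from [compute_importance()]).
#' @param dimension Dimension label, e.g. `"Component 1"`.
#' @param n Number of features per dataset.
#' @param dataset Optional single dataset name; default all datasets.
#' @param label_column Optional features-metadata column used as display
#'   label; rows with a missing label fall back to the feature ID.
#' @param ms The `multiomics_set` carrying features metadata (required when
#'   `label_column` is given).
#' @return A tibble `dataset`, `feature_id`, `label`, `importance`, `weight`,
#'   top `n` per dataset by decreasing importance (ties broken by feature
#'   ID).
#' @export
top_features <- function(imp, dimension, n = 10, dataset = NULL,
                         label_column = NULL, ms = NULL) {
  stopifnot(inherits(imp, "importance_table"), n >= 1)
  if (!dimension %in% imp$dimension) {
    stop(sprintf("unknown dimension '%s'", dimension), call. = FALSE)
  }
  tab <- imp[imp$dimension == dimension, , drop = FALSE]
  if (!is.null(dataset)) {
    if (!dataset %in% tab$dataset) {
      stop(sprintf("unknown dataset '%s'", dataset), call. = FALSE)
    }
    tab <- tab[tab$dataset == dataset, , drop = FALSE]
  }
  tab <- tab |>
    dplyr::arrange(.data$dataset, dplyr::desc(.data$importance),
                   .data$feature_id) |>
    dplyr::group_by(.data$dataset) |>
    dplyr::slice_head(n = n) |>
    dplyr::ungroup()
  tab$label <- tab$feature_id
  if (!is.null(label_column)) {
    if (is.null(ms)) stop("`ms` is required when `label_column` is given",
                          call. = FALSE)
    for (ds_name in unique(tab$dataset)) {
      meta <- get_dataset(ms, ds_name)$features_meta
      if (!label_column %in% names(meta)) {
        stop(sprintf("label column '%s' not in features metadata of '%s'",
                     label_column, ds_name), call. = FALSE)
      }
      idx <- tab$dataset == ds_name
      lab <- meta[[label_column]][match(tab$feature_id[idx], meta$feature_id)]
      keep <- !is.na(lab) & nzchar(as.character(lab))
      tab$label[idx][keep] <- as.character(lab)[keep]
    }
  }
  dplyr::select(tab, "dataset", "feature_id", "label", "importance", "weight")
}

#' Write / read the standard dimension-reduction format as CSV
#'
#' `write_standard_output()` serialises a result as two CSVs,
#' `<prefix>_feature_weights.csv` (with importance scores appended) and
#' `<prefix>_sample_scores.csv`; `read_standard_output()` reconstructs the
#' `dimension_reduction` losslessly (weights and scores).
#'
#' @param dr A `dimension_reduction`.
#' @param prefix Output path prefix.
#' @return `write_standard_output()`: the two paths, invisibly;
#'   `read_standard_output()`: a `dimension_reduction`.
#' @export
write_standard_output <- function(dr, prefix) {
  stopifnot(inherits(dr, "dimension_reduction"))
  imp <- compute_importance(dr)
  fw_path <- paste0(prefix, "_feature_weights.csv")
  ss_path <- paste0(prefix, "_sample_scores.csv")
  utils::write.csv(as.data.frame(imp), fw_path, row.names = FALSE)
  utils::write.csv(as.data.frame(dr$sample_scores), ss_path, row.names = FALSE)
  invisible(c(fw_path, ss_path))
}

#' @rdname write_standard_output
#' @param method Method label for the reconstructed result.
#' @export
read_standard_output <- function(prefix, method = "imported") {
  fw <- tibble::as_tibble(utils::read.csv(paste0(prefix, "_feature_weights.csv"),
                                          check.names = FALSE))
  ss <- tibble::as_tibble(utils::read.csv(paste0(prefix, "_sample_scores.csv"),
                                          check.names = FALSE))
  dims <- unique(ss$dimension)
  fw <- fw[, c("feature_id", "dataset", "dimension", "weight")]
  fw$feature_id <- as.character(fw$feature_id)
  ss$sample_id <- as.character(ss$sample_id)
  new_dimension_reduction(method, fw, ss[, c("sample_id", "dimension", "score")],
                          dims)
}
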