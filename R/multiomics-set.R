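#' Combine omics datasets into a multi-omics set
#'
#' A `multiomics_set` is an ordered, named collection of [omics_dataset()]
#' objects sharing one sample-ID namespace: a given sample ID denotes the same
#' biological sample in every dataset that contains it. Samples-metadata rows
#' describing the same sample in different datasets must agree on shared
#' columns (`NA` never conflicts); disagreement is a validation error.
#'
#' @param datasets A list of `omics_dataset` objects. Names are taken from the
#'   datasets' own `name` fields and must be unique.
#' @return A `multiomics_set` with elements `datasets` (named list) and
#'   `sample_registry` (union of sample IDs, in first-seen order).
#' @export
multiomics_set <- function(datasets) {
  if (!is.list(datasets) || length(datasets) == 0) {
    stop("`datasets` must be a non-empty list of omics_dataset objects",
         call. = FALSE)
  }
  lapply(datasets, validate_omics_dataset)
  nms <- vapply(datasets, function(d) d$name, character(1))
  check_unique_ids(nms, "dataset")
  names(datasets) <- nms
  registry <- unique(unlist(lapply(datasets, sample_ids), use.names = FALSE))
  ms <- structure(
    list(datasets = datasets, sample_registry = registry),
    class = "multiomics_set"
  )
  check_samples_meta_consistency(ms)
  ms
}

# Shared sample IDs must not carry conflicting metadata across datasets.
check_samples_meta_consistency <- function(ms) {
  metas <- lapply(ms$datasets, function(d) d$samples_meta)
  if (length(metas) < 2) return(invisible(ms))
  combined <- dplyr::bind_rows(metas, .id = "..dataset")
  shared_cols <- setdiff(names(combined), c("..dataset", "sample_id"))
  for (col in shared_cols) {
    tab <- combined[!is.na(combined[[col]]), c("sample_id", col)]
    n_distinct <- tapply(tab[[col]], tab$sample_id,
                         function(v) length(unique(v)))
    bad <- names(n_distinct)[n_distinct > 1]
    if (length(bad) > 0) {
      stop(sprintf(
        "conflicting samples metadata for column '%s' on sample(s): %s",
        col, paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
    }
  }
  invisible(ms)
}

validate_multiomics_set <- function(ms) {
  stopifnot(inherits(ms, "multiomics_set"))
  lapply(ms$datasets, validate_omics_dataset)
  check_unique_ids(names(ms$datasets), "dataset")
  check_samples_meta_consistency(ms)
  ms
}

#' @export
print.multiomics_set <- function(x, ...) {
  cat(sprintf("<multiomics_set> %d dataset(s), %d samples in registry\n",
              length(x$datasets), length(x$sample_registry)))
  for (d in x$datasets) {
    cat(sprintf("  - %s: %d features x %d samples\n",
                d$name, nrow(d$matrix), ncol(d$matrix)))
  }
  invisible(x)
}

#' Retrieve one dataset from a multi-omics set
#'
#' @param ms A `multiomics_set`.
#' @param name Dataset name.
#' @return The `omics_dataset`.
#' @export
get_dataset <- function(ms, name) {
  if (!name %in% names(ms$datasets)) {
    stop(sprintf("unknown dataset '%s' (available: %s)", name,
                 paste(names(ms$datasets), collapse = ", ")), call. = FALSE)
  }
  ms$datasets[[name]]
}

#' Exclusive sample-overlap counts across datasets
#'
#' Counts samples per combination of datasets with UpSet semantics: each
#' sample is counted only under the exact set of datasets that contain it, so
#' the counts sum to the size of the sample registry.
#'
#' @param ms A `multiomics_set`.
#' @return A tibble with columns `combination` (dataset names joined by
#'   `"+"`, in set order), `n_datasets` and `n_samples`, sorted by
#'   decreasing count.
#' @export
sample_overlap_counts <- function(ms) {
  validate_multiomics_set(ms)
  membership <- vapply(
    ms$datasets,
    function(d) ms$sample_registry %in% sample_ids(d),
    logical(length(ms$sample_registry))
  )
  membership <- matrix(membership, nrow = length(ms$sample_registry),
                       dimnames = list(ms$sample_registry, names(ms$datasets)))
  combo <- apply(membership, 1, function(row) {
    paste(names(ms$datasets)[row], collapse = "+")
  })
  counts <- table(combo)
  out <- tibble::tibble(
    combination = names(counts),
    n_datasets = lengths(strsplit(names(counts), "+", fixed = TRUE)),
    n_samples = as.integer(counts)
  )
  dplyr::arrange(out, dplyr::desc(.data$n_samples), .data$combination)
}

#' Restrict all datasets to their common samples
#'
#' Keeps only samples present in every dataset, imposing an identical sample
#' ordering (registry order) across datasets. Idempotent.
#'
#' @param ms A `multiomics_set`.
#' @return A `multiomics_set` in which all datasets share the same samples.
#' @export
subset_common_samples <- function(ms) {
  validate_multiomics_set(ms)
  common <- Reduce(intersect, lapply(ms$datasets, sample_ids))
  if (length(common) == 0) {
    stop("no sample is present in all datasets", call. = FALSE)
  }
  common <- ms$sample_registry[ms$sample_registry %in% common]
  multiomics_set(lapply(ms$datasets, subset_dataset, samples = common))
}

#' Replace one dataset inside a multi-omics set
#'
#' Swaps in a modified version of a dataset (imputed, transformed,
#' prefiltered, ...). The replacement may not introduce sample IDs unknown to
#' the set's registry; all invariants are re-validated.
#'
#' @param ms A `multiomics_set`.
#' @param name Name of the dataset to replace.
#' @param ds The replacement `omics_dataset`.
#' @return The updated `multiomics_set`.
#' @export
replace_dataset <- function(ms, name, ds) {
  validate_multiomics_set(ms)
  validate_omics_dataset(ds)
  if (!name %in% names(ms$datasets)) {
    stop(sprintf("unknown dataset '%s'", name), call. = FALSE)
  }
  new_samples <- setdiff(sample_ids(ds), ms$sample_registry)
  if (length(new_samples) > 0) {
    stop(sprintf("replacement introduces sample ID(s) unknown to the set: %s",
                 paste(utils::head(new_samples, 5), collapse = ", ")),
         call. = FALSE)
  }
  ds$name <- name
  datasets <- ms$datasets
  datasets[[name]] <- ds
  multiomics_set(datasets)
}
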