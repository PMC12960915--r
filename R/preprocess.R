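#' Missing-value summary across a multi-omics set
#'
#' @param ms A `multiomics_set`.
#' @return A tibble with one row per dataset: `dataset`, `n_missing`,
#'   `pct_missing` (percentage of all cells).
#' @export
missingness_summary <- function(ms) {
  validate_multiomics_set(ms)
  rows <- lapply(ms$datasets, function(d) {
    n_na <- sum(is.na(d$matrix))
    tibble::tibble(
      dataset = d$name,
      n_missing = n_na,
      pct_missing = 100 * n_na / length(d$matrix)
    )
  })
  dplyr::bind_rows(rows)
}

#' Per-feature mean and standard deviation
#'
#' Computed over observed cells only (sample standard deviation, n-1
#' denominator). Features with fewer than two observed values get `NA` for
#' the standard deviation. Useful to judge whether a variance-stabilising
#' transformation is needed.
#'
#' @param ds An `omics_dataset`.
#' @return A tibble `feature_id`, `mean`, `sd`, `n_observed`.
#' @export
mean_sd_table <- function(ds) {
  validate_omics_dataset(ds)
  m <- ds$matrix
  n_obs <- as.integer(rowSums(!is.na(m)))
  mu <- rowMeans(m, na.rm = TRUE)
  mu[n_obs == 0] <- NA_real_
  sds <- apply(m, 1, stats::sd, na.rm = TRUE)
  sds[n_obs < 2] <- NA_real_
  tibble::tibble(feature_id = feature_ids(ds), mean = unname(mu),
                 sd = unname(sds), n_observed = unname(n_obs))
}

#' Transform an omics dataset
#'
#' Supported methods:
#' * `log2_halfmin` — zeros are replaced by half the smallest non-zero value
#'   observed anywhere in the dataset, then `log2` is applied. Negative
#'   values are an error.
#' * `log2_plus1` — `log2(x + 1)`; negative values are an error.
#' * `zscore` — per-feature centring and unit-variance scaling over observed
#'   cells; a zero-variance feature is an error naming the feature.
#' * `custom` — `custom_fn(matrix)` must return a numeric matrix with
#'   identical dimnames.
#'
#' Missing cells stay missing. Each call appends a record to the dataset's
#' transformation log (retrievable with [transform_records()]), so a report
#' of what was applied to each dataset can be assembled.
#'
#' @param ds An `omics_dataset`.
#' @param method One of `"log2_halfmin"`, `"log2_plus1"`, `"zscore"`,
#'   `"custom"`.
#' @param custom_fn Function applied to the matrix when `method = "custom"`.
#' @param custom_name Label recorded for a custom transform.
#' @return The transformed `omics_dataset`.
#' @export
transform_dataset <- function(ds,
                              method = c("log2_halfmin", "log2_plus1",
                                         "zscore", "custom"),
                              custom_fn = NULL, custom_name = "custom") {
  method <- match.arg(method)
  validate_omics_dataset(ds)
  m <- ds$matrix
  params <- ""
  if (method == "log2_halfmin") {
    if (any(m < 0, na.rm = TRUE)) {
      stop("log2_halfmin requires non-negative data", call. = FALSE)
    }
    nonzero <- m[!is.na(m) & m > 0]
    if (length(nonzero) == 0) {
      stop("log2_halfmin: no non-zero value in the dataset", call. = FALSE)
    }
    half_min <- min(nonzero) / 2
    m[!is.na(m) & m == 0] <- half_min
    m <- log2(m)
    params <- sprintf("zero_replacement=%g", half_min)
  } else if (method == "log2_plus1") {
    if (any(m < 0, na.rm = TRUE)) {
      stop("log2_plus1 requires non-negative data", call. = FALSE)
    }
    m <- log2(m + 1)
  } else if (method == "zscore") {
    mu <- rowMeans(m, na.rm = TRUE)
    sds <- apply(m, 1, stats::sd, na.rm = TRUE)
    bad <- which(is.na(sds) | sds == 0)
    if (length(bad) > 0) {
      stop(sprintf("zscore: zero or undefined variance for feature(s): %s",
                   paste(utils::head(rownames(m)[bad], 5), collapse = ", ")),
           call. = FALSE)
    }
    m <- (m - mu) / sds
  } else {
    if (!is.function(custom_fn)) {
      stop("method = 'custom' requires `custom_fn`", call. = FALSE)
    }
    out <- custom_fn(m)
    if (!is.matrix(out) || !identical(dimnames(out), dimnames(m))) {
      stop("custom_fn must return a matrix with unchanged dimnames",
           call. = FALSE)
    }
    m <- out
    method <- custom_name
  }
  ds$matrix <- m
  ds$transforms <- dplyr::bind_rows(
    ds$transforms,
    tibble::tibble(dataset = ds$name, transform = method, parameters = params)
  )
  validate_omics_dataset(ds)
}

#' Transformation log of a dataset or set
#'
#' @param x An `omics_dataset` or `multiomics_set`.
#' @return A tibble `dataset`, `transform`, `parameters` in application order.
#' @export
transform_records <- function(x) {
  if (inherits(x, "multiomics_set")) {
    return(dplyr::bind_rows(lapply(x$datasets, transform_records)))
  }
  validate_omics_dataset(x)
  x$transforms
}

# Resolve a count-or-fraction keep parameter: values below 1 are read as a
# fraction of n, values above 1 as a count. Exactly 1 is a fraction (keep
# everything) when given as a double, a count when given as an integer (1L).
resolve_keep <- function(keep, n, what = "features") {
  if (!is.numeric(keep) || length(keep) != 1L || is.na(keep) || keep <= 0) {
    stop("`keep` must be a positive number", call. = FALSE)
  }
  fraction <- keep < 1 || (keep == 1 && !is.integer(keep))
  k <- if (fraction) max(1L, as.integer(round(keep * n))) else as.integer(round(keep))
  if (k > n) {
    stop(sprintf("`keep` (%d) exceeds the number of %s (%d)", k, what, n),
         call. = FALSE)
  }
  k
}

#' Unsupervised feature prefiltering by variability
#'
#' Retains the most variable features of a dataset, scored either by median
#' absolute deviation (`mad`, plain `median(|x - median(x)|)` over observed
#' cells) or by coefficient of variation (`cov`, `sd / |mean|`; a feature
#' with mean exactly zero is an error). Ties at the cutoff are broken by
#' lexicographic feature ID so runs are reproducible. The retained features
#' keep their original matrix order; feature metadata is subset accordingly.
#'
#' @param ds An `omics_dataset`.
#' @param score `"mad"` or `"cov"`.
#' @param keep Number of features to retain if > 1 (or an integer, e.g.
#'   `1L`), fraction of features if in (0, 1] as a double (`1.0` keeps
#'   everything).
#' @return The prefiltered `omics_dataset`.
#' @export
prefilter_unsupervised <- function(ds, score = c("mad", "cov"), keep) {
  score <- match.arg(score)
  validate_omics_dataset(ds)
  k <- resolve_keep(keep, nrow(ds$matrix))
  s <- feature_variability(ds$matrix, score)
  ord <- order(-s, feature_ids(ds))
  retained <- sort(match(feature_ids(ds)[ord[seq_len(k)]], feature_ids(ds)))
  out <- subset_dataset(ds, features = feature_ids(ds)[retained])
  attr(out, "prefilter_scores") <- stats::setNames(s, feature_ids(ds))
  out
}

feature_variability <- function(m, score) {
  if (score == "mad") {
    apply(m, 1, function(x) stats::median(abs(x - stats::median(x, na.rm = TRUE)),
                                          na.rm = TRUE))
  } else {
    mu <- rowMeans(m, na.rm = TRUE)
    if (any(mu == 0, na.rm = TRUE)) {
      stop(sprintf("cov score undefined for zero-mean feature(s): %s",
                   paste(utils::head(rownames(m)[which(mu == 0)], 5),
                         collapse = ", ")), call. = FALSE)
    }
    sds <- apply(m, 1, stats::sd, na.rm = TRUE)
    sds / abs(mu)
  }
}
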