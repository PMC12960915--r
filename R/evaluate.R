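#' Silhouette scores of samples in the latent space
#'
#' Assesses whether a sample grouping of interest (treatment, genotype, ...)
#' is separated by the latent dimensions: each sample gets
#' `s_i = (b_i - a_i) / max(a_i, b_i)` where `a_i` is its mean Euclidean
#' distance (in the selected dimensions' score space) to samples of its own
#' group and `b_i` the smallest mean distance to another group. Samples in
#' singleton groups score 0 by convention.
#'
#' @param dr A `dimension_reduction`.
#' @param grouping Group label per sample: either a vector named by sample
#'   ID, or unnamed and aligned with the result's sample order.
#' @param dimensions Subset of dimension labels (default: all).
#' @return A list with `samples` (tibble `sample_id`, `group`, `neighbor`,
#'   `silhouette`) and `groups` (tibble `group`, `n`, `mean_silhouette`).
#' @export
silhouette_scores <- function(dr, grouping, dimensions = NULL) {
  stopifnot(inherits(dr, "dimension_reduction"))
  dimensions <- dimensions %||% dr$dimensions
  unknown <- setdiff(dimensions, dr$dimensions)
  if (length(unknown) > 0) {
    stop(sprintf("unknown dimension(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  sm <- score_matrix(dr, dimensions)
  grouping <- align_grouping(grouping, rownames(sm))
  grp <- as.factor(grouping)
  if (nlevels(droplevels(grp)) < 2) {
    stop("at least two groups are required for silhouette scores", call. = FALSE)
  }
  d <- stats::dist(sm)
  sil <- cluster::silhouette(as.integer(grp), dist = d)
  lev <- levels(grp)
  samples <- tibble::tibble(
    sample_id = rownames(sm),
    group = as.character(grp),
    neighbor = lev[sil[, "neighbor"]],
    silhouette = sil[, "sil_width"]
  )
  groups <- samples |>
    dplyr::group_by(group = .data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_silhouette = mean(.data$silhouette), .groups = "drop")
  list(samples = samples, groups = groups)
}

score_matrix <- function(dr, dimensions) {
  ss <- dr$sample_scores[dr$sample_scores$dimension %in% dimensions, ]
  wide <- tidyr::pivot_wider(ss, names_from = "dimension",
                             values_from = "score")
  m <- as.matrix(wide[, dimensions, drop = FALSE])
  rownames(m) <- wide$sample_id
  m
}

align_grouping <- function(grouping, sample_ids) {
  if (!is.null(names(grouping))) {
    missing <- setdiff(sample_ids, names(grouping))
    if (length(missing) > 0) {
      stop(sprintf("grouping lacks label(s) for sample(s): %s",
                   paste(utils::head(missing, 5), collapse = ", ")),
           call. = FALSE)
    }
    grouping <- grouping[sample_ids]
  } else if (length(grouping) != length(sample_ids)) {
    stop("unnamed grouping must have one label per sample", call. = FALSE)
  }
  grouping
}

#' Compare feature weights with a features-metadata label
#'
#' Joins the weights and importance scores of one dataset/dimension with a
#' column of the features metadata — e.g. a differential-expression flag or a
#' fold change from a single-omics analysis — yielding a table ready for
#' plotting. For a numeric label the Pearson correlation between importance
#' and label is attached as attribute `correlation` (`NA` when the label is
#' constant).
#'
#' @param dr A `dimension_reduction`.
#' @param ms The `multiomics_set` carrying features metadata.
#' @param dataset,dimension Which block and latent dimension to extract.
#' @param label_column Features-metadata column name.
#' @return A tibble `feature_id`, `weight`, `importance`, `label`.
#' @export
weights_vs_label <- function(dr, ms, dataset, dimension, label_column) {
  imp <- compute_importance(dr)
  if (!dimension %in% imp$dimension) {
    stop(sprintf("unknown dimension '%s'", dimension), call. = FALSE)
  }
  if (!dataset %in% imp$dataset) {
    stop(sprintf("unknown dataset '%s'", dataset), call. = FALSE)
  }
  meta <- get_dataset(ms, dataset)$features_meta
  if (!label_column %in% names(meta)) {
    stop(sprintf("label column '%s' not in features metadata of '%s'",
                 label_column, dataset), call. = FALSE)
  }
  tab <- imp[imp$dataset == dataset & imp$dimension == dimension, ]
  out <- tibble::tibble(
    feature_id = tab$feature_id,
    weight = tab$weight,
    importance = tab$importance,
    label = meta[[label_column]][match(tab$feature_id, meta$feature_id)]
  )
  corr <- NA_real_
  if (is.numeric(out$label)) {
    ok <- !is.na(out$label)
    if (sum(ok) >= 3 && stats::sd(out$label[ok]) > 0 &&
        stats::sd(out$importance[ok]) > 0) {
      corr <- stats::cor(out$importance[ok], out$label[ok])
    }
  }
  attr(out, "correlation") <- corr
  out
}

#' Cross-tabulate selected features against a metadata label
#'
#' For sparse methods, "selected" means a non-zero weight in at least one
#' dimension of the given dataset. When the method performed no selection
#' (all weights non-zero), every feature is counted as selected and a warning
#' is raised. Margins always sum to the dataset's feature count.
#'
#' @param dr A `dimension_reduction`.
#' @param ms The `multiomics_set` with features metadata.
#' @param dataset Dataset name.
#' @param label_column Features-metadata column.
#' @return A contingency `table`, selected (TRUE/FALSE) x label levels
#'   (missing labels tabulated as `"<NA>"`).
#' @export
selected_vs_label <- function(dr, ms, dataset, label_column) {
  stopifnot(inherits(dr, "dimension_reduction"))
  fw <- dr$feature_weights
  if (!dataset %in% fw$dataset) {
    stop(sprintf("unknown dataset '%s'", dataset), call. = FALSE)
  }
  meta <- get_dataset(ms, dataset)$features_meta
  if (!label_column %in% names(meta)) {
    stop(sprintf("label column '%s' not in features metadata of '%s'",
                 label_column, dataset), call. = FALSE)
  }
  fw <- fw[fw$dataset == dataset, ]
  sel_by_feature <- tapply(fw$weight != 0, fw$feature_id, any)
  if (all(sel_by_feature)) {
    warning("method performed no feature selection; all features counted as selected",
            call. = FALSE)
  }
  lab <- meta[[label_column]][match(names(sel_by_feature), meta$feature_id)]
  table(selected = as.vector(sel_by_feature),
        label = addNA(as.factor(lab), ifany = TRUE))
}

# ---- feature sets -----------------------------------------------------------

#' Build a feature-set collection
#'
#' @param membership Two-column data frame (or CSV path) mapping `feature_id`
#'   to `set_id`.
#' @param set_names Optional data frame (or CSV path) with columns `set_id`,
#'   `set_name`.
#' @return A `feature_set_collection`: named list of member ID vectors plus a
#'   set-name lookup.
#' @export
make_feature_sets <- function(membership, set_names = NULL) {
  if (is.character(membership) && length(membership) == 1L) {
    membership <- utils::read.csv(membership, check.names = FALSE)
  }
  membership <- tibble::as_tibble(membership)
  if (!all(c("feature_id", "set_id") %in% names(membership))) {
    stop("membership table needs columns `feature_id` and `set_id`",
         call. = FALSE)
  }
  sets <- split(as.character(membership$feature_id),
                as.character(membership$set_id))
  sets <- lapply(sets, unique)
  names_lookup <- stats::setNames(names(sets), names(sets))
  if (!is.null(set_names)) {
    if (is.character(set_names) && length(set_names) == 1L) {
      set_names <- utils::read.csv(set_names, check.names = FALSE)
    }
    idx <- match(names(names_lookup), as.character(set_names$set_id))
    found <- !is.na(idx)
    names_lookup[found] <- as.character(set_names$set_name)[idx[found]]
  }
  structure(list(sets = sets, set_names = names_lookup),
            class = "feature_set_collection")
}

#' Extract feature sets from a features-metadata column
#'
#' The column is expected to hold delimiter-separated set identifiers per
#' feature (e.g. `"GO:1;GO:2"`); empty or missing entries contribute nothing.
#'
#' @param ds An `omics_dataset`.
#' @param column Metadata column name.
#' @param delimiter Separator between set IDs (default `";"`).
#' @return A `feature_set_collection`.
#' @export
feature_sets_from_metadata <- function(ds, column, delimiter = ";") {
  validate_omics_dataset(ds)
  meta <- ds$features_meta
  if (!column %in% names(meta)) {
    stop(sprintf("column '%s' not in features metadata", column), call. = FALSE)
  }
  vals <- as.character(meta[[column]])
  keep <- !is.na(vals) & nzchar(vals)
  pairs <- lapply(which(keep), function(i) {
    tibble::tibble(feature_id = meta$feature_id[i],
                   set_id = trimws(strsplit(vals[i], delimiter, fixed = TRUE)[[1]]))
  })
  membership <- dplyr::bind_rows(pairs)
  if (nrow(membership) == 0) stop("no set annotation found", call. = FALSE)
  make_feature_sets(membership)
}

#' Feature-set enrichment of a latent dimension
#'
#' Tests whether a feature set's importance scores for one latent dimension
#' are shifted relative to the rest of the dataset's features: sets are first
#' matched against the background (the features actually present in the
#' dataset), sets smaller than `min_size` after matching are excluded (and
#' reported via the `excluded_sets` attribute), and each remaining set is
#' tested with a Welch two-sample t-test of member vs non-member importance
#' scores — a set-vs-background reduction of generally-applicable gene-set
#' enrichment for the case where the per-feature statistic is a single score
#' vector. P-values are Benjamini-Hochberg adjusted across tested sets.
#'
#' @param imp An `importance_table`.
#' @param dimension,dataset Which importance scores to use.
#' @param sets A `feature_set_collection`.
#' @param alternative `"greater"` (members more important, default),
#'   `"less"`, or `"two.sided"`.
#' @param min_size Minimum matched set size (default 5, >= 2).
#' @return An `enrichment_result` tibble: `set_id`, `set_name`, `statistic`,
#'   `p_value`, `adj_p_value`, `n_features`, sorted by `p_value`.
#' @export
enrich_sets <- function(imp, dimension, dataset, sets,
                        alternative = c("greater", "less", "two.sided"),
                        min_size = 5) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(imp, "importance_table"),
            inherits(sets, "feature_set_collection"), min_size >= 2)
  tab <- imp[imp$dimension == dimension & imp$dataset == dataset, ]
  if (nrow(tab) == 0) {
    stop(sprintf("no importance scores for dataset '%s', dimension '%s'",
                 dataset, dimension), call. = FALSE)
  }
  background <- tab$feature_id
  scores <- stats::setNames(tab$importance, background)
  matched <- lapply(sets$sets, intersect, background)
  sizes <- lengths(matched)
  testable <- sizes >= min_size & sizes < length(background)
  excluded <- tibble::tibble(set_id = names(matched)[!testable],
                             n_matched = sizes[!testable])
  if (!any(testable)) {
    stop("all feature sets were excluded after matching to the background",
         call. = FALSE)
  }
  rows <- lapply(names(matched)[testable], function(sid) {
    members <- matched[[sid]]
    inside <- scores[members]
    outside <- scores[setdiff(background, members)]
    ht <- stats::t.test(inside, outside, alternative = alternative,
                        var.equal = FALSE)
    tibble::tibble(set_id = sid,
                   set_name = unname(sets$set_names[sid]),
                   statistic = unname(ht$statistic),
                   p_value = ht$p.value,
                   n_features = length(members))
  })
  out <- dplyr::bind_rows(rows)
  out$adj_p_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set_id),
             c("set_id", "set_name", "statistic", "p_value", "adj_p_value",
               "n_features")]
  structure(out, class = c("enrichment_result", class(out)),
            excluded_sets = excluded)
}
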