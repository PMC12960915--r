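#' Correlate the latent dimensions of two integration results
#'
#' Two methods that uncover the same structure should produce pairs of
#' latent dimensions whose sample scores — and, more loosely, feature
#' weights — are highly correlated. Score correlations are computed over the
#' samples shared by both results; weight correlations over the shared
#' (feature, dataset) pairs (features a sparse method did not select carry
#' weight 0 and so still participate). Cells whose vectors have zero variance
#' are reported `NA`.
#'
#' @param a,b `dimension_reduction` objects.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A `dimension_correlation`: `score_corr` and `weight_corr`
#'   (dimensions of `a` x dimensions of `b`), `n_samples`, `n_features`, and
#'   the two method labels.
#' @export
correlate_results <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(a, "dimension_reduction"),
            inherits(b, "dimension_reduction"))
  sa <- score_matrix(a, a$dimensions)
  sb <- score_matrix(b, b$dimensions)
  shared_samples <- intersect(rownames(sa), rownames(sb))
  wa <- weight_matrix(a)
  wb <- weight_matrix(b)
  shared_features <- intersect(rownames(wa), rownames(wb))
  if (length(shared_samples) < 3 || length(shared_features) < 3) {
    stop(sprintf(
      "insufficient overlap: %d shared sample(s), %d shared (feature, dataset) pair(s); at least 3 of each required",
      length(shared_samples), length(shared_features)), call. = FALSE)
  }
  structure(
    list(
      methods = c(a$method, b$method),
      dims_a = a$dimensions, dims_b = b$dimensions,
      score_corr = safe_cor(sa[shared_samples, , drop = FALSE],
                            sb[shared_samples, , drop = FALSE], method),
      weight_corr = safe_cor(wa[shared_features, , drop = FALSE],
                             wb[shared_features, , drop = FALSE], method),
      n_samples = length(shared_samples),
      n_features = length(shared_features)
    ),
    class = "dimension_correlation"
  )
}

# (feature, dataset) x dimension weight matrix with composite rownames
weight_matrix <- function(dr) {
  fw <- dr$feature_weights
  key <- paste(fw$dataset, fw$feature_id, sep = "\r")
  wide <- tidyr::pivot_wider(
    tibble::tibble(key = key, dimension = fw$dimension, weight = fw$weight),
    names_from = "dimension", values_from = "weight")
  m <- as.matrix(wide[, dr$dimensions, drop = FALSE])
  rownames(m) <- wide$key
  m
}

# Pairwise correlations column-by-column; zero-variance vectors give NA
# without the cor() warning noise.
safe_cor <- function(ma, mb, method) {
  out <- suppressWarnings(stats::cor(ma, mb, method = method))
  sda <- apply(ma, 2, stats::sd)
  sdb <- apply(mb, 2, stats::sd)
  out[sda == 0, ] <- NA_real_
  out[, sdb == 0] <- NA_real_
  out
}

#' @export
print.dimension_correlation <- function(x, ...) {
  cat(sprintf("<dimension_correlation> %s vs %s over %d samples / %d features\n",
              x$methods[1], x$methods[2], x$n_samples, x$n_features))
  print(round(x$score_corr, 3))
  invisible(x)
}

#' All pairwise dimension correlations among several results
#'
#' Convenience wrapper producing every unordered pair (including
#' self-comparisons, needed for the diagonal blocks of
#' [cluster_correlations()]).
#'
#' @param results Named list of `dimension_reduction` objects.
#' @param ... Passed to [correlate_results()].
#' @return List of `dimension_correlation` objects.
#' @export
compare_all <- function(results, ...) {
  stopifnot(is.list(results), length(results) >= 2, !is.null(names(results)))
  nms <- names(results)
  out <- list()
  for (i in seq_along(nms)) {
    for (j in i:length(nms)) {
      out[[paste(nms[i], nms[j], sep = " vs ")]] <-
        correlate_results(results[[i]], results[[j]], ...)
    }
  }
  out
}

#' Assemble and order a clustered correlation heatmap
#'
#' Combines pairwise dimension correlations into one symmetric block matrix
#' (dimension labels namespaced as `"method/dimension"`) and orders it by
#' average-linkage hierarchical clustering on the distance `1 - |r|`, so that
#' similar latent dimensions across methods end up adjacent. `NA`
#' correlations are treated as 0 (distance 1) for the clustering but kept
#' `NA` in the returned values.
#'
#' @param corrs List of `dimension_correlation` objects covering every
#'   unordered pair of methods, self-pairs included (see [compare_all()]).
#' @param use `"scores"` (default) or `"weights"`.
#' @return A list: `matrix` (ordered symmetric correlation matrix), `labels`
#'   (leaf order), `hclust` (the tree).
#' @export
cluster_correlations <- function(corrs, use = c("scores", "weights")) {
  use <- match.arg(use)
  stopifnot(is.list(corrs), length(corrs) >= 1)
  pick <- function(cc) if (use == "scores") cc$score_corr else cc$weight_corr
  methods <- unique(unlist(lapply(corrs, function(cc) cc$methods)))
  if (length(methods) < 2) stop("at least two methods are required", call. = FALSE)
  key <- function(m1, m2) paste(m1, m2, sep = "\r")
  have <- new.env(parent = emptyenv())
  for (cc in corrs) assign(key(cc$methods[1], cc$methods[2]), cc, envir = have)
  lookup <- function(m1, m2) {
    if (exists(key(m1, m2), envir = have)) return(list(cc = get(key(m1, m2), envir = have), t = FALSE))
    if (exists(key(m2, m1), envir = have)) return(list(cc = get(key(m2, m1), envir = have), t = TRUE))
    stop(sprintf("missing pairwise comparison: %s vs %s", m1, m2), call. = FALSE)
  }
  labels_of <- function(m) {
    cc <- lookup(m, m)$cc
    paste(m, cc$dims_a, sep = "/")
  }
  all_labels <- unlist(lapply(methods, labels_of))
  big <- matrix(NA_real_, length(all_labels), length(all_labels),
                dimnames = list(all_labels, all_labels))
  offsets <- c(0, cumsum(vapply(methods, function(m) length(labels_of(m)), 0L)))
  for (i in seq_along(methods)) {
    for (j in seq_along(methods)) {
      res <- lookup(methods[i], methods[j])
      blk <- pick(res$cc)
      if (res$t) blk <- t(blk)
      big[(offsets[i] + 1):offsets[i + 1],
          (offsets[j] + 1):offsets[j + 1]] <- blk
    }
  }
  big <- (big + t(big)) / 2     # enforce exact symmetry
  dmat <- 1 - abs(big)
  dmat[is.na(dmat)] <- 1
  hc <- stats::hclust(stats::as.dist(dmat), method = "average")
  ord <- hc$order
  list(matrix = big[ord, ord, drop = FALSE],
       labels = all_labels[ord],
       hclust = hc)
}

#' Greedy matching of latent dimensions between two results
#'
#' Pairs dimensions by descending absolute sample-score correlation, each
#' dimension used at most once; pairs whose |r| falls below the threshold are
#' dropped.
#'
#' @param corr A `dimension_correlation`.
#' @param threshold Minimum |score correlation| for a pair (default 0.7).
#' @return A tibble `dim_a`, `dim_b`, `r_scores`, `r_weights`, ordered by
#'   decreasing `|r_scores|`.
#' @export
match_dimensions <- function(corr, threshold = 0.7) {
  stopifnot(inherits(corr, "dimension_correlation"))
  sc <- corr$score_corr
  pairs <- list()
  absr <- abs(sc)
  absr[is.na(absr)] <- -Inf
  while (any(is.finite(absr)) && max(absr) >= threshold) {
    idx <- which(absr == max(absr), arr.ind = TRUE)[1, ]
    i <- idx[1]; j <- idx[2]
    pairs[[length(pairs) + 1]] <- tibble::tibble(
      dim_a = corr$dims_a[i], dim_b = corr$dims_b[j],
      r_scores = sc[i, j],
      r_weights = corr$weight_corr[i, j]
    )
    absr[i, ] <- -Inf
    absr[, j] <- -Inf
  }
  if (length(pairs) == 0) {
    return(tibble::tibble(dim_a = character(), dim_b = character(),
                          r_scores = numeric(), r_weights = numeric()))
  }
  dplyr::bind_rows(pairs)
}

# ---- consensus importance ---------------------------------------------------

consensus_aggregators <- list(
  average = function(m) rowMeans(m),
  geometric = function(m) {
    out <- exp(rowMeans(log(m)))
    out[apply(m == 0, 1, any)] <- 0
    out
  },
  harmonic = function(m) {
    out <- ncol(m) / rowSums(1 / m)
    out[apply(m == 0, 1, any)] <- 0
    out
  },
  l2 = function(m) sqrt(rowSums(m^2)),
  product = function(m) apply(m, 1, prod)
)

#' Consensus importance score across integration methods
#'
#' Aggregates a feature's importance scores for one chosen latent dimension
#' per method into a single consensus score, enabling robust feature
#' prioritisation. Only features present in every method's result (per
#' dataset) are scored: importance is undefined for features a method never
#' saw, e.g. after differing prefiltering. Stringent aggregators (geometric,
#' harmonic, product) are 0 whenever any method gives 0, favouring features
#' supported by all methods; the L2 norm (`sqrt(sum(m^2))`) also rewards
#' features strong in only some methods.
#'
#' @param imps Named list of `importance_table`s, one per method.
#' @param dimensions Character vector (recycled or named by method) giving
#'   the dimension label to use from each method.
#' @param aggregation `"geometric"` (default), `"average"`, `"harmonic"`,
#'   `"l2"`, or `"product"`.
#' @return A tibble `feature_id`, `dataset`, one `m_<method>` column per
#'   method, and `consensus`, sorted by decreasing consensus (ties by feature
#'   ID). Attribute `n_intersection` records the scored feature count.
#' @export
consensus_importance <- function(imps, dimensions,
                                 aggregation = c("geometric", "average",
                                                 "harmonic", "l2", "product")) {
  aggregation <- match.arg(aggregation)
  stopifnot(is.list(imps), length(imps) >= 2, !is.null(names(imps)))
  if (length(dimensions) == 1L) dimensions <- rep(dimensions, length(imps))
  if (!is.null(names(dimensions))) dimensions <- dimensions[names(imps)]
  if (length(dimensions) != length(imps) || any(is.na(dimensions))) {
    stop("`dimensions` must supply one dimension label per method", call. = FALSE)
  }
  per_method <- lapply(seq_along(imps), function(j) {
    tab <- imps[[j]]
    if (!dimensions[j] %in% tab$dimension) {
      stop(sprintf("dimension '%s' absent from method '%s'",
                   dimensions[j], names(imps)[j]), call. = FALSE)
    }
    tab <- tab[tab$dimension == dimensions[j], c("feature_id", "dataset",
                                                 "importance")]
    names(tab)[3] <- paste0("m_", names(imps)[j])
    tibble::as_tibble(tab)
  })
  joined <- Reduce(function(x, y) dplyr::inner_join(x, y,
                                                    by = c("feature_id", "dataset")),
                   per_method)
  if (nrow(joined) == 0) {
    stop("no feature is present in all methods' results", call. = FALSE)
  }
  m <- as.matrix(joined[, paste0("m_", names(imps)), drop = FALSE])
  joined$consensus <- consensus_aggregators[[aggregation]](m)
  out <- joined[order(-joined$consensus, joined$feature_id), ]
  attr(out, "n_intersection") <- nrow(out)
  attr(out, "aggregation") <- aggregation
  out
}
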