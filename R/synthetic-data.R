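#' Configuration for the multi-omics generator
#'
#' Describes a simulated multi-omics experiment: several measurement blocks
#' sharing latent factors (plus optional block-specific factors), sparse
#' loadings, a binary sample group that shifts the first shared factor, MCAR
#' missingness, and partially overlapping per-block sample sets.
#'
#' Defaults describe the reference simulation used throughout the package's
#' tests: 100 samples, three Gaussian blocks of 200/150/100 features with
#' noise standard deviation 0.3 and no missingness, one shared factor, no
#' block-specific factors, 10% active features per factor, a two-group
#' sample split shifting factor 1 by 2 factor-standard deviations, and full
#' sample overlap.
#'
#' @param n_samples Number of biological samples.
#' @param blocks Data frame with columns `name`, `n_features`, `noise_sd`,
#'   `missing_rate`, `prefix` (feature-ID prefix), one row per omics block.
#' @param k_shared Number of latent factors shared by all blocks.
#' @param k_specific Block-specific factor count (scalar, recycled).
#' @param sparsity Fraction of features with non-zero loading per factor.
#' @param group_effect Shift of factor 1 between the two sample groups, in
#'   factor-standard-deviation units.
#' @param sample_overlap Fraction of samples present in each block (1 = all).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 100,
                       blocks = default_sim_blocks(),
                       k_shared = 1,
                       k_specific = 0,
                       sparsity = 0.1,
                       group_effect = 2,
                       sample_overlap = 1,
                       seed = 1L) {
  blocks <- tibble::as_tibble(blocks)
  needed <- c("name", "n_features", "noise_sd", "missing_rate", "prefix")
  if (!all(needed %in% names(blocks))) {
    stop(sprintf("`blocks` needs columns: %s", paste(needed, collapse = ", ")),
         call. = FALSE)
  }
  if (any(blocks$missing_rate < 0 | blocks$missing_rate > 1) ||
      sparsity <= 0 || sparsity > 1 ||
      sample_overlap <= 0 || sample_overlap > 1) {
    stop("rates and fractions must lie in [0, 1]", call. = FALSE)
  }
  k_specific <- rep(as.integer(k_specific), length.out = nrow(blocks))
  if (any(k_shared + k_specific > pmin(blocks$n_features, n_samples))) {
    stop("factor counts exceed the smallest block dimension", call. = FALSE)
  }
  structure(list(n_samples = as.integer(n_samples), blocks = blocks,
                 k_shared = as.integer(k_shared), k_specific = k_specific,
                 sparsity = sparsity, group_effect = group_effect,
                 sample_overlap = sample_overlap, seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_sim_blocks <- function() {
  tibble::tibble(
    name = c("rna", "protein", "metabolite"),
    n_features = c(200L, 150L, 100L),
    noise_sd = 0.3,
    missing_rate = 0,
    prefix = c("R_", "P_", "M_")
  )
}

#' Generate a synthetic multi-omics experiment with known latent structure
#'
#' Each block is `X = F_shared %*% t(L_shared) + F_specific %*% t(L_specific)
#' + noise` (stored features x samples). Factors are standard normal; the
#' first shared factor's mean differs by `group_effect` between two balanced
#' sample groups (recorded in the samples metadata as `group`). For each
#' factor, a fraction `sparsity` of the block's features is active; active
#' loading magnitudes are drawn uniformly from \[0.5, 1.5\] with random sign
#' (bounded away from zero so active features are identifiable), inactive
#' loadings are exactly 0. Missingness is applied completely at random at
#' the block's configured rate; per-block sample subsets are drawn at the
#' configured overlap fraction.
#'
#' @param config A [sim_config()].
#' @return A list: `data` (a `multiomics_set`; features metadata carry the
#'   per-feature `active_shared` truth flag) and `truth` (list with
#'   `factors`, per-block `loadings`, `active` masks, `groups`,
#'   `missing_masks`).
#' @export
generate_multiomics <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  sample_names <- sprintf("sample_%03d", seq_len(n))
  groups <- factor(sample(rep(c("groupA", "groupB"), length.out = n)),
                   levels = c("groupA", "groupB"))
  k_shared <- config$k_shared
  f_shared <- matrix(stats::rnorm(n * k_shared), n, k_shared,
                     dimnames = list(sample_names,
                                     paste0("shared_", seq_len(k_shared))))
  f_shared[, 1] <- f_shared[, 1] +
    ifelse(groups == "groupB", config$group_effect / 2, -config$group_effect / 2)

  datasets <- list()
  truth_loadings <- list()
  truth_active <- list()
  missing_masks <- list()
  all_factors <- f_shared

  for (b in seq_len(nrow(config$blocks))) {
    blk <- config$blocks[b, ]
    p <- blk$n_features
    feat <- sprintf("%s%03d", blk$prefix, seq_len(p))
    k_spec <- config$k_specific[b]
    f_spec <- NULL
    if (k_spec > 0) {
      f_spec <- matrix(stats::rnorm(n * k_spec), n, k_spec,
                       dimnames = list(sample_names,
                                       paste0(blk$name, "_specific_",
                                              seq_len(k_spec))))
      all_factors <- cbind(all_factors, f_spec)
    }
    k_total <- k_shared + k_spec
    n_active <- max(1L, round(config$sparsity * p))
    L <- matrix(0, p, k_total, dimnames = list(feat, NULL))
    active <- matrix(FALSE, p, k_total, dimnames = list(feat, NULL))
    for (k in seq_len(k_total)) {
      idx <- sample.int(p, n_active)
      L[idx, k] <- stats::runif(n_active, 0.5, 1.5) *
        sample(c(-1, 1), n_active, replace = TRUE)
      active[idx, k] <- TRUE
    }
    fmat <- cbind(f_shared, f_spec)
    x <- t(fmat %*% t(L)) +
      matrix(stats::rnorm(p * n, sd = blk$noise_sd), p, n)
    dimnames(x) <- list(feat, sample_names)

    keep_n <- round(config$sample_overlap * n)
    keep <- sort(sample.int(n, keep_n))
    x <- x[, keep, drop = FALSE]

    na_mask <- matrix(stats::runif(length(x)) < blk$missing_rate,
                      nrow(x), ncol(x), dimnames = dimnames(x))
    x[na_mask] <- NA_real_

    fmeta <- tibble::tibble(
      feature_id = feat,
      active_shared = active[, 1],
      true_loading_f1 = L[, 1]
    )
    smeta <- tibble::tibble(sample_id = sample_names[keep],
                            group = as.character(groups)[keep])
    datasets[[blk$name]] <- omics_dataset(blk$name, x, features_meta = fmeta,
                                          samples_meta = smeta)
    truth_loadings[[blk$name]] <- L
    truth_active[[blk$name]] <- active
    missing_masks[[blk$name]] <- na_mask
  }

  list(
    data = multiomics_set(datasets),
    truth = list(factors = all_factors,
                 loadings = truth_loadings,
                 active = truth_active,
                 groups = stats::setNames(as.character(groups), sample_names),
                 missing_masks = missing_masks)
  )
}

#' A tiny fixed multi-omics instance with hand-checkable expectations
#'
#' Three rank-one blocks over 12 samples with partially overlapping sample
#' sets, built from closed-form patterns (no randomness) so that overlap
#' counts, MAD-prefiltering order, importance scores and consensus rankings
#' can be enumerated by hand. Shipped for documentation and as a regression
#' anchor.
#'
#' Block `alpha` has 30 features over samples s01-s10, `beta` 20 features
#' over s03-s12, `gamma` 10 features over s01-s12. Feature `k` of each block
#' measures `k * z_j` where `z` is a fixed centred sample pattern, so
#' feature variability (and any rank-one loading) grows linearly in `k`.
#'
#' @return A list: `data` (the `multiomics_set`) and `expected` — hand
#'   enumerated values: `overlap` (exclusive sample-overlap counts),
#'   `mad_alpha_top5` (MAD-prefilter survivors at keep = 5),
#'   `importance_alpha` (importance of each alpha feature on the first
#'   principal axis), `consensus_order` (geometric-consensus ordering of
#'   three designated alpha features).
#' @export
make_worked_fixture <- function() {
  all_samples <- sprintf("s%02d", 1:12)
  pattern <- function(n) seq(-(n - 1) / 2, (n - 1) / 2)   # centred, step 1
  build_block <- function(name, p, samples, prefix) {
    z <- pattern(length(samples))
    m <- outer(seq_len(p), z)
    dimnames(m) <- list(sprintf("%s%02d", prefix, seq_len(p)), samples)
    omics_dataset(name, m)
  }
  alpha <- build_block("alpha", 30, all_samples[1:10], "a")
  beta <- build_block("beta", 20, all_samples[3:12], "b")
  gamma <- build_block("gamma", 10, all_samples, "g")
  ms <- multiomics_set(list(alpha, beta, gamma))

  # Hand enumeration: s01,s02 in alpha+gamma; s11,s12 in beta+gamma;
  # s03..s10 in all three.
  expected_overlap <- tibble::tibble(
    combination = c("alpha+beta+gamma", "alpha+gamma", "beta+gamma"),
    n_samples = c(8L, 2L, 2L)
  )
  # MAD of feature k in alpha: k * median(|z|) with z = -4.5..4.5 -> 2.5k;
  # top 5 are a30..a26 (kept in matrix order).
  expected_mad_top5 <- sprintf("a%02d", 26:30)
  # Rank-one block: first-axis loading proportional to k, so importance is
  # k / 30 for feature k.
  expected_importance_alpha <- tibble::tibble(
    feature_id = sprintf("a%02d", 1:30),
    importance = (1:30) / 30
  )
  list(
    data = ms,
    expected = list(
      overlap = expected_overlap,
      mad_alpha_top5 = expected_mad_top5,
      importance_alpha = expected_importance_alpha,
      consensus_features = c("a30", "a15", "a01"),
      consensus_order = c("a30", "a15", "a01")   # geometric mean of k/30 twice
    )
  )
}
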