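rand_blocks <- function(seed, n = 30, p = 12, q = 7) {
  set.seed(seed)
  list(
    X = matrix(rnorm(n * p), n, p,
               dimnames = list(sprintf("s%02d", 1:n), sprintf("x%02d", 1:p))),
    Y = matrix(rnorm(n * q), n, q,
               dimnames = list(sprintf("s%02d", 1:n), sprintf("y%02d", 1:q)))
  )
}

test_that("dense sPLS component 1 equals the SVD of the cross-covariance", {
  for (seed in 1:3) {
    b <- rand_blocks(seed)
    fit <- spls(b$X, b$Y, ncomp = 1)
    M <- crossprod(scale(b$X), scale(b$Y))
    sv <- svd(M)
    expect_lt(signed_diff(fit$block_loadings$X[, 1], sv$u[, 1]), 1e-6)
    expect_lt(signed_diff(fit$block_loadings$Y[, 1], sv$v[, 1]), 1e-6)
  }
})

test_that("dense sPLS agrees with the mixOmics reference implementation", {
  b <- rand_blocks(42, n = 40, p = 15, q = 8)
  b$Y[, 1] <- b$X[, 1] * 2 + rnorm(40, sd = 0.3)
  ours <- spls(b$X, b$Y, ncomp = 2, mode = "regression")
  ref <- suppressMessages(mixOmics::spls(b$X, b$Y, ncomp = 2,
                                         mode = "regression"))
  for (h in 1:2) {
    expect_lt(signed_diff(ours$block_loadings$X[, h], ref$loadings$X[, h]), 1e-6)
    expect_lt(signed_diff(ours$block_loadings$Y[, h], ref$loadings$Y[, h]), 1e-6)
  }
  # sparse case: identical selected sets
  ours_s <- spls(b$X, b$Y, ncomp = 1, keepX = 3, keepY = 2)
  ref_s <- suppressMessages(mixOmics::spls(b$X, b$Y, ncomp = 1,
                                           keepX = 3, keepY = 2))
  expect_setequal(rownames(ours_s$block_loadings$X)[ours_s$selected$X[, 1]],
                  mixOmics::selectVar(ref_s)$X$name)
})

test_that("the sparsity constraint yields exactly keep non-zero loadings", {
  b <- rand_blocks(7)
  for (k in c(1, 3, 6, 12)) {
    fit <- spls(b$X, b$Y, ncomp = 2, keepX = k, keepY = 4)
    expect_identical(unname(colSums(fit$block_loadings$X != 0)), rep(k, 2))
    expect_identical(unname(colSums(fit$block_loadings$Y != 0)), rep(4, 2))
  }
  expect_error(spls(b$X, b$Y, keepX = 99), "keepX")
  rownames(b$Y) <- rev(rownames(b$Y))
  expect_error(spls(b$X, b$Y), "identical sample IDs")
})

test_that("blocks sharing a latent factor produce correlated component-1 scores", {
  set.seed(15)
  n <- 60
  f <- rnorm(n)
  X <- outer(f, rnorm(50)) + matrix(rnorm(n * 50, sd = 0.5), n, 50)
  Y <- outer(f, rnorm(30)) + matrix(rnorm(n * 30, sd = 0.5), n, 30)
  dimnames(X) <- list(sprintf("s%02d", 1:n), sprintf("x%03d", 1:50))
  dimnames(Y) <- list(sprintf("s%02d", 1:n), sprintf("y%03d", 1:30))
  fit <- spls(X, Y, ncomp = 1, keepX = 10, keepY = 10, mode = "canonical")
  expect_gt(abs(cor(fit$block_scores$X[, 1], fit$block_scores$Y[, 1])), 0.9)
})

test_that("score covariance is non-increasing across components (deflation)", {
  for (seed in 1:3) {
    b <- rand_blocks(seed, n = 25, p = 10, q = 8)
    for (mode in c("regression", "canonical")) {
      fit <- spls(b$X, b$Y, ncomp = 4, mode = mode)
      covs <- fit$diagnostics$cov_explained
      expect_true(all(diff(covs) < 1e-8))
    }
  }
})

test_that("sPLS-DA is exactly sPLS on the centred one-hot outcome", {
  b <- rand_blocks(33, n = 24, p = 10)
  groups <- rep(c("A", "B", "C"), each = 8)
  da <- splsda(b$X, groups, ncomp = 2, keepX = 4)
  onehot <- stats::model.matrix(~ 0 + factor(groups))
  colnames(onehot) <- c("A", "B", "C")
  rownames(onehot) <- rownames(b$X)
  manual <- spls(scale(b$X), scale(onehot, scale = FALSE), ncomp = 2,
                 keepX = 4, keepY = 3, mode = "regression",
                 center = FALSE, scale. = FALSE)
  expect_equal(da$block_loadings$X, manual$block_loadings$X)
  expect_equal(da$sample_scores, manual$block_scores$X)
})

test_that("sPLS-DA finds the single perfectly discriminating feature", {
  # oracle: enumerate every single-feature discriminant, pick the best
  for (seed in 1:3) {
    set.seed(seed)
    n <- 20; p <- 8
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("s%02d", 1:n), sprintf("f%02d", 1:p)))
    groups <- rep(c("A", "B"), each = n / 2)
    x[groups == "B", 5] <- x[groups == "B", 5] + 10   # feature f05 separates
    sep <- apply(scale(x), 2, function(col) abs(cor(col, as.integer(factor(groups)))))
    oracle_best <- names(which.max(sep))
    fit <- splsda(x, groups, ncomp = 1, keepX = 1)
    expect_identical(fit$selected_features, "f05")
    expect_identical(fit$selected_features, oracle_best)
  }
  expect_error(splsda(x, rep("A", 20), ncomp = 1), "two sample groups")
})

test_that("sPLS-DA recalls informative features under a 2-sd group shift", {
  sim <- make_group_shift_data(seed = 101)
  fit <- splsda(sim$x, sim$groups, ncomp = 1, keepX = 10)
  recall <- mean(sim$informative %in% fit$selected_features)
  expect_gte(recall, 0.8)
})

test_that("permuted labels collapse the silhouette towards the null", {
  # Training-data silhouette of a supervised method is inflated under the
  # null by selection overfitting, so the meaningful contract is that the
  # permutation null sits far below the true-label separation.
  sim <- make_group_shift_data(seed = 55)
  sil_of <- function(groups) {
    fit <- splsda(sim$x, groups, ncomp = 1, keepX = 10)
    dr <- to_standard_output(fit)
    mean(silhouette_scores(dr, stats::setNames(groups,
                                               rownames(sim$x)))$samples$silhouette)
  }
  true_sil <- sil_of(sim$groups)
  null_sils <- vapply(1:20, function(rep_i) {
    set.seed(1000 + rep_i)
    sil_of(sample(sim$groups))
  }, numeric(1))
  expect_gt(true_sil, 0.7)
  expect_lt(abs(mean(null_sils)), 0.45)
  expect_gt(true_sil, 2 * abs(mean(null_sils)))
})

test_that("supervised prefiltering retains the informative features", {
  sim <- make_group_shift_data(seed = 77)
  ds <- omics_dataset("rna", t(sim$x))
  kept <- prefilter_supervised(ds, sim$groups, keep = 10, ncomp = 1)
  expect_lte(nrow(kept$matrix), 10)
  expect_gte(mean(sim$informative %in% feature_ids(kept)), 0.8)

  # keep = all features is the identity
  all_kept <- prefilter_supervised(ds, sim$groups, keep = 1.0)
  expect_identical(feature_ids(all_kept), feature_ids(ds))
  expect_error(prefilter_supervised(ds, sim$groups, keep = 1e5), "exceeds")
})

test_that("consensus multi-block PCA reduces to PCA on a single block", {
  ds <- rand_ds("x", p = 20, n = 15, seed = 8)
  ref <- nipals_pca(ds, ncomp = 3, center = TRUE, scale. = TRUE)
  mb <- consensus_mbpca(list(x = t(ds$matrix)), ncomp = 3)
  for (h in 1:3) {
    expect_lt(signed_diff(mb$block_loadings$x[, h], ref$loadings[, h]), 1e-6)
    expect_gt(abs(cor(mb$sample_scores[, h], ref$scores[, h])), 1 - 1e-9)
  }
})

test_that("two identical blocks obtain identical loadings", {
  ds <- rand_ds("x", p = 15, n = 12, seed = 3)
  b <- t(ds$matrix)
  mb <- consensus_mbpca(list(a = b, c = b), ncomp = 2)
  expect_equal(unname(mb$block_loadings$a), unname(mb$block_loadings$c),
               tolerance = 1e-8)
})

test_that("three blocks sharing a factor recover it in global component 1", {
  set.seed(29)
  n <- 50
  f <- rnorm(n)
  blocks <- lapply(c(a = 40, b = 30, c = 20), function(p) {
    m <- outer(f, rnorm(p)) + matrix(rnorm(n * p, sd = 0.3), n, p)
    dimnames(m) <- list(sprintf("s%02d", 1:n),
                        sprintf("f%03d", seq_len(p)))
    m
  })
  mb <- consensus_mbpca(blocks, ncomp = 1)
  expect_gt(abs(cor(mb$sample_scores[, 1], f)), 0.95)
})

test_that("global scores are orthogonal across components", {
  sim <- generate_multiomics(sim_config(seed = 5, k_shared = 2))
  mb <- consensus_mbpca(sim$data, ncomp = 3)
  gram <- crossprod(mb$sample_scores)
  expect_lt(max(abs(gram[upper.tri(gram)])) / max(diag(gram)), 1e-8)
})

test_that("adapters register, run, and enforce result invariants", {
  withr::defer(unregister_adapter("mbpca_alias"))
  withr::defer(unregister_adapter("broken"))
  register_adapter(
    "mbpca_alias",
    prepare = function(ms, ...) ms,
    collect = function(fit) fit
  )
  sim <- generate_multiomics(sim_config(seed = 2))
  res <- run_adapter("mbpca_alias", sim$data,
                     method_fn = function(ms) consensus_mbpca(ms, ncomp = 1))
  expect_s3_class(res, "integration_result")
  expect_error(register_adapter("mbpca_alias", identity, identity),
               "already registered")

  register_adapter(
    "broken",
    prepare = function(ms, ...) ms,
    collect = function(fit) {
      fit$block_loadings[[1]] <- fit$block_loadings[[1]] * 3  # break unit norm
      fit
    }
  )
  expect_error(
    run_adapter("broken", sim$data,
                method_fn = function(ms) consensus_mbpca(ms, ncomp = 1)),
    "unit-norm")
})
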