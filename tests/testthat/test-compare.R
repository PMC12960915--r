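test_that("self-comparison gives unit diagonal, sign flip gives -1", {
  dr <- rand_dr("m1", seed = 1, n = 25, p = 12, ncomp = 3)
  cc <- correlate_results(dr, dr)
  expect_equal(unname(diag(cc$score_corr)), rep(1, 3), tolerance = 1e-12)
  expect_equal(unname(diag(cc$weight_corr)), rep(1, 3), tolerance = 1e-12)

  flipped <- dr
  flipped$feature_weights$weight <- -dr$feature_weights$weight
  flipped$sample_scores$score <- -dr$sample_scores$score
  cc2 <- correlate_results(dr, flipped)
  expect_equal(unname(diag(cc2$score_corr)), rep(-1, 3), tolerance = 1e-12)
  expect_equal(unname(diag(cc2$weight_corr)), rep(-1, 3), tolerance = 1e-12)
})

test_that("correlate_results is symmetric under argument swap", {
  a <- rand_dr("a", seed = 2, ncomp = 2)
  b <- rand_dr("b", seed = 3, ncomp = 3)
  ab <- correlate_results(a, b)
  ba <- correlate_results(b, a)
  expect_equal(ab$score_corr, t(ba$score_corr))
  expect_equal(ab$weight_corr, t(ba$weight_corr))
})

test_that("independent random results correlate like the permutation null", {
  n <- 50
  a <- rand_dr("a", seed = 4, n = n, ncomp = 3)
  b <- rand_dr("b", seed = 5, n = n, ncomp = 3)
  cc <- correlate_results(a, b)
  observed <- as.vector(cc$score_corr)
  # permutation reference for the null correlation distribution
  set.seed(6)
  sa <- omicsweave:::score_matrix(a, a$dimensions)
  sb <- omicsweave:::score_matrix(b, b$dimensions)
  null_r <- replicate(500, cor(sa[sample(n), 1], sb[, 1]))
  expect_lt(max(abs(observed)), max(abs(null_r)) + 0.1)
  ks <- suppressWarnings(stats::ks.test(observed, null_r))
  expect_gt(ks$p.value, 0.01)
})

test_that("insufficient overlap raises an error stating the counts", {
  a <- rand_dr("a", seed = 7, n = 10)
  b <- rand_dr("b", seed = 8, n = 10)
  b$sample_scores$sample_id <- sub("^s", "t", b$sample_scores$sample_id)
  expect_error(correlate_results(a, b), "0 shared sample")
})

test_that("duplicated results cluster their matching dimensions together", {
  dr <- rand_dr("base", seed = 9, ncomp = 3)
  results <- list(m1 = dr, m2 = dr, m3 = dr)
  results <- lapply(names(results), function(nm) {
    out <- results[[nm]]; out$method <- nm; out
  })
  names(results) <- c("m1", "m2", "m3")
  hm <- cluster_correlations(compare_all(results))
  expect_identical(sort(hm$labels),
                   sort(as.vector(outer(c("m1", "m2", "m3"),
                                        paste("Component", 1:3),
                                        paste, sep = "/"))))
  # each dimension's three instances must be adjacent in leaf order
  dim_of <- sub("^m[0-9]/", "", hm$labels)
  runs <- rle(dim_of)
  expect_identical(unname(runs$lengths), rep(3L, 3))
})

test_that("matched dimensions across two constructed methods sit adjacent", {
  set.seed(10)
  a <- rand_dr("ma", seed = 11, n = 30, ncomp = 3)
  b <- a
  b$method <- "mb"
  # dims 1,2 match (sign-flipped copy + tiny noise), dim 3 independent
  sb <- omicsweave:::score_matrix(a, a$dimensions)
  sb[, 1] <- -sb[, 1] + rnorm(30, sd = 0.05)
  sb[, 2] <- sb[, 2] + rnorm(30, sd = 0.05)
  sb[, 3] <- rnorm(30)
  b$sample_scores$score <- as.vector(sb)
  hm <- cluster_correlations(compare_all(list(ma = a, mb = b)))
  pos <- stats::setNames(seq_along(hm$labels), hm$labels)
  expect_equal(abs(pos[["ma/Component 1"]] - pos[["mb/Component 1"]]), 1)
  expect_equal(abs(pos[["ma/Component 2"]] - pos[["mb/Component 2"]]), 1)
  # missing pairwise comparison is an error
  partial <- compare_all(list(ma = a, mb = b))
  partial[["ma vs mb"]] <- NULL
  expect_error(cluster_correlations(partial), "missing pairwise")
})

test_that("match_dimensions recovers permutations and honours the threshold", {
  a <- rand_dr("a", seed = 12, n = 40, ncomp = 4)
  self <- match_dimensions(correlate_results(a, a), threshold = 0.9)
  expect_identical(self$dim_a, self$dim_b)
  expect_equal(self$r_scores, rep(1, 4), tolerance = 1e-12)

  # permuted copy: greedy pairing recovers the permutation
  perm <- c(3, 1, 4, 2)
  b <- a
  b$method <- "b"
  sa <- omicsweave:::score_matrix(a, a$dimensions)
  b$sample_scores$score <- as.vector(sa[, perm])
  got <- match_dimensions(correlate_results(a, b), threshold = 0.9)
  expect_identical(nrow(got), 4L)
  mapping <- stats::setNames(got$dim_b, got$dim_a)
  for (j in 1:4) {
    expect_identical(mapping[[paste("Component", perm[j])]],
                     paste("Component", j))
  }

  # nothing above threshold -> empty
  c_dr <- rand_dr("c", seed = 13, n = 40, ncomp = 4)
  none <- match_dimensions(correlate_results(a, c_dr), threshold = 0.99)
  expect_identical(nrow(none), 0L)
})

test_that("consensus aggregators hit their closed forms", {
  imp_of <- function(vals) {
    tab <- tibble::tibble(feature_id = names(vals), dataset = "d",
                          dimension = "Component 1", weight = vals,
                          importance = vals)
    structure(tab, class = c("importance_table", class(tab)))
  }
  ones <- c(fa = 1, fb = 1)
  tabs <- list(m1 = imp_of(ones), m2 = imp_of(ones), m3 = imp_of(ones))
  for (f in c("average", "geometric", "harmonic", "product")) {
    out <- consensus_importance(tabs, "Component 1", aggregation = f)
    expect_equal(out$consensus, c(1, 1))
  }
  l2 <- consensus_importance(tabs, "Component 1", aggregation = "l2")
  expect_equal(l2$consensus, rep(sqrt(3), 2))

  # 3-4-5 triangle
  duo <- list(m1 = imp_of(c(fa = 0.6)), m2 = imp_of(c(fa = 0.8)))
  expect_equal(consensus_importance(duo, "Component 1",
                                    aggregation = "l2")$consensus, 1.0)

  # zero anywhere collapses the stringent aggregators
  z <- list(m1 = imp_of(c(fa = 0, fb = 0.5)), m2 = imp_of(c(fa = 1, fb = 0.5)))
  for (f in c("geometric", "harmonic", "product")) {
    out <- consensus_importance(z, "Component 1", aggregation = f)
    expect_identical(out$consensus[out$feature_id == "fa"], 0)
  }
})

test_that("aggregator inequalities hold on random positive vectors", {
  set.seed(14)
  for (i in 1:50) {
    j <- sample(2:5, 1)
    m <- matrix(runif(j * 8, 0.01, 1), 8, j)
    agg <- omicsweave:::consensus_aggregators
    harm <- agg$harmonic(m); geom <- agg$geometric(m)
    avg <- agg$average(m); l2 <- agg$l2(m)
    expect_true(all(harm <= geom + 1e-12))
    expect_true(all(geom <= avg + 1e-12))
    expect_true(all(avg <= apply(m, 1, max) + 1e-12))
    expect_true(all(apply(m, 1, max) <= l2 + 1e-12))
    expect_true(all(l2 <= sqrt(j) * apply(m, 1, max) + 1e-12))
  }
})

test_that("geometric favours consistent features, l2 favours spikes", {
  imp_of <- function(vals) {
    tab <- tibble::tibble(feature_id = names(vals), dataset = "d",
                          dimension = "Component 1", weight = vals,
                          importance = vals)
    structure(tab, class = c("importance_table", class(tab)))
  }
  tabs <- list(m1 = imp_of(c(consistent = 0.7, spiky = 1.0)),
               m2 = imp_of(c(consistent = 0.7, spiky = 0.2)))
  geom <- consensus_importance(tabs, "Component 1", aggregation = "geometric")
  l2 <- consensus_importance(tabs, "Component 1", aggregation = "l2")
  expect_identical(geom$feature_id[1], "consistent")
  expect_identical(l2$feature_id[1], "spiky")
})

test_that("consensus is symmetric in method order and validates inputs", {
  a <- compute_importance(rand_dr("a", seed = 15, ncomp = 2,
                                  datasets = c("d1", "d2")))
  b <- compute_importance(rand_dr("b", seed = 16, ncomp = 2,
                                  datasets = c("d1", "d2")))
  ab <- consensus_importance(list(ma = a, mb = b), "Component 1")
  ba <- consensus_importance(list(mb = b, ma = a), "Component 1")
  expect_equal(ab$consensus, ba$consensus)
  expect_identical(ab$feature_id, ba$feature_id)

  expect_error(consensus_importance(list(ma = a, mb = b), "Component 9"),
               "absent")
  expect_error(consensus_importance(list(ma = a, mb = b), "Component 1",
                                    aggregation = "median"), "arg")
})
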