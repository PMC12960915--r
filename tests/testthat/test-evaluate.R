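cluster_dr <- function(seed = 1, n_per = 10, centers = list(c(0, 0), c(10, 10)),
                       sd = 0.1) {
  set.seed(seed)
  scores <- do.call(rbind, lapply(centers, function(ctr) {
    cbind(rnorm(n_per, ctr[1], sd), rnorm(n_per, ctr[2], sd))
  }))
  rownames(scores) <- sprintf("s%03d", seq_len(nrow(scores)))
  w <- list(d1 = matrix(rnorm(6), 3, 2,
                        dimnames = list(c("f1", "f2", "f3"), NULL)))
  groups <- rep(paste0("g", seq_along(centers)), each = n_per)
  list(dr = make_dr("toy", w, scores),
       groups = stats::setNames(groups, rownames(scores)))
}

test_that("well-separated clusters earn silhouette close to 1", {
  cd <- cluster_dr()
  sil <- silhouette_scores(cd$dr, cd$groups)
  expect_gt(mean(sil$samples$silhouette), 0.9)
  expect_identical(sort(unique(sil$samples$neighbor)), c("g1", "g2"))
})

test_that("silhouette equals the brute-force oracle on random instances", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(10:50, 1)
    k <- sample(2:4, 1)
    scores <- matrix(rnorm(n * 2), n, 2,
                     dimnames = list(sprintf("s%03d", 1:n), NULL))
    groups <- sample(paste0("g", 1:k), n, replace = TRUE)
    # ensure at least two non-empty groups
    groups[1:2] <- c("g1", "g2")
    w <- list(d = matrix(rnorm(4), 2, 2, dimnames = list(c("fa", "fb"), NULL)))
    dr <- make_dr("toy", w, scores)
    sil <- silhouette_scores(dr, stats::setNames(groups, rownames(scores)))
    oracle <- brute_silhouette(scores, groups)
    expect_equal(sil$samples$silhouette, unname(oracle), tolerance = 1e-10)
  }
})

test_that("singleton groups score zero and degenerate groupings error", {
  cd <- cluster_dr()
  g <- cd$groups
  g[1] <- "lonely"
  sil <- silhouette_scores(cd$dr, g)
  expect_identical(sil$samples$silhouette[1], 0)
  expect_error(silhouette_scores(cd$dr, stats::setNames(rep("g", 20),
                                                        names(cd$groups))),
               "two groups")
  expect_error(silhouette_scores(cd$dr, cd$groups, dimensions = "Blah"),
               "unknown dimension")
})

de_fixture <- function() {
  # DE features carry twice the weight of the others
  p <- 20
  ids <- sprintf("f%02d", 1:p)
  de <- rep(c(TRUE, FALSE), each = p / 2)
  w <- ifelse(de, 2, 1) * (1 + 0.01 * seq_len(p))
  wm <- list(rna = matrix(w, p, 1, dimnames = list(ids, NULL)))
  scores <- matrix(rnorm(6), 6, 1, dimnames = list(paste0("s", 1:6), NULL))
  dr <- make_dr("toy", wm, scores, dims = "Component 1")
  ds <- make_ds("rna", p = p, n = 6, features = ids)
  ds <- attach_metadata(ds, data.frame(feature_id = ids, de = de,
                                       fold = abs(w)), axis = "features")
  list(dr = dr, ms = multiomics_set(list(ds)), de = de)
}

test_that("weights_vs_label joins labels and reports numeric correlations", {
  fx <- de_fixture()
  tab <- weights_vs_label(fx$dr, fx$ms, "rna", "Component 1", "de")
  expect_gt(mean(tab$importance[tab$label]), mean(tab$importance[!tab$label]))

  # numeric label equal to |weight| correlates perfectly with importance
  tab_f <- weights_vs_label(fx$dr, fx$ms, "rna", "Component 1", "fold")
  expect_equal(attr(tab_f, "correlation"), 1.0, tolerance = 1e-12)

  # constant label: correlation undefined
  ds2 <- attach_metadata(get_dataset(fx$ms, "rna"),
                         data.frame(feature_id = sprintf("f%02d", 1:20),
                                    konst = 1), axis = "features")
  ms2 <- multiomics_set(list(ds2))
  tab_k <- weights_vs_label(fx$dr, ms2, "rna", "Component 1", "konst")
  expect_true(is.na(attr(tab_k, "correlation")))

  expect_error(weights_vs_label(fx$dr, fx$ms, "rna", "Component 1", "zzz"),
               "zzz")
})

test_that("selected_vs_label cross-tabulates with conserved margins", {
  p <- 100
  ids <- sprintf("f%03d", 1:p)
  w <- numeric(p)
  w[1:10] <- 1                       # 10 selected
  labeled <- c(1:8, 50, 51)          # overlap with selection = 8
  lab <- ids %in% ids[labeled]
  wm <- list(rna = matrix(w, p, 1, dimnames = list(ids, NULL)))
  dr <- make_dr("toy", wm, matrix(rnorm(4), 4, 1,
                                  dimnames = list(paste0("s", 1:4), NULL)),
                dims = "Component 1")
  ds <- make_ds("rna", p = p, n = 4, features = ids)
  ds <- attach_metadata(ds, data.frame(feature_id = ids, de = lab),
                        axis = "features")
  ms <- multiomics_set(list(ds))
  tab <- selected_vs_label(dr, ms, "rna", "de")
  expect_identical(tab["TRUE", "TRUE"], 8L)
  expect_identical(sum(tab), as.integer(p))
  expect_identical(unname(rowSums(tab)), c(90, 10))

  # dense method: everything selected, with a warning
  wm2 <- list(rna = matrix(rnorm(p), p, 1, dimnames = list(ids, NULL)))
  dr2 <- make_dr("toy", wm2, matrix(rnorm(4), 4, 1,
                                    dimnames = list(paste0("s", 1:4), NULL)),
                 dims = "Component 1")
  expect_warning(tab2 <- selected_vs_label(dr2, ms, "rna", "de"),
                 "no feature selection")
  expect_identical(unname(rowSums(tab2)), 100)
})

importance_fixture <- function(member_ids, background_ids, member_mean = 0.8,
                               bg_mean = 0.2, sd = 0.1, seed = 1) {
  set.seed(seed)
  ids <- c(member_ids, background_ids)
  imp_vals <- c(pmin(pmax(rnorm(length(member_ids), member_mean, sd), 0), 1),
                pmin(pmax(rnorm(length(background_ids), bg_mean, sd), 0), 1))
  tab <- tibble::tibble(feature_id = ids, dataset = "rna",
                        dimension = "Component 1",
                        weight = imp_vals, importance = imp_vals)
  structure(tab, class = c("importance_table", class(tab)))
}

test_that("enrichment equals a direct Welch t-test and flags a shifted set", {
  members <- sprintf("m%03d", 1:20)
  background <- sprintf("b%03d", 1:480)
  imp <- importance_fixture(members, background)
  sets <- make_feature_sets(data.frame(feature_id = members, set_id = "S1"))
  res <- enrich_sets(imp, "Component 1", "rna", sets, alternative = "greater")
  oracle <- stats::t.test(imp$importance[imp$feature_id %in% members],
                          imp$importance[!imp$feature_id %in% members],
                          alternative = "greater", var.equal = FALSE)
  expect_equal(res$statistic, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, oracle$p.value, tolerance = 1e-12)
  expect_lt(res$p_value, 1e-6)
  expect_identical(res$n_features, 20L)
})

test_that("sets are matched to the background and small sets excluded", {
  imp <- importance_fixture(sprintf("m%03d", 1:10), sprintf("b%03d", 1:90))
  sets <- make_feature_sets(data.frame(
    feature_id = c(sprintf("m%03d", 1:10), "m001", "ghost1", "ghost2"),
    set_id = c(rep("big", 10), "tiny", "tiny", "unmatched")))
  res <- enrich_sets(imp, "Component 1", "rna", sets, min_size = 2)
  expect_identical(res$set_id, "big")
  excluded <- attr(res, "excluded_sets")
  expect_setequal(excluded$set_id, c("tiny", "unmatched"))
  sets_all_small <- make_feature_sets(data.frame(feature_id = "m001",
                                                 set_id = "solo"))
  expect_error(enrich_sets(imp, "Component 1", "rna", sets_all_small),
               "excluded")
})

test_that("p-values are invariant to relabeling non-member features", {
  members <- sprintf("m%03d", 1:15)
  background <- sprintf("b%03d", 1:85)
  imp <- importance_fixture(members, background, member_mean = 0.5,
                            bg_mean = 0.4)
  sets1 <- make_feature_sets(data.frame(
    feature_id = c(members, sprintf("b%03d", 1:20)),
    set_id = c(rep("target", 15), rep("other", 20))))
  sets2 <- make_feature_sets(data.frame(
    feature_id = c(members, sprintf("b%03d", 40:59)),
    set_id = c(rep("target", 15), rep("other", 20))))
  p1 <- enrich_sets(imp, "Component 1", "rna", sets1)
  p2 <- enrich_sets(imp, "Component 1", "rna", sets2)
  expect_identical(p1$p_value[p1$set_id == "target"],
                   p2$p_value[p2$set_id == "target"])
})

test_that("BH adjustment is monotone in raw p and bounded by 1", {
  set.seed(9)
  ids <- sprintf("f%03d", 1:200)
  imp <- importance_fixture(character(), ids, bg_mean = 0.5, sd = 0.15)
  membership <- dplyr::bind_rows(lapply(1:30, function(i) {
    tibble::tibble(feature_id = sample(ids, 15), set_id = sprintf("S%02d", i))
  }))
  res <- enrich_sets(imp, "Component 1", "rna",
                     make_feature_sets(membership), alternative = "two.sided")
  expect_true(all(res$adj_p_value >= res$p_value - 1e-15))
  expect_true(all(diff(res$adj_p_value) >= -1e-15))   # sorted by raw p
  expect_lte(max(res$adj_p_value), 1)
  expect_equal(res$adj_p_value,
               stats::p.adjust(res$p_value, method = "BH"))
})

test_that("feature sets can be extracted from delimited metadata columns", {
  ds <- make_ds("rna", p = 4, n = 2)
  ds <- attach_metadata(ds, data.frame(
    feature_id = sprintf("f%02d", 1:4),
    go = c("GO:1;GO:2", "GO:1", NA, "GO:2")), axis = "features")
  fs <- feature_sets_from_metadata(ds, "go")
  expect_setequal(names(fs$sets), c("GO:1", "GO:2"))
  expect_setequal(fs$sets[["GO:1"]], c("f01", "f02"))
  expect_setequal(fs$sets[["GO:2"]], c("f01", "f04"))
})
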