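# Independent oracles and small fixture builders shared across tests.

# Brute-force silhouette: direct transcription of the definition, one pairwise
# distance at a time. Singleton groups score 0.
brute_silhouette <- function(scores, groups) {
  groups <- as.character(groups)
  n <- nrow(scores)
  d <- as.matrix(stats::dist(scores))
  vapply(seq_len(n), function(i) {
    own <- which(groups == groups[i])
    if (length(own) == 1) return(0)
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(groups), groups[i]), function(g) {
      mean(d[i, groups == g])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

# Brute-force exclusive overlap counts: enumerate the union element by element.
brute_overlap <- function(sets) {
  all_ids <- unique(unlist(sets))
  sig <- vapply(all_ids, function(id) {
    paste(names(sets)[vapply(sets, function(s) id %in% s, logical(1))],
          collapse = "+")
  }, character(1))
  as.list(table(sig))
}

# Quick dataset builder around a matrix (default: deterministic values).
make_ds <- function(name = "ds", p = 4, n = 3, values = NULL,
                    features = sprintf("f%02d", seq_len(p)),
                    samples = sprintf("s%02d", seq_len(n))) {
  m <- matrix(values %||% seq_len(p * n), p, n,
              dimnames = list(features, samples))
  omicsweave::omics_dataset(name, m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random gaussian dataset with sample/feature names.
rand_ds <- function(name, p, n, seed, missing_rate = 0, prefix = "f") {
  set.seed(seed)
  m <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(p)),
                              sprintf("s%03d", seq_len(n))))
  if (missing_rate > 0) m[runif(p * n) < missing_rate] <- NA
  omicsweave::omics_dataset(name, m)
}

# Build a dimension_reduction directly from weight/score matrices.
make_dr <- function(method, weights, scores,
                    dims = paste("Component", seq_len(ncol(scores)))) {
  fw <- dplyr::bind_rows(lapply(names(weights), function(nm) {
    L <- weights[[nm]]
    tibble::tibble(feature_id = rep(rownames(L), ncol(L)), dataset = nm,
                   dimension = rep(dims, each = nrow(L)),
                   weight = as.vector(L))
  }))
  ss <- tibble::tibble(sample_id = rep(rownames(scores), ncol(scores)),
                       dimension = rep(dims, each = nrow(scores)),
                       score = as.vector(scores))
  omicsweave:::new_dimension_reduction(method, fw, ss, dims)
}

rand_dr <- function(method, seed, n = 20, p = 10, ncomp = 2,
                    datasets = "d1") {
  set.seed(seed)
  weights <- lapply(stats::setNames(datasets, datasets), function(nm) {
    L <- matrix(rnorm(p * ncomp), p, ncomp,
                dimnames = list(sprintf("%s_f%03d", nm, seq_len(p)), NULL))
    sweep(L, 2, sqrt(colSums(L^2)), "/")
  })
  scores <- matrix(rnorm(n * ncomp), n, ncomp,
                   dimnames = list(sprintf("s%03d", seq_len(n)), NULL))
  make_dr(method, weights, scores)
}

# Align the sign of vector a to b, then report max abs difference.
signed_diff <- function(a, b) {
  s <- if (sum(a * b) < 0) -1 else 1
  max(abs(a * s - b))
}

# Simulation used by the sPLS-DA selection checks: two groups, `n_info`
# informative features shifted by `shift` standard deviations.
make_group_shift_data <- function(seed, n = 60, p = 200, n_info = 10,
                                  shift = 2) {
  set.seed(seed)
  groups <- rep(c("A", "B"), each = n / 2)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%03d", 1:n), sprintf("f%03d", 1:p)))
  info <- sample(p, n_info)
  x[groups == "B", info] <- x[groups == "B", info] + shift
  list(x = x, groups = groups, informative = colnames(x)[info])
}
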