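#' @keywords internal
# Center/scale a samples x features block; returns the processed matrix.
process_block <- function(x, center = TRUE, scale. = TRUE) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (any(is.na(x))) {
    stop("integration methods require complete data; impute missing values first",
         call. = FALSE)
  }
  if (center || scale.) {
    ctr <- if (center) colMeans(x) else FALSE
    scl <- if (scale.) apply(x, 2, stats::sd) else FALSE
    if (scale. && any(scl == 0)) {
      stop(sprintf("cannot scale zero-variance feature(s): %s",
                   paste(utils::head(colnames(x)[scl == 0], 5), collapse = ", ")),
           call. = FALSE)
    }
    x <- scale(x, center = ctr, scale = scl)
    attr(x, "scaled:center") <- NULL
    attr(x, "scaled:scale") <- NULL
  }
  x
}

# Coerce an omics_dataset (features x samples) or matrix to samples x features.
as_block <- function(x) {
  if (inherits(x, "omics_dataset")) t(x$matrix) else x
}

# Keep exactly `keep` non-zero entries by soft-thresholding at the magnitude
# of the (keep+1)-th largest |value|; ties at the cutoff are resolved by index
# order. The vector is then renormalised to unit norm.
soft_threshold_keep <- function(v, keep) {
  p <- length(v)
  if (keep >= p) return(v / sqrt(sum(v^2)))
  ord <- order(-abs(v), seq_along(v))
  kept <- ord[seq_len(keep)]
  lambda <- max(abs(v[ord[(keep + 1):p]]))
  out <- numeric(p)
  out[kept] <- sign(v[kept]) * (abs(v[kept]) - lambda)
  if (all(out == 0)) {
    # degenerate ties at the cutoff: fall back to hard truncation
    out[kept] <- v[kept]
  }
  out / sqrt(sum(out^2))
}

new_integration_result <- function(method, ncomp, block_loadings, block_scores,
                                   sample_scores, selected, diagnostics,
                                   dim_prefix = "Component", extras = list()) {
  res <- structure(
    c(list(method = method, ncomp = ncomp, block_loadings = block_loadings,
           block_scores = block_scores, sample_scores = sample_scores,
           selected = selected, diagnostics = diagnostics,
           dim_prefix = dim_prefix),
      extras),
    class = "integration_result"
  )
  validate_integration_result(res)
}

#' Validate a raw integration result
#'
#' Checks the structural invariants every integration method (native or
#' adapter-provided) must satisfy: unit-norm loading columns per dataset, and
#' selected-feature masks whose cardinality matches the non-zero loadings.
#'
#' @param res An `integration_result`.
#' @return `res`, invisibly-valid.
#' @export
validate_integration_result <- function(res) {
  stopifnot(inherits(res, "integration_result"))
  for (nm in names(res$block_loadings)) {
    L <- res$block_loadings[[nm]]
    norms <- sqrt(colSums(L^2))
    if (any(abs(norms - 1) > 1e-6 & norms > 0)) {
      stop(sprintf("loading columns of dataset '%s' are not unit-norm", nm),
           call. = FALSE)
    }
    sel <- res$selected[[nm]]
    if (!is.null(sel) && !identical(dim(sel), dim(L))) {
      stop(sprintf("selection mask of dataset '%s' has wrong shape", nm),
           call. = FALSE)
    }
  }
  n_scores <- nrow(res$sample_scores)
  for (nm in names(res$block_scores)) {
    if (ncol(res$block_scores[[nm]]) != res$ncomp) {
      stop("block score component count mismatch", call. = FALSE)
    }
  }
  if (ncol(res$sample_scores) != res$ncomp) {
    stop("sample score component count mismatch", call. = FALSE)
  }
  res
}

#' @export
print.integration_result <- function(x, ...) {
  cat(sprintf("<integration_result> %s: %d component(s), blocks: %s\n",
              x$method, x$ncomp, paste(names(x$block_loadings), collapse = ", ")))
  invisible(x)
}

#' Two-block sparse partial least squares
#'
#' For each component the dominant singular pair of the cross-covariance
#' matrix `t(X) %*% Y` is found by alternating iteration; sparsity is
#' enforced by soft-thresholding each loading vector so that exactly the
#' requested number of entries is non-zero (the threshold is the magnitude of
#' the first discarded entry, preserving relative magnitudes among survivors).
#' Blocks are deflated between components: in `regression` mode both blocks
#' are deflated on the X scores, in `canonical` mode each block on its own
#' scores. The sign convention makes the largest absolute X-loading entry of
#' each component positive.
#'
#' @param X,Y Numeric matrices, samples x features, with identical row
#'   (sample) names in identical order, or `omics_dataset` objects (which are
#'   transposed internally). Data must be complete.
#' @param ncomp Number of components.
#' @param keepX,keepY Number of features with non-zero loadings per
#'   component; either a scalar (recycled) or a vector of length `ncomp`.
#'   Default: all features (dense PLS).
#' @param mode `"regression"` or `"canonical"`.
#' @param center,scale. Column centring/unit-variance scaling applied to both
#'   blocks before fitting (defaults `TRUE`, as is conventional for PLS on
#'   heterogeneous omics scales).
#' @param tol,max_iter Convergence control for the alternating iteration.
#' @param names Length-2 character vector naming the two blocks in the
#'   result.
#'
#' @return An `integration_result` with per-block unit-norm `block_loadings`,
#'   per-block `block_scores`, joint `sample_scores` (the average of the two
#'   block scores), per-block `selected` masks, and a `diagnostics` table
#'   with the absolute score covariance explained per component.
#' @export
spls <- function(X, Y, ncomp = 2, keepX = NULL, keepY = NULL,
                 mode = c("regression", "canonical"),
                 center = TRUE, scale. = TRUE, tol = 1e-9, max_iter = 500,
                 names = c("X", "Y")) {
  mode <- match.arg(mode)
  X <- as_block(X); Y <- as_block(Y)
  if (is.null(rownames(X)) || is.null(rownames(Y)) ||
      !identical(rownames(X), rownames(Y))) {
    stop("X and Y must share identical sample IDs in identical order",
         call. = FALSE)
  }
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (ncomp < 1 || ncomp > min(n - 1, p, q)) {
    stop(sprintf("ncomp must be in [1, %d]", min(n - 1, p, q)), call. = FALSE)
  }
  keepX <- check_keep(keepX, p, ncomp, "keepX")
  keepY <- check_keep(keepY, q, ncomp, "keepY")
  Xc <- process_block(X, center, scale.)
  Yc <- process_block(Y, center, scale.)

  dims <- paste0("comp", seq_len(ncomp))
  LX <- matrix(0, p, ncomp, dimnames = list(colnames(X), dims))
  LY <- matrix(0, q, ncomp, dimnames = list(colnames(Y), dims))
  TX <- matrix(0, n, ncomp, dimnames = list(rownames(X), dims))
  TY <- matrix(0, n, ncomp, dimnames = list(rownames(X), dims))
  covs <- numeric(ncomp)

  for (h in seq_len(ncomp)) {
    M <- crossprod(Xc, Yc)                      # p x q
    u <- M[, which.max(colSums(M^2))]
    if (sum(u^2) == 0) u <- M[, 1] + 1e-12
    u <- u / sqrt(sum(u^2))
    v <- NULL
    iter <- 0L
    repeat {
      iter <- iter + 1L
      v <- soft_threshold_keep(as.vector(crossprod(M, u)), keepY[h])
      u_new <- soft_threshold_keep(as.vector(M %*% v), keepX[h])
      delta <- sqrt(sum((u_new - u)^2))
      u <- u_new
      if (delta < tol || iter >= max_iter) break
    }
    s <- sign(u[which.max(abs(u))])
    u <- u * s; v <- v * s
    tvec <- as.vector(Xc %*% u)
    svec <- as.vector(Yc %*% v)
    covs[h] <- abs(stats::cov(tvec, svec))
    # deflation
    cx <- as.vector(crossprod(Xc, tvec)) / sum(tvec^2)
    Xc <- Xc - tcrossprod(tvec, cx)
    if (mode == "regression") {
      dy <- as.vector(crossprod(Yc, tvec)) / sum(tvec^2)
      Yc <- Yc - tcrossprod(tvec, dy)
    } else {
      ey <- as.vector(crossprod(Yc, svec)) / sum(svec^2)
      Yc <- Yc - tcrossprod(svec, ey)
    }
    LX[, h] <- u; LY[, h] <- v; TX[, h] <- tvec; TY[, h] <- svec
  }

  block_loadings <- stats::setNames(list(LX, LY), names)
  block_scores <- stats::setNames(list(TX, TY), names)
  selected <- stats::setNames(list(LX != 0, LY != 0), names)
  new_integration_result(
    method = "spls", ncomp = ncomp,
    block_loadings = block_loadings, block_scores = block_scores,
    sample_scores = (TX + TY) / 2, selected = selected,
    diagnostics = tibble::tibble(component = dims, cov_explained = covs),
    extras = list(mode = mode, keepX = keepX, keepY = keepY)
  )
}

check_keep <- function(keep, width, ncomp, what) {
  if (is.null(keep)) keep <- width
  keep <- as.integer(keep)
  if (length(keep) == 1L) keep <- rep(keep, ncomp)
  if (length(keep) != ncomp) {
    stop(sprintf("%s must have length 1 or ncomp", what), call. = FALSE)
  }
  if (any(keep < 1 | keep > width)) {
    stop(sprintf("%s entries must be in [1, %d]", what, width), call. = FALSE)
  }
  keep
}

#' Sparse PLS discriminant analysis
#'
#' Exactly [spls()] in regression mode with the outcome block set to the
#' centred one-hot indicator matrix of the sample groups (no sparsity on the
#' outcome side). Used both for supervised integration and for supervised
#' prefiltering.
#'
#' @param X Samples x features matrix (or `omics_dataset`), complete.
#' @param groups Factor or character vector of group labels, one per sample
#'   (>= 2 groups, each with >= 2 samples).
#' @param ncomp Number of components.
#' @param keepX Non-zero X loadings per component (scalar or vector).
#' @param center,scale. Preprocessing of `X` (defaults `TRUE`).
#' @param ... Passed to [spls()].
#' @return An `integration_result` (method `"splsda"`); `sample_scores` are
#'   the X-block scores. The union of features selected across components is
#'   in `selected_features`.
#' @export
splsda <- function(X, groups, ncomp = 1, keepX = NULL, center = TRUE,
                   scale. = TRUE, ...) {
  X <- as_block(X)
  groups <- as.factor(groups)
  if (length(groups) != nrow(X)) {
    stop("`groups` must have one label per sample", call. = FALSE)
  }
  if (nlevels(droplevels(groups)) < 2) {
    stop("at least two sample groups are required", call. = FALSE)
  }
  if (any(table(groups) < 2)) {
    stop("every group needs at least two samples", call. = FALSE)
  }
  Yd <- stats::model.matrix(~ 0 + groups)
  colnames(Yd) <- levels(groups)
  rownames(Yd) <- rownames(X)
  Yd <- scale(Yd, center = TRUE, scale = FALSE)
  Xp <- process_block(X, center, scale.)
  res <- spls(Xp, Yd, ncomp = ncomp, keepX = keepX, keepY = ncol(Yd),
              mode = "regression", center = FALSE, scale. = FALSE,
              names = c("X", "outcome"), ...)
  res$method <- "splsda"
  res$sample_scores <- res$block_scores$X
  res$groups <- groups
  res$selected_features <- rownames(res$block_loadings$X)[
    rowSums(res$selected$X) > 0]
  validate_integration_result(res)
}

#' Supervised feature prefiltering via sPLS-DA
#'
#' Runs [splsda()] with per-component keep counts of roughly `keep / ncomp`
#' and retains the union of features selected across components (so the
#' retained count is approximately, never more than `ceiling(keep / ncomp) *
#' ncomp`). Deterministic: the fit has no random element.
#'
#' @param ds An `omics_dataset` (complete data).
#' @param groups Group label per sample of `ds`.
#' @param keep Target number (> 1) or fraction (in (0, 1]) of features.
#' @param ncomp Components used for selection (default 1).
#' @param ... Passed to [splsda()].
#' @return The prefiltered `omics_dataset` (original feature order).
#' @export
prefilter_supervised <- function(ds, groups, keep, ncomp = 1, ...) {
  validate_omics_dataset(ds)
  k <- resolve_keep(keep, nrow(ds$matrix))
  if (k == nrow(ds$matrix)) return(ds)
  per_comp <- ceiling(k / ncomp)
  fit <- splsda(ds, groups, ncomp = ncomp, keepX = per_comp, ...)
  retained <- feature_ids(ds)[feature_ids(ds) %in% fit$selected_features]
  subset_dataset(ds, features = retained)
}

#' Consensus multi-block PCA
#'
#' A native multi-block dimension reduction: per component, a global score
#' vector is found by multi-block NIPALS (consensus PCA with super-score
#' normalisation), maximising the summed squared covariances between the
#' global score and each block's scores. Block loadings are unit-norm and
#' every block is deflated on the global score, making global scores
#' orthogonal across components. With a single block this reduces exactly to
#' PCA.
#'
#' @param blocks Named list of samples x features matrices (or
#'   `omics_dataset`s, or a `multiomics_set`) sharing identical sample order;
#'   complete data.
#' @param ncomp Number of components.
#' @param center,scale. Per-block column centring/scaling (defaults `TRUE`).
#' @param tol,max_iter Convergence control.
#' @return An `integration_result` (method `"consensus_mbpca"`):
#'   `sample_scores` hold the global scores, `block_scores`/`block_loadings`
#'   the per-block quantities, and `diagnostics` the summed squared
#'   block-score covariances per component.
#' @export
consensus_mbpca <- function(blocks, ncomp = 2, center = TRUE, scale. = TRUE,
                            tol = 1e-9, max_iter = 500) {
  if (inherits(blocks, "multiomics_set")) {
    blocks <- lapply(blocks$datasets, identity)
  }
  blocks <- lapply(blocks, as_block)
  if (is.null(names(blocks)) || any(!nzchar(names(blocks)))) {
    names(blocks) <- paste0("block", seq_along(blocks))
  }
  sample_sets <- lapply(blocks, rownames)
  if (length(unique(sample_sets)) != 1) {
    stop("all blocks must share identical sample IDs in identical order; ",
         "use subset_common_samples() first", call. = FALSE)
  }
  n <- nrow(blocks[[1]])
  if (ncomp < 1 || ncomp > min(n - 1, vapply(blocks, ncol, 0L))) {
    stop("ncomp exceeds the rank permitted by the smallest block", call. = FALSE)
  }
  Xc <- lapply(blocks, process_block, center = center, scale. = scale.)
  K <- length(Xc)
  dims <- paste0("comp", seq_len(ncomp))
  loadings <- lapply(Xc, function(b)
    matrix(0, ncol(b), ncomp, dimnames = list(colnames(b), dims)))
  bscores <- lapply(Xc, function(b)
    matrix(0, n, ncomp, dimnames = list(rownames(b), dims)))
  gscores <- matrix(0, n, ncomp, dimnames = list(rownames(blocks[[1]]), dims))
  ssq <- numeric(ncomp)

  for (h in seq_len(ncomp)) {
    sums <- vapply(Xc, function(b) sum(b^2), 0)
    lead <- Xc[[which.max(sums)]]
    tg <- lead[, which.max(colSums(lead^2))]
    iter <- 0L
    repeat {
      iter <- iter + 1L
      P <- vector("list", K); Tb <- matrix(0, n, K)
      for (k in seq_len(K)) {
        pk <- as.vector(crossprod(Xc[[k]], tg))
        pk <- pk / sqrt(sum(pk^2))
        P[[k]] <- pk
        Tb[, k] <- Xc[[k]] %*% pk
      }
      w <- as.vector(crossprod(Tb, tg))
      w <- w / sqrt(sum(w^2))
      t_new <- as.vector(Tb %*% w)
      t_new <- t_new / sqrt(sum(t_new^2)) * sqrt(sum(tg^2))
      delta <- sqrt(sum((t_new - tg)^2)) / sqrt(sum(t_new^2))
      tg <- t_new
      if (delta < tol || iter >= max_iter) break
    }
    # sign convention: largest |loading| entry of the first block positive
    p1 <- as.vector(crossprod(Xc[[1]], tg))
    if (sign(p1[which.max(abs(p1))]) < 0) tg <- -tg
    for (k in seq_len(K)) {
      pk <- as.vector(crossprod(Xc[[k]], tg))
      pk <- pk / sqrt(sum(pk^2))
      loadings[[k]][, h] <- pk
      bscores[[k]][, h] <- Xc[[k]] %*% pk
    }
    gscores[, h] <- tg
    ssq[h] <- sum(vapply(seq_len(K),
                         function(k) stats::cov(tg, bscores[[k]][, h])^2, 0))
    for (k in seq_len(K)) {
      ck <- as.vector(crossprod(Xc[[k]], tg)) / sum(tg^2)
      Xc[[k]] <- Xc[[k]] - tcrossprod(tg, ck)
    }
  }

  new_integration_result(
    method = "consensus_mbpca", ncomp = ncomp,
    block_loadings = loadings, block_scores = bscores,
    sample_scores = gscores,
    selected = lapply(loadings, function(L) L != 0),
    diagnostics = tibble::tibble(component = dims, ssq_block_cov = ssq)
  )
}

# ---- adapter registry -------------------------------------------------------

the_adapters <- new.env(parent = emptyenv())

#' Register an integration-method adapter
#'
#' An adapter makes an external integration method usable within the
#' framework: `prepare(ms, ...)` converts a `multiomics_set` into the
#' method's input, and `collect(fit)` converts the method's output into an
#' `integration_result`, which is validated on collection.
#'
#' @param name Unique method name.
#' @param prepare Function `multiomics_set, ... -> method input`.
#' @param collect Function `method output -> integration_result`.
#' @return The adapter, invisibly.
#' @export
register_adapter <- function(name, prepare, collect) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.function(prepare), is.function(collect))
  if (name %in% ls(the_adapters)) {
    stop(sprintf("adapter '%s' is already registered", name), call. = FALSE)
  }
  adapter <- list(name = name, prepare = prepare, collect = collect)
  assign(name, adapter, envir = the_adapters)
  invisible(adapter)
}

#' @rdname register_adapter
#' @export
list_adapters <- function() sort(ls(the_adapters))

#' @rdname register_adapter
#' @param x Adapter name to remove (for `unregister_adapter`).
#' @export
unregister_adapter <- function(x) {
  if (exists(x, envir = the_adapters)) rm(list = x, envir = the_adapters)
  invisible(NULL)
}

#' Run a registered adapter
#'
#' @param name Registered adapter name.
#' @param ms A `multiomics_set`.
#' @param method_fn The external method: a function applied to the prepared
#'   input; defaults to the identity (for adapters whose `prepare` already
#'   produces the fit).
#' @param ... Passed to the adapter's `prepare`.
#' @return A validated `integration_result`.
#' @export
run_adapter <- function(name, ms, method_fn = identity, ...) {
  if (!name %in% ls(the_adapters)) {
    stop(sprintf("no adapter registered under '%s'", name), call. = FALSE)
  }
  adapter <- get(name, envir = the_adapters)
  res <- adapter$collect(method_fn(adapter$prepare(ms, ...)))
  if (!inherits(res, "integration_result")) {
    stop("adapter collect() must return an integration_result", call. = FALSE)
  }
  validate_integration_result(res)
}
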