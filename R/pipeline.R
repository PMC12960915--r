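# ---- operation registry -----------------------------------------------------

the_operations <- new.env(parent = emptyenv())

#' Register a pipeline operation
#'
#' Operations are the units a pipeline step can execute. Each is a function
#' `fn(inputs, params)` where `inputs` is a named list of the parent steps'
#' outputs and `params` the step's parameter list. The `version` string is
#' part of the step's content hash: bump it when the operation's behaviour
#' changes so dependent steps are re-run (code introspection is deliberately
#' not used — it is not portable across machines or R versions).
#'
#' @param name Unique operation name.
#' @param fn Function of `(inputs, params)`.
#' @param version Version tag entering the content hash.
#' @param overwrite Allow replacing an existing registration.
#' @return The operation record, invisibly.
#' @export
register_operation <- function(name, fn, version = "1", overwrite = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.function(fn))
  if (!overwrite && name %in% ls(the_operations)) {
    stop(sprintf("operation '%s' is already registered", name), call. = FALSE)
  }
  assign(name, list(name = name, fn = fn, version = as.character(version)),
         envir = the_operations)
  invisible(get(name, envir = the_operations))
}

#' @rdname register_operation
#' @export
list_operations <- function() sort(ls(the_operations))

get_operation <- function(name) {
  if (!name %in% ls(the_operations)) {
    stop(sprintf("unknown operation '%s'", name), call. = FALSE)
  }
  get(name, envir = the_operations)
}

#' Define a pipeline step
#'
#' @param name Unique step name.
#' @param op Registered operation name.
#' @param inputs Character vector of upstream step names whose outputs feed
#'   this step.
#' @param params Named list of parameters (must be serialisable; part of the
#'   content hash).
#' @param files Character vector of input file paths; their digests enter
#'   the content hash so edits to the files invalidate the step.
#' @return A `pipeline_step`.
#' @export
pipeline_step <- function(name, op, inputs = character(), params = list(),
                          files = character()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name, op = op, inputs = as.character(inputs),
                 params = params, files = as.character(files)),
            class = "pipeline_step")
}

# ---- pipeline construction --------------------------------------------------

#' Build a pipeline from step definitions or a YAML config
#'
#' The steps form a directed acyclic graph through their input references;
#' the DAG is validated (cycles are an error naming the offending steps) and
#' a topological order computed. All step and run state lives under `store`,
#' so a pipeline can be rebuilt in a new session and still see its cache.
#'
#' A YAML config has the shape:
#' ```yaml
#' steps:
#'   - name: raw
#'     op: generate_multiomics
#'     params: {n_samples: 50}
#'   - name: pca
#'     op: pca_dataset
#'     inputs: [raw]
#'     params: {dataset: rna, ncomp: 2}
#' ```
#'
#' @param config A list of `pipeline_step`s, or the path to a YAML file.
#' @param store Directory for cached outputs and run metadata.
#' @return An `omics_pipeline`.
#' @export
build_pipeline <- function(config, store = file.path(tempdir(), "pipeline_store")) {
  if (is.character(config) && length(config) == 1L) {
    cfg <- yaml::read_yaml(config)
    if (is.null(cfg$steps)) stop("YAML config must define `steps:`", call. = FALSE)
    config <- lapply(cfg$steps, function(s) {
      pipeline_step(name = s$name, op = s$op,
                    inputs = s$inputs %||% character(),
                    params = s$params %||% list(),
                    files = s$files %||% character())
    })
  }
  stopifnot(is.list(config), length(config) >= 1)
  config <- unlist_steps(config)
  names(config) <- vapply(config, function(s) s$name, character(1))
  check_unique_ids(names(config), "step")
  for (s in config) {
    get_operation(s$op)   # errors on unknown op
    unknown <- setdiff(s$inputs, names(config))
    if (length(unknown) > 0) {
      stop(sprintf("step '%s' references unknown input step(s): %s",
                   s$name, paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(names(config))
  for (s in config) {
    for (inp in s$inputs) g <- g + igraph::edge(inp, s$name)
  }
  if (!igraph::is_dag(g)) {
    # peel zero-in-degree vertices; whatever remains belongs to a cycle
    remaining <- names(config)
    deps <- lapply(config, function(s) s$inputs)
    repeat {
      free <- remaining[vapply(remaining, function(n)
        length(intersect(deps[[n]], remaining)) == 0, logical(1))]
      if (length(free) == 0) break
      remaining <- setdiff(remaining, free)
    }
    stop(sprintf("pipeline contains a cycle involving step(s): %s",
                 paste(remaining, collapse = ", ")), call. = FALSE)
  }
  order <- names(igraph::topo_sort(g, mode = "out"))
  if (!dir.exists(store)) dir.create(store, recursive = TRUE)
  structure(list(steps = config, graph = g, order = order, store = store),
            class = "omics_pipeline")
}

# flatten nested lists of steps (e.g. target_factory output mixed with steps)
unlist_steps <- function(x) {
  if (inherits(x, "pipeline_step")) return(list(x))
  out <- list()
  for (el in x) {
    if (inherits(el, "pipeline_step")) out <- c(out, list(el))
    else if (is.list(el)) out <- c(out, unlist_steps(el))
    else stop("pipeline config must contain pipeline_step objects", call. = FALSE)
  }
  out
}

#' @export
print.omics_pipeline <- function(x, ...) {
  cat(sprintf("<omics_pipeline> %d step(s): %s\n", length(x$steps),
              paste(x$order, collapse = " -> ")))
  invisible(x)
}

# ---- hashing and seeds ------------------------------------------------------

md5_of_object <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(obj, NULL, version = 3), tmp)
  unname(tools::md5sum(tmp))
}

md5_of_files <- function(paths) {
  if (length(paths) == 0) return(character())
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop(sprintf("input file(s) not found: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  unname(tools::md5sum(paths))
}

# canonical serialization of a parameter list: sorted by name, deparsed
canonical_params <- function(params) {
  if (length(params) == 0) return("")
  if (!is.null(names(params))) params <- params[order(names(params))]
  paste(deparse(params, control = c("keepNA", "keepInteger", "niceNames",
                                    "showAttributes")),
        collapse = "")
}

# Definition hash: operation identity + parameters + input step names +
# input-file digests. Ancestor outputs are tracked separately.
step_def_hash <- function(step) {
  op <- get_operation(step$op)
  md5_of_object(list(op = op$name, version = op$version,
                     params = canonical_params(step$params),
                     inputs = step$inputs,
                     files = md5_of_files(step$files)))
}

#' Derive the seed of a pipeline step
#'
#' A deterministic FNV-1a-style 32-bit mix of the global seed and the UTF-8
#' bytes of the step name: independent of execution order and of which other
#' steps exist, identical across machines, and always below 2^31 so it is a
#' valid `set.seed()` input.
#'
#' @param global_seed Integer pipeline-level seed.
#' @param step_name Step name.
#' @return Integer seed.
#' @export
derive_seed <- function(global_seed, step_name) {
  bytes <- utf8ToInt(paste0(format(global_seed, scientific = FALSE), ":",
                            step_name))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # multiply by the FNV prime mod 2^32 using exact double arithmetic
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- ((lo * 16777619) + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  as.integer(h %% 2147483647)
}

# ---- state ------------------------------------------------------------------

state_path <- function(pipeline) file.path(pipeline$store, "state.rds")
cache_path <- function(pipeline, name) {
  file.path(pipeline$store, paste0("step_", name, ".rds"))
}

read_state <- function(pipeline) {
  p <- state_path(pipeline)
  if (file.exists(p)) readRDS(p) else list()
}

# ---- execution --------------------------------------------------------------

#' Run a pipeline
#'
#' Steps execute in topological order. A step is (re-)executed iff it has no
#' valid cache, its definition hash changed (operation version, parameters,
#' input-file digests), or any parent's output digest changed; otherwise its
#' cached output is reused. Each executing step gets the deterministic seed
#' `derive_seed(global_seed, name)` via `set.seed()` before its operation is
#' called, so identical pipelines with identical global seeds produce
#' bit-identical outputs on any machine. A failing step marks all its
#' descendants failed; the run record is persisted regardless.
#'
#' @param pipeline An `omics_pipeline`.
#' @param global_seed Integer seed for the whole run.
#' @return A `run_record` tibble: `step`, `hash`, `seed`, `status`
#'   (`executed` / `cached` / `failed`), `runtime_s`, one row per step. Also
#'   written to `run_metadata.jsonl` in the store.
#' @export
run_pipeline <- function(pipeline, global_seed = 1L) {
  stopifnot(inherits(pipeline, "omics_pipeline"))
  state <- read_state(pipeline)
  records <- list()
  failed <- character()
  outputs <- new.env(parent = emptyenv())

  for (name in pipeline$order) {
    step <- pipeline$steps[[name]]
    seed <- derive_seed(global_seed, name)
    if (any(step$inputs %in% failed)) {
      failed <- c(failed, name)
      state[[name]] <- NULL
      records[[name]] <- record_row(name, NA_character_, seed, "failed", 0)
      next
    }
    def_hash <- step_def_hash(step)
    parent_digests <- vapply(step$inputs,
                             function(i) state[[i]]$out_digest, character(1))
    cached <- state[[name]]
    up_to_date <- !is.null(cached) &&
      identical(cached$def_hash, def_hash) &&
      identical(cached$parent_digests, parent_digests) &&
      file.exists(cache_path(pipeline, name))
    if (up_to_date) {
      records[[name]] <- record_row(name, def_hash, cached$seed, "cached", 0)
      next
    }
    inputs <- lapply(step$inputs, function(i) step_output(pipeline, i, outputs))
    names(inputs) <- step$inputs
    op <- get_operation(step$op)
    t0 <- proc.time()[["elapsed"]]
    result <- tryCatch({
      set.seed(seed)
      op$fn(inputs, step$params)
    }, error = function(e) structure(list(message = conditionMessage(e)),
                                     class = "step_failure"))
    elapsed <- proc.time()[["elapsed"]] - t0
    if (inherits(result, "step_failure")) {
      failed <- c(failed, name)
      state[[name]] <- NULL
      records[[name]] <- record_row(name, def_hash, seed, "failed", elapsed,
                                    result$message)
      next
    }
    saveRDS(result, cache_path(pipeline, name))
    assign(name, result, envir = outputs)
    state[[name]] <- list(def_hash = def_hash,
                          parent_digests = parent_digests,
                          out_digest = md5_of_object(result),
                          seed = seed)
    records[[name]] <- record_row(name, def_hash, seed, "executed", elapsed)
  }
  saveRDS(state, state_path(pipeline))
  rec <- dplyr::bind_rows(records[pipeline$order])
  jsonl <- file.path(pipeline$store, "run_metadata.jsonl")
  writeLines(vapply(seq_len(nrow(rec)), function(i) {
    jsonlite::toJSON(as.list(rec[i, ]), auto_unbox = TRUE)
  }, character(1)), jsonl)
  class(rec) <- c("run_record", class(rec))
  rec
}

record_row <- function(step, hash, seed, status, runtime_s, message = NA_character_) {
  tibble::tibble(step = step, hash = hash, seed = as.integer(seed),
                 status = status, runtime_s = runtime_s, message = message)
}

step_output <- function(pipeline, name, outputs) {
  if (exists(name, envir = outputs)) return(get(name, envir = outputs))
  readRDS(cache_path(pipeline, name))
}

# Steps whose definition (or an ancestor's) changed since the cached run.
stale_steps <- function(pipeline) {
  state <- read_state(pipeline)
  stale <- character()
  for (name in pipeline$order) {
    step <- pipeline$steps[[name]]
    cached <- state[[name]]
    own_stale <- is.null(cached) ||
      !identical(cached$def_hash, step_def_hash(step)) ||
      !file.exists(cache_path(pipeline, name))
    if (own_stale || any(step$inputs %in% stale)) stale <- c(stale, name)
  }
  stale
}

#' Which steps are out of date?
#'
#' @param pipeline An `omics_pipeline`.
#' @return Character vector of step names whose definition or ancestry
#'   changed since the last run.
#' @export
outdated_steps <- function(pipeline) stale_steps(pipeline)

#' Retrieve a cached step output
#'
#' @param pipeline An `omics_pipeline`.
#' @param name Step name.
#' @return The step's output exactly as downstream steps consumed it.
#'   Errors for unknown steps, never-run steps, and steps whose cache is
#'   stale (invalidated but not yet re-run).
#' @export
get_output <- function(pipeline, name) {
  stopifnot(inherits(pipeline, "omics_pipeline"))
  if (!name %in% names(pipeline$steps)) {
    stop(sprintf("unknown step '%s'", name), call. = FALSE)
  }
  if (!file.exists(cache_path(pipeline, name))) {
    stop(sprintf("step '%s' has never been run", name), call. = FALSE)
  }
  if (name %in% stale_steps(pipeline)) {
    stop(sprintf("cache for step '%s' is stale; re-run the pipeline first",
                 name), call. = FALSE)
  }
  readRDS(cache_path(pipeline, name))
}

#' Pipeline status table
#'
#' @param pipeline An `omics_pipeline`.
#' @return Tibble `step`, `op`, `has_cache`, `outdated`.
#' @export
pipeline_status <- function(pipeline) {
  stale <- stale_steps(pipeline)
  tibble::tibble(
    step = pipeline$order,
    op = vapply(pipeline$steps[pipeline$order], function(s) s$op, character(1)),
    has_cache = vapply(pipeline$order,
                       function(n) file.exists(cache_path(pipeline, n)),
                       logical(1)),
    outdated = pipeline$order %in% stale
  )
}

#' Export the pipeline DAG as Graphviz DOT
#'
#' @param pipeline An `omics_pipeline`.
#' @param path Optional file to write to.
#' @return The DOT source as a character scalar (invisibly when written).
#' @export
pipeline_dot <- function(pipeline, path = NULL) {
  edges <- unlist(lapply(pipeline$steps, function(s) {
    if (length(s$inputs) == 0) return(NULL)
    sprintf("  \"%s\" -> \"%s\";", s$inputs, s$name)
  }))
  nodes <- sprintf("  \"%s\";", names(pipeline$steps))
  dot <- paste(c("digraph pipeline {", nodes, edges, "}"), collapse = "\n")
  if (!is.null(path)) {
    writeLines(dot, path)
    return(invisible(dot))
  }
  dot
}

# ---- target factories -------------------------------------------------------

#' Generate groups of steps for repetitive per-dataset tasks
#'
#' Factories expand one declaration into one deterministic step per dataset
#' (`pca_<dataset>`, `transform_<dataset>`, `load_<dataset>`), wired to the
#' step holding the `multiomics_set` (or, for `load_all`, feeding a
#' container-building step named `<prefix>multiomics`). Name collisions with
#' existing steps surface when the pipeline is built.
#'
#' @param kind `"pca_all"`, `"transform_all"` or `"load_all"`.
#' @param ms_ref Name of the step producing the `multiomics_set` (`pca_all`,
#'   `transform_all`).
#' @param datasets Character vector of dataset names (for `load_all`: named
#'   list of per-dataset specs with `path`, `orientation`, ...).
#' @param params Extra parameters merged into each generated step.
#' @param prefix Optional prefix for generated step names.
#' @return A list of `pipeline_step`s.
#' @export
target_factory <- function(kind = c("pca_all", "transform_all", "load_all"),
                           ms_ref = NULL, datasets, params = list(),
                           prefix = "") {
  kind <- match.arg(kind)
  if (kind == "load_all") {
    stopifnot(is.list(datasets), !is.null(names(datasets)))
    steps <- lapply(names(datasets), function(nm) {
      spec <- datasets[[nm]]
      pipeline_step(
        name = paste0(prefix, "load_", nm),
        op = "load_omics_csv",
        params = c(list(name = nm), spec, params),
        files = spec$path
      )
    })
    container <- pipeline_step(
      name = paste0(prefix, "multiomics"),
      op = "build_multiomics",
      inputs = vapply(steps, function(s) s$name, character(1))
    )
    return(c(steps, list(container)))
  }
  stopifnot(is.character(ms_ref), is.character(datasets))
  op <- if (kind == "pca_all") "pca_dataset" else "transform_dataset"
  short <- if (kind == "pca_all") "pca_" else "transform_"
  lapply(datasets, function(nm) {
    pipeline_step(
      name = paste0(prefix, short, nm),
      op = op,
      inputs = ms_ref,
      params = c(list(dataset = nm), params)
    )
  })
}

# Built-in operations available to pipeline configs.
register_builtin_operations <- function() {
  builtin <- list(
    load_omics_csv = list(fn = function(inputs, params) {
      load_omics_csv(params$path, params$name,
                     orientation = params$orientation %||% "features_rows")
    }, version = "1"),
    build_multiomics = list(fn = function(inputs, params) {
      multiomics_set(unname(inputs))
    }, version = "1"),
    subset_common_samples = list(fn = function(inputs, params) {
      subset_common_samples(inputs[[1]])
    }, version = "1"),
    pca_dataset = list(fn = function(inputs, params) {
      nipals_pca(get_dataset(inputs[[1]], params$dataset),
                 ncomp = params$ncomp %||% 2,
                 center = params$center %||% TRUE,
                 scale. = params$scale %||% FALSE)
    }, version = "1"),
    transform_dataset = list(fn = function(inputs, params) {
      transform_dataset(get_dataset(inputs[[1]], params$dataset),
                        method = params$method %||% "zscore")
    }, version = "1"),
    impute_missing = list(fn = function(inputs, params) {
      impute_missing(inputs[[1]], ncomp = params$ncomp %||% 2)
    }, version = "1"),
    generate_multiomics = list(fn = function(inputs, params) {
      generate_multiomics(do.call(sim_config, params))
    }, version = "1")
  )
  for (nm in names(builtin)) {
    register_operation(nm, builtin[[nm]]$fn, builtin[[nm]]$version,
                       overwrite = TRUE)
  }
}

.onLoad <- function(libname, pkgname) {
  register_builtin_operations()
}
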