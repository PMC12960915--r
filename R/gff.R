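#' Build a features-metadata table from a GFF3/GTF file
#'
#' Reads gene/transcript annotation and returns one metadata row per record of
#' the requested feature type, keyed by an attribute (e.g. `ID` for GFF3,
#' `gene_id` for GTF). Coordinates are kept as in the file: 1-based, inclusive.
#' Records lacking the ID attribute are skipped with a warning; malformed
#' files raise an error naming the file.
#'
#' @param path Path to a GFF3 or GTF file. Both attribute dialects
#'   (`key=value;` and `key "value";`) are supported.
#' @param id_attribute Attribute whose value becomes the `feature_id` key.
#' @param feature_type_filter Feature type (column 3) to retain, e.g.
#'   `"gene"`.
#' @param format `"auto"` (from the file extension), `"gff3"` or `"gtf"`.
#' @return A tibble with columns `feature_id`, `chromosome`, `start`, `end`,
#'   `strand`, plus one column per parsed attribute.
#' @export
load_gff_features <- function(path, id_attribute = "ID",
                              feature_type_filter = "gene",
                              format = c("auto", "gff3", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "gff3"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = format),
    error = function(e) {
      stop(sprintf("failed to parse %s as %s: %s", path, toupper(format),
                   conditionMessage(e)), call. = FALSE)
    }
  )
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df <- df[as.character(df$type) == feature_type_filter, , drop = FALSE]
  if (nrow(df) == 0) {
    stop(sprintf("no record of type '%s' in %s", feature_type_filter, path),
         call. = FALSE)
  }
  if (!id_attribute %in% names(df)) {
    stop(sprintf("attribute '%s' not present on any record in %s",
                 id_attribute, path), call. = FALSE)
  }
  ids <- as.character(df[[id_attribute]])
  no_id <- is.na(ids) | !nzchar(ids)
  if (any(no_id)) {
    warning(sprintf("skipping %d '%s' record(s) lacking attribute '%s'",
                    sum(no_id), feature_type_filter, id_attribute),
            call. = FALSE)
    df <- df[!no_id, , drop = FALSE]
    ids <- ids[!no_id]
  }
  check_unique_ids(ids, "feature")
  attr_cols <- setdiff(names(df),
                       c("seqnames", "start", "end", "width", "strand",
                         "source", "type", "score", "phase"))
  out <- tibble::tibble(
    feature_id = ids,
    chromosome = as.character(df$seqnames),
    start = as.integer(df$start),
    end = as.integer(df$end),
    strand = as.character(df$strand)
  )
  for (col in attr_cols) {
    val <- df[[col]]
    if (is.list(val)) val <- vapply(val, function(v) paste(v, collapse = ","),
                                    character(1))
    out[[col]] <- val
  }
  out
}
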