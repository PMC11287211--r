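# Readers/writers for the plain-text dialects the analysis stages exchange:
# tab-separated annotation and feature tables, comma-separated plate and
# extraction series. All validation failures in a file are reported together.

#' Read and write genome annotation tables
#'
#' Tab-separated, UTF-8, header required, one row per detected annotation:
#' columns `genome_id`, `domain`, `lineage`, `annotation_id`. Duplicate
#' (genome_id, annotation_id) rows collapse to a single detection on read.
#'
#' @param path File path.
#' @return `read_annotations()`: a validated long tibble.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  validate_annotations(x)
}

#' @rdname read_annotations
#' @param annotations A long annotation tibble.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(annotations, path)
  invisible(path)
}

#' Read and write serial-extraction series
#'
#' Comma-separated with columns `round`, `aq_conc_nM` and optionally
#' `censored` (logical). Round indices must be consecutive; censored rounds
#' are flagged, never zero-filled.
#'
#' @param path File path.
#' @return `read_series()`: a validated tibble.
#' @export
read_series <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- readr::read_csv(path, show_col_types = FALSE)
  validate_series(x)
}

#' @rdname read_series
#' @param series An extraction-series tibble.
#' @export
write_series <- function(series, path) {
  readr::write_csv(series, path)
  invisible(path)
}

#' Read and write zOTU feature tables
#'
#' Three tab-separated files: a counts table (first column `zotu_id`, one
#' column per sample), a taxonomy table (`zotu_id`, `lineage` with
#' semicolon-delimited ranks), and sample metadata (`sample_id`, `medium`,
#' `corrinoid`, `timepoint`, `replicate`, `inoculated`). All cross-file
#' consistency violations are reported together via [feature_table()].
#'
#' @param counts_path,taxonomy_path,metadata_path File paths.
#' @return `read_feature_table()`: a [feature_table()].
#' @export
read_feature_table <- function(counts_path, taxonomy_path, metadata_path) {
  for (p in c(counts_path, taxonomy_path, metadata_path)) {
    if (!file.exists(p)) abort(paste0("file not found: ", p))
  }
  counts_df <- readr::read_tsv(counts_path, show_col_types = FALSE)
  if (names(counts_df)[1] != "zotu_id") {
    abort("counts table must have `zotu_id` as its first column.")
  }
  non_int <- names(counts_df)[-1][!vapply(counts_df[-1], function(x) {
    is.numeric(x) && all(x == round(x), na.rm = TRUE)
  }, logical(1))]
  if (length(non_int) > 0) {
    abort(paste0("non-integer counts in column(s): ",
                 paste(non_int, collapse = ", ")))
  }
  counts <- as.matrix(counts_df[-1])
  rownames(counts) <- counts_df$zotu_id

  taxonomy <- readr::read_tsv(taxonomy_path, show_col_types = FALSE)
  metadata <- readr::read_tsv(metadata_path, show_col_types = FALSE)
  feature_table(counts, metadata, taxonomy)
}

#' @rdname read_feature_table
#' @param ft A [feature_table()].
#' @param dir Output directory (created if absent); writes `counts.tsv`,
#'   `taxonomy.tsv`, `metadata.tsv`.
#' @export
write_feature_table <- function(ft, dir) {
  stopifnot(inherits(ft, "feature_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  counts_df <- tibble::as_tibble(ft$counts, rownames = "zotu_id")
  readr::write_tsv(counts_df, file.path(dir, "counts.tsv"))
  ranks <- setdiff(ft$ranks, "zotu")
  tax <- tibble::tibble(
    zotu_id = ft$taxonomy$zotu_id,
    lineage = do.call(paste, c(ft$taxonomy[ranks], sep = ";"))
  )
  readr::write_tsv(tax, file.path(dir, "taxonomy.tsv"))
  readr::write_tsv(ft$samples, file.path(dir, "metadata.tsv"))
  invisible(dir)
}
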