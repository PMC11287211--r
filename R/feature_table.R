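#' zOTU feature table with sample metadata and taxonomy
#'
#' Bundles a zOTU x sample count matrix with per-sample metadata and a
#' per-zOTU taxonomy lineage, validating the three against each other. All
#' invariant violations are reported together.
#'
#' @param counts Non-negative integer matrix, zOTUs in rows (rownames =
#'   zOTU ids), samples in columns (colnames = sample ids).
#' @param samples Data frame with columns `sample_id`, `medium`, `corrinoid`,
#'   `timepoint`, `replicate`, `inoculated` (logical).
#' @param taxonomy Data frame with columns `zotu_id` and `lineage`
#'   (semicolon-delimited, phylum first) or pre-split rank columns.
#' @param ranks Rank names above the zOTU level, outermost first.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(counts, samples, taxonomy,
                          ranks = c("phylum", "class", "order", "family",
                                    "genus")) {
  counts <- as.matrix(counts)
  samples <- tibble::as_tibble(samples)
  taxonomy <- tibble::as_tibble(taxonomy)

  req_meta <- c("sample_id", "medium", "corrinoid", "timepoint", "replicate",
                "inoculated")
  missing_meta <- setdiff(req_meta, names(samples))

  failures <- list(
    fail_if(is.null(rownames(counts)) || is.null(colnames(counts)),
            "`counts` must have zOTU rownames and sample colnames."),
    fail_if(any(counts < 0) || any(counts != round(counts)),
            "`counts` must be non-negative integers."),
    fail_if(length(missing_meta) > 0,
            paste0("sample metadata missing column(s): ",
                   paste(missing_meta, collapse = ", "))),
    fail_if(!"zotu_id" %in% names(taxonomy),
            "`taxonomy` must have a `zotu_id` column.")
  )
  check_all(failures, "feature_table")

  zero_samples <- colnames(counts)[colSums(counts) == 0]
  in_counts_not_meta <- setdiff(colnames(counts), samples$sample_id)
  no_lineage <- setdiff(rownames(counts), taxonomy$zotu_id)
  check_all(list(
    fail_if(length(zero_samples) > 0,
            paste0("sample(s) with zero total counts: ",
                   paste(zero_samples, collapse = ", "))),
    fail_if(length(in_counts_not_meta) > 0,
            paste0("sample(s) in counts missing from metadata: ",
                   paste(in_counts_not_meta, collapse = ", "))),
    fail_if(length(no_lineage) > 0,
            paste0("zOTU(s) without taxonomy: ",
                   paste(head(no_lineage, 5), collapse = ", "))),
    fail_if(anyDuplicated(samples$sample_id) > 0,
            "duplicate sample_id in metadata."),
    fail_if(anyDuplicated(taxonomy$zotu_id) > 0,
            "duplicate zotu_id in taxonomy.")
  ), "feature_table")

  samples <- samples[match(colnames(counts), samples$sample_id), ]
  taxonomy <- taxonomy[match(rownames(counts), taxonomy$zotu_id), ]
  if ("lineage" %in% names(taxonomy)) {
    taxonomy <- dplyr::bind_cols(
      taxonomy["zotu_id"], parse_lineage(taxonomy$lineage, ranks = ranks)
    )
  } else {
    missing_ranks <- setdiff(ranks, names(taxonomy))
    if (length(missing_ranks) > 0) {
      abort(paste0("taxonomy missing rank column(s): ",
                   paste(missing_ranks, collapse = ", ")))
    }
    taxonomy <- taxonomy[c("zotu_id", ranks)]
  }
  storage.mode(counts) <- "integer"

  structure(
    list(counts = counts, samples = samples, taxonomy = taxonomy,
         ranks = c(ranks, "zotu")),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d zOTUs x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  ranks:", paste(x$ranks, collapse = " > "), "\n")
  cat("  media:", paste(unique(x$samples$medium), collapse = ", "),
      "| corrinoids:", paste(unique(x$samples$corrinoid), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a feature table by sample
#'
#' Keeps the samples for which `...` predicates on the metadata hold, then
#' drops zOTUs with zero counts in the remainder.
#'
#' @param ft A [feature_table()].
#' @param ... Filter expressions evaluated in the sample metadata, e.g.
#'   `medium == "M9"`, `inoculated`.
#' @return A `feature_table`.
#' @export
filter_samples <- function(ft, ...) {
  stopifnot(inherits(ft, "feature_table"))
  keep <- dplyr::filter(ft$samples, ...)
  if (nrow(keep) == 0) abort("no samples left after filtering.")
  counts <- ft$counts[, keep$sample_id, drop = FALSE]
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  feature_table(counts, keep,
                ft$taxonomy[ft$taxonomy$zotu_id %in% rownames(counts), ],
                ranks = setdiff(ft$ranks, "zotu"))
}

taxon_labels <- function(ft, rank) {
  rank <- match.arg(rank, ft$ranks)
  if (rank == "zotu") rownames(ft$counts) else ft$taxonomy[[rank]]
}

#' Aggregate a feature table at a taxonomy rank
#'
#' Sums the counts of all zOTUs sharing a label at the chosen rank. Per-sample
#' totals are invariant across ranks; `zotu` returns the table unchanged.
#'
#' @param ft A [feature_table()].
#' @param rank One of the table's ranks (`"phylum"` ... `"genus"`, `"zotu"`).
#' @return A list with `counts` (taxa x samples integer matrix), `rel_abund`
#'   (columns sum to 1), `samples` (metadata tibble) and `rank`.
#' @export
aggregate_taxa <- function(ft, rank = "zotu") {
  stopifnot(inherits(ft, "feature_table"))
  rank <- match.arg(rank, ft$ranks)
  labels <- taxon_labels(ft, rank)
  counts <- rowsum(ft$counts, group = labels)
  storage.mode(counts) <- "integer"
  rel <- sweep(counts, 2, colSums(counts), "/")
  list(counts = counts, rel_abund = rel, samples = ft$samples, rank = rank)
}

#' Long tidy view of relative abundances at a rank
#'
#' @inheritParams aggregate_taxa
#' @return A tibble: `taxon`, `sample_id`, `count`, `rel_abund`, joined with
#'   the sample metadata.
#' @export
rel_abundance <- function(ft, rank = "zotu") {
  agg <- aggregate_taxa(ft, rank)
  long <- tibble::as_tibble(agg$counts, rownames = "taxon") |>
    tidyr::pivot_longer(-"taxon", names_to = "sample_id",
                        values_to = "count") |>
    dplyr::left_join(
      tibble::as_tibble(agg$rel_abund, rownames = "taxon") |>
        tidyr::pivot_longer(-"taxon", names_to = "sample_id",
                            values_to = "rel_abund"),
      by = c("taxon", "sample_id")
    ) |>
    dplyr::left_join(agg$samples, by = "sample_id")
  long
}
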