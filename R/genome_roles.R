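#' Classify genomes into corrinoid ecological roles
#'
#' Assigns each genome/MAG one of four corrinoid ecological roles from its set
#' of detected annotation identifiers:
#'
#' * `producer`: at least one corrin-ring biosynthesis marker **and** at least
#'   one corrinoid-dependent function;
#' * `producer_non_user`: biosynthesis marker(s) but no corrinoid-dependent
#'   function;
#' * `dependent`: no biosynthesis marker, at least one corrinoid-dependent
#'   function;
#' * `independent`: neither.
#'
#' The rule is a total function of the two marker counts, so every genome
#' receives exactly one role. Producer/non-users are a category that has not
#' been verified in complete genomes; they are flagged (`unverified = TRUE`)
#' and a warning is raised when any occur.
#'
#' @param annotations A data frame with one row per detected annotation:
#'   columns `genome_id`, `domain` (`"bacteria"` or `"archaea"`), `lineage`
#'   (semicolon-delimited ranks, phylum first) and `annotation_id` (KO/Pfam).
#'   Duplicate (genome_id, annotation_id) rows collapse to one detection.
#' @param cfg A [marker_config()].
#' @return A tibble with one row per genome: `genome_id`, `domain`, `phylum`,
#'   `role` (factor with the four levels above), `n_biosynthesis_markers`,
#'   `n_dependent_functions`, `unverified`.
#' @examples
#' ann <- tibble::tibble(
#'   genome_id = c("g1", "g1", "g2"),
#'   domain = "bacteria",
#'   lineage = "Actinobacteria;Actinomycetia",
#'   annotation_id = c("K06042", "K00548", "PF08471")
#' )
#' classify_roles(ann)
#' @export
classify_roles <- function(annotations, cfg = marker_config()) {
  stopifnot(inherits(cfg, "marker_config"))
  annotations <- validate_annotations(annotations)

  dep_all <- unique(unlist(cfg$dependent, use.names = FALSE))

  per_genome <- annotations |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::summarise(
      n_domain = dplyr::n_distinct(.data$domain),
      n_lineage = dplyr::n_distinct(.data$lineage),
      domain = dplyr::first(.data$domain),
      lineage = dplyr::first(.data$lineage),
      detected = list(unique(.data$annotation_id)),
      .groups = "drop"
    )

  conflicting <- per_genome$genome_id[per_genome$n_domain > 1 |
                                        per_genome$n_lineage > 1]
  if (length(conflicting) > 0) {
    abort(paste0("conflicting domain/lineage for genome_id(s): ",
                 paste(conflicting, collapse = ", ")))
  }

  n_bio <- vapply(per_genome$detected,
                  function(d) length(intersect(d, cfg$biosynthesis)),
                  integer(1))
  n_dep <- vapply(per_genome$detected, function(d) {
    sum(vapply(cfg$dependent, function(ids) any(ids %in% d), logical(1)))
  }, integer(1))

  role <- dplyr::case_when(
    n_bio > 0 & n_dep > 0  ~ "producer",
    n_bio > 0 & n_dep == 0 ~ "producer_non_user",
    n_bio == 0 & n_dep > 0 ~ "dependent",
    .default = "independent"
  )

  out <- tibble::tibble(
    genome_id = per_genome$genome_id,
    domain = per_genome$domain,
    phylum = parse_lineage(per_genome$lineage, ranks = "phylum")$phylum,
    role = factor(role, levels = corrinoid_roles()),
    n_biosynthesis_markers = n_bio,
    n_dependent_functions = n_dep,
    unverified = role == "producer_non_user"
  )
  if (any(out$unverified)) {
    warn(sprintf(
      "%d genome(s) classified producer_non_user; this role is unverified in complete genomes.",
      sum(out$unverified)
    ))
  }
  out
}

corrinoid_roles <- function() {
  c("producer", "dependent", "independent", "producer_non_user")
}

validate_annotations <- function(annotations) {
  annotations <- tibble::as_tibble(annotations)
  required <- c("genome_id", "domain", "lineage", "annotation_id")
  missing <- setdiff(required, names(annotations))
  if (length(missing) > 0) {
    abort(paste0("annotation table missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad_id <- which(is.na(annotations$genome_id) |
                    trimws(annotations$genome_id) == "")
  bad_ann <- which(is.na(annotations$annotation_id) |
                     trimws(annotations$annotation_id) == "" |
                     grepl("\\s", annotations$annotation_id))
  check_all(list(
    fail_if(nrow(annotations) == 0, "annotation table is empty."),
    fail_if(length(bad_id) > 0,
            paste0("empty genome_id in row(s): ",
                   paste(head(bad_id, 5), collapse = ", "))),
    fail_if(length(bad_ann) > 0,
            paste0("malformed annotation_id in row(s): ",
                   paste(head(bad_ann, 5), collapse = ", ")))
  ), "annotation table")
  dplyr::distinct(annotations, .data$genome_id, .data$annotation_id,
                  .keep_all = TRUE)
}

#' Summarise role counts overall or by grouping columns
#'
#' Counts role assignments, optionally per `phylum` and/or `domain`. Counts at
#' any grouping always marginalise to the overall totals.
#'
#' @param assignments Output of [classify_roles()].
#' @param by Optional character vector of grouping columns
#'   (`"phylum"`, `"domain"`).
#' @return A tibble with the grouping columns, `role`, `n` and `prop`
#'   (proportion of all genomes). Roles with zero genomes are retained.
#' @export
role_summary <- function(assignments, by = NULL) {
  stopifnot(all(by %in% c("phylum", "domain")))
  n_total <- nrow(assignments)
  assignments |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::count(.data$role, .drop = FALSE, name = "n") |>
    dplyr::ungroup() |>
    dplyr::mutate(prop = .data$n / n_total)
}

#' Tally corrinoid-dependent versus -independent enzyme redundancy
#'
#' For each function with a configured corrinoid-independent alternative,
#' counts genomes encoding only the corrinoid-dependent enzyme
#' (`dependent_only`), only the alternative (`independent_only`), `both`, or
#' `neither`. The four categories partition the genome set. Two percentage
#' denominators are reported: all genomes (`pct_all`) and genomes with either
#' version detected (`pct_detected`) — the latter matching statements such as
#' the share of RNR-carrying genomes that keep only the corrinoid-independent
#' enzyme.
#'
#' @inheritParams classify_roles
#' @param functions Which paired functions to report; defaults to every
#'   function with an independent alternative in `cfg`.
#' @return A tibble: `fn`, `category`, `n`, `pct_all`, `pct_detected`.
#' @export
redundancy_report <- function(annotations, cfg = marker_config(),
                              functions = names(cfg$independent)) {
  stopifnot(inherits(cfg, "marker_config"))
  missing <- setdiff(functions, names(cfg$independent))
  if (length(missing) > 0) {
    abort(paste0("function(s) without a configured dependent/independent pair: ",
                 paste(missing, collapse = ", ")))
  }
  annotations <- validate_annotations(annotations)
  detected <- annotations |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::summarise(detected = list(unique(.data$annotation_id)),
                     .groups = "drop")
  n_total <- nrow(detected)

  purrr::map_dfr(functions, function(f) {
    has_dep <- vapply(detected$detected,
                      function(d) any(cfg$dependent[[f]] %in% d), logical(1))
    has_ind <- vapply(detected$detected,
                      function(d) any(cfg$independent[[f]] %in% d), logical(1))
    cat_ <- dplyr::case_when(
      has_dep & has_ind ~ "both",
      has_dep ~ "dependent_only",
      has_ind ~ "independent_only",
      .default = "neither"
    )
    cat_ <- factor(cat_, levels = c("dependent_only", "independent_only",
                                    "both", "neither"))
    n <- as.integer(table(cat_))
    n_detected <- sum(cat_ != "neither")
    tibble::tibble(
      fn = f,
      category = levels(cat_),
      n = n,
      pct_all = 100 * n / n_total,
      pct_detected = ifelse(
        levels(cat_) == "neither", NA_real_,
        100 * n / max(n_detected, 1L)
      )
    )
  })
}
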