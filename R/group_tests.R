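#' ANOSIM and PERMANOVA on a distance matrix
#'
#' Permutation tests of whole-community separation between groups of samples.
#' ANOSIM uses the rank-based statistic
#' `R = (mean between-group rank - mean within-group rank) / (N(N-1)/4)`,
#' in `[-1, 1]`; PERMANOVA uses the pseudo-F ratio of between- to
#' within-group sums of squared distances. Both are computed by
#' \pkg{vegan} ([vegan::anosim()], [vegan::adonis2()]); the observed
#' statistics are permutation-free and deterministic, and the permutation
#' p-value follows the `(1 + hits) / (1 + n_perm)` convention. The RNG seed
#' is mandatory and recorded in the result.
#'
#' @param d A `dist` over samples (e.g. [bray_curtis()]).
#' @param groups Grouping vector, one label per sample; at least 2 groups of
#'   at least 2 samples each.
#' @param n_perm Number of permutations (default 999; below 99 a warning is
#'   raised).
#' @param seed Integer RNG seed for the permutations.
#' @return A one-row tibble: `method`, `statistic_name`, `statistic`,
#'   `p_value`, `n_perm`, `seed`, `n_samples`, `n_groups`.
#' @examples
#' m <- rbind(a1 = c(9, 1), a2 = c(8, 2), b1 = c(1, 9), b2 = c(2, 8))
#' d <- bray_curtis(m)
#' anosim_test(d, c("a", "a", "b", "b"), n_perm = 199, seed = 1)
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = 1) {
  check_grouping(d, groups, n_perm)
  fit <- with_seed(seed, vegan::anosim(d, grouping = factor(groups),
                                       permutations = n_perm))
  test_result("anosim", "R", fit$statistic, fit$signif, n_perm, seed, groups)
}

#' @rdname anosim_test
#' @export
permanova_test <- function(d, groups, n_perm = 999, seed = 1) {
  check_grouping(d, groups, n_perm)
  meta <- data.frame(group = factor(groups))
  fit <- with_seed(seed, vegan::adonis2(d ~ group, data = meta,
                                        permutations = n_perm))
  test_result("permanova", "pseudo_F", fit$F[1], fit$`Pr(>F)`[1], n_perm,
              seed, groups)
}

check_grouping <- function(d, groups, n_perm) {
  if (!inherits(d, "dist")) abort("`d` must be a `dist`.")
  if (length(groups) != attr(d, "Size")) {
    abort("`groups` must have one label per sample in `d`.")
  }
  sizes <- table(groups)
  check_all(list(
    fail_if(length(sizes) < 2, "need at least 2 groups."),
    fail_if(any(sizes < 2),
            paste0("group(s) of size 1: ",
                   paste(names(sizes)[sizes < 2], collapse = ", ")))
  ), "grouping")
  if (n_perm < 99) warn("fewer than 99 permutations: p-values are coarse.")
  invisible(TRUE)
}

test_result <- function(method, statistic_name, statistic, p_value, n_perm,
                        seed, groups) {
  tibble::tibble(
    method = method, statistic_name = statistic_name,
    statistic = unname(statistic), p_value = unname(p_value),
    n_perm = n_perm, seed = seed,
    n_samples = length(groups), n_groups = length(unique(groups))
  )
}

#' Kruskal-Wallis screen for corrinoid-responsive taxa
#'
#' At each timepoint and the chosen taxonomy rank, tests every observed taxon
#' for differences in relative abundance across treatment groups with the
#' tie-corrected Kruskal-Wallis H (chi-square p-value). Significance is
#' called at unadjusted `p <= alpha` (default 0.05) — the screen's native
#' convention — and a Benjamini-Hochberg adjusted column (`p_adj`, within
#' timepoint) is always emitted alongside so the multiplicity choice stays
#' visible. Taxa observed in fewer than two groups, or with identical values
#' in every sample (H undefined after tie correction), are skipped and
#' reported with `status = "skipped"` rather than tested.
#'
#' @param ft A [feature_table()].
#' @param rank Taxonomy rank to screen at.
#' @param group Metadata column holding the treatment (default
#'   `"corrinoid"`).
#' @param timepoints Timepoints to screen; default all present.
#' @param alpha Significance level for the unadjusted call.
#' @param exclude_uninoculated Drop samples with `inoculated == FALSE`
#'   before testing (uninoculated controls are retained elsewhere for
#'   contamination checks, not for treatment screens).
#' @return A tibble with one row per taxon x timepoint: `timepoint`, `rank`,
#'   `taxon`, `status`, `n_groups`, `statistic` (H), `df`, `p_value`,
#'   `p_adj`, `significant`.
#' @export
kw_screen <- function(ft, rank = "zotu", group = "corrinoid",
                      timepoints = NULL, alpha = 0.05,
                      exclude_uninoculated = TRUE) {
  stopifnot(inherits(ft, "feature_table"))
  if (!group %in% names(ft$samples)) {
    abort(paste0("no metadata column `", group, "`."))
  }
  if (exclude_uninoculated && any(!ft$samples$inoculated)) {
    ft <- filter_samples(ft, .data$inoculated)
  }
  timepoints <- timepoints %||% sort(unique(ft$samples$timepoint))

  purrr::map_dfr(timepoints, function(tp) {
    sub <- filter_samples(ft, .data$timepoint == tp)
    agg <- aggregate_taxa(sub, rank)
    g <- factor(agg$samples[[group]])
    if (nlevels(g) < 2) abort("need >= 2 treatment groups per timepoint.")

    res <- purrr::map_dfr(rownames(agg$rel_abund), function(tax) {
      vals <- agg$rel_abund[tax, ]
      groups_present <- unique(g[agg$counts[tax, ] > 0])
      if (length(groups_present) < 2 || length(unique(vals)) == 1) {
        return(tibble::tibble(taxon = tax, status = "skipped",
                              n_groups = nlevels(g), statistic = NA_real_,
                              df = NA_integer_, p_value = NA_real_))
      }
      kt <- kruskal.test(vals, g)
      tibble::tibble(taxon = tax, status = "tested", n_groups = nlevels(g),
                     statistic = unname(kt$statistic),
                     df = unname(kt$parameter), p_value = kt$p.value)
    })
    res$timepoint <- tp
    res$rank <- rank
    res$p_adj <- p.adjust(res$p_value, method = "BH")
    res$significant <- !is.na(res$p_value) & res$p_value <= alpha
    res[c("timepoint", "rank", "taxon", "status", "n_groups", "statistic",
          "df", "p_value", "p_adj", "significant")]
  })
}

#' Fraction of taxa responsive to corrinoid treatment (count-based)
#'
#' The enrichment-style summary: the number of distinct taxa at a rank that
#' were significant at *any* screened timepoint, divided by all taxa observed
#' at that rank.
#'
#' @param screen Output of [kw_screen()] (one rank).
#' @return A one-row tibble: `rank`, `n_responsive`, `n_taxa`, `fraction`.
#' @export
responsive_fraction_count <- function(screen) {
  if (nrow(screen) == 0) abort("empty screen result.")
  if (length(unique(screen$rank)) != 1) {
    abort("`screen` must contain a single rank.")
  }
  taxa <- unique(screen$taxon)
  if (length(taxa) == 0) abort("no taxa in screen result.")
  responsive <- unique(screen$taxon[screen$significant])
  tibble::tibble(
    rank = screen$rank[1],
    n_responsive = length(responsive),
    n_taxa = length(taxa),
    fraction = length(responsive) / length(taxa)
  )
}

#' Community share of corrinoid-responsive taxa (abundance-based)
#'
#' The microcosm-style summary: per timepoint, the summed mean relative
#' abundance of the taxa called significant at that timepoint — the
#' proportion of the community responsive to treatment. Deliberately a
#' separate operation from [responsive_fraction_count()]; the two summaries
#' answer different questions and are never conflated.
#'
#' @param screen Output of [kw_screen()] (one rank).
#' @param ft The [feature_table()] the screen was computed from.
#' @param exclude_uninoculated Must match the screen's setting.
#' @return A tibble per timepoint: `timepoint`, `rank`, `n_significant`,
#'   `prop_community`.
#' @export
responsive_fraction_abundance <- function(screen, ft,
                                          exclude_uninoculated = TRUE) {
  stopifnot(inherits(ft, "feature_table"))
  if (nrow(screen) == 0) abort("empty screen result.")
  if (length(unique(screen$rank)) != 1) {
    abort("`screen` must contain a single rank.")
  }
  rank <- screen$rank[1]
  if (exclude_uninoculated && any(!ft$samples$inoculated)) {
    ft <- filter_samples(ft, .data$inoculated)
  }
  purrr::map_dfr(unique(screen$timepoint), function(tp) {
    sig <- screen$taxon[screen$timepoint == tp & screen$significant]
    sub <- filter_samples(ft, .data$timepoint == tp)
    rel <- aggregate_taxa(sub, rank)$rel_abund
    mean_rel <- rowMeans(rel)
    tibble::tibble(
      timepoint = tp, rank = rank, n_significant = length(sig),
      prop_community = sum(mean_rel[intersect(sig, names(mean_rel))])
    )
  })
}

#' Pairwise Mann-Whitney comparisons of one taxon between treatments
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) tests of a taxon's relative
#' abundance for every pair of treatment groups at one timepoint. Exact
#' p-values where no ties permit; normal approximation with tie correction
#' otherwise.
#'
#' @inheritParams kw_screen
#' @param taxon Taxon label at `rank`.
#' @param timepoint Single timepoint to compare within.
#' @param alpha Significance level.
#' @return A tibble per pair: `group1`, `group2`, `statistic` (U), `p_value`,
#'   `significant`.
#' @export
pairwise_mw <- function(ft, taxon, rank = "zotu", timepoint = NULL,
                        group = "corrinoid", alpha = 0.05,
                        exclude_uninoculated = TRUE) {
  stopifnot(inherits(ft, "feature_table"))
  if (exclude_uninoculated && any(!ft$samples$inoculated)) {
    ft <- filter_samples(ft, .data$inoculated)
  }
  if (!is.null(timepoint)) {
    tp <- timepoint
    ft <- filter_samples(ft, .data$timepoint == tp)
  }
  agg <- aggregate_taxa(ft, rank)
  if (!taxon %in% rownames(agg$rel_abund)) {
    abort(paste0("taxon not observed at rank ", rank, ": ", taxon))
  }
  g <- factor(agg$samples[[group]])
  sizes <- table(g)
  if (any(sizes < 2)) {
    abort(paste0("group(s) with a single replicate: ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  vals <- agg$rel_abund[taxon, ]
  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    wt <- suppressWarnings(
      wilcox.test(vals[g == p[1]], vals[g == p[2]], alternative = "two.sided")
    )
    tibble::tibble(group1 = p[1], group2 = p[2],
                   statistic = unname(wt$statistic), p_value = wt$p.value,
                   significant = wt$p.value <= alpha)
  })
}
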