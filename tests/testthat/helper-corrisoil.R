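# Fixture builders shared across test files. Everything is constructed in
# code; no fixture files.

# Minimal feature table: `counts` is a taxa x samples matrix; one corrinoid
# label per sample (recycled), single medium/timepoint unless given.
make_ft <- function(counts, corrinoid = "none", medium = "M9", timepoint = 1,
                    inoculated = TRUE, lineage = NULL) {
  n_tax <- nrow(counts)
  n_samp <- ncol(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("zotu_%03d", seq_len(n_tax))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("s%02d", seq_len(n_samp))
  }
  corrinoid <- rep(corrinoid, length.out = n_samp)
  samples <- tibble::tibble(
    sample_id = colnames(counts),
    medium = rep(medium, length.out = n_samp),
    corrinoid = corrinoid,
    timepoint = rep(timepoint, length.out = n_samp),
    replicate = stats::ave(seq_len(n_samp), corrinoid, FUN = seq_along),
    inoculated = rep(inoculated, length.out = n_samp)
  )
  if (is.null(lineage)) {
    lineage <- paste0("Phy", 1 + (seq_len(n_tax) - 1) %% 2,
                      ";c1;o", 1 + (seq_len(n_tax) - 1) %% 3, ";f1;g",
                      seq_len(n_tax))
  }
  taxonomy <- tibble::tibble(zotu_id = rownames(counts), lineage = lineage)
  feature_table(counts, samples, taxonomy)
}

# One-row annotation tibble per (genome, identifier) from a named list
# genome_id -> character vector of identifiers.
make_annotations <- function(detected, domain = "bacteria",
                             lineage = "Proteobacteria;c") {
  purrr::imap_dfr(detected, function(ids, g) {
    ids <- if (length(ids) == 0) "K00001" else ids
    tibble::tibble(genome_id = g, domain = domain, lineage = lineage,
                   annotation_id = ids)
  })
}

# Independent brute-force ANOSIM R: rank all pairwise distances, difference
# of mean between- and within-group ranks over N(N-1)/4.
brute_anosim_r <- function(d, groups) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  iu <- which(upper.tri(dm))
  r <- rank(dm[iu])
  between <- outer(groups, groups, FUN = "!=")[iu]
  (mean(r[between]) - mean(r[!between])) / (n * (n - 1) / 4)
}

# Independent one-factor PERMANOVA pseudo-F from sums of squared distances.
brute_pseudo_f <- function(d, groups) {
  dm <- as.matrix(d)^2
  n <- nrow(dm)
  k <- length(unique(groups))
  sst <- sum(dm[upper.tri(dm)]) / n
  ssw <- sum(vapply(unique(groups), function(g) {
    idx <- which(groups == g)
    sub <- dm[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]) / length(idx)
  }, numeric(1)))
  ((sst - ssw) / (k - 1)) / (ssw / (n - k))
}
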