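#' Bray-Curtis and Jaccard dissimilarity between samples
#'
#' `bray_curtis()` computes Bray-Curtis dissimilarity,
#' `BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i)`, on relative abundances at the
#' chosen rank. `jaccard()` computes the binary Jaccard distance,
#' `1 - |A intersect B| / |A union B|`, on presence/absence. Both delegate to
#' [vegan::vegdist()] and return a `dist` with a `metric` attribute; entries
#' lie in `[0, 1]`, the implicit diagonal is zero.
#'
#' @param x A [feature_table()], or a samples x taxa numeric matrix with
#'   sample rownames.
#' @param rank Taxonomy rank at which to aggregate (feature-table input only).
#' @return A `dist` over samples.
#' @export
bray_curtis <- function(x, rank = "zotu") {
  m <- sample_matrix(x, rank, relative = TRUE)
  d <- vegan::vegdist(m, method = "bray")
  attr(d, "metric") <- "bray_curtis"
  d
}

#' @rdname bray_curtis
#' @export
jaccard <- function(x, rank = "zotu") {
  m <- sample_matrix(x, rank, relative = FALSE)
  d <- vegan::vegdist(m > 0, method = "jaccard", binary = TRUE)
  attr(d, "metric") <- "jaccard"
  d
}

# samples in rows, taxa in columns, for vegan
sample_matrix <- function(x, rank = "zotu", relative = TRUE) {
  if (inherits(x, "feature_table")) {
    agg <- aggregate_taxa(x, rank)
    m <- t(if (relative) agg$rel_abund else agg$counts)
  } else {
    m <- as.matrix(x)
    if (is.null(rownames(m))) {
      abort("matrix input must have sample rownames.")
    }
    zero <- rownames(m)[rowSums(m) == 0]
    if (length(zero) > 0) {
      abort(paste0("sample(s) with all-zero counts: ",
                   paste(zero, collapse = ", ")))
    }
    if (relative) m <- sweep(m, 1, rowSums(m), "/")
  }
  m
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling: eigendecomposition of the double-centred squared
#' distance matrix (via [stats::cmdscale()]). Axes are ordered by eigenvalue;
#' the proportion of variance explained is computed over the positive
#' eigenvalues only. Negative eigenvalues (non-Euclidean input) are reported
#' unchanged; an optional Cailliez correction makes the input Euclidean
#' first.
#'
#' @param d A `dist` (e.g. from [bray_curtis()]) or symmetric matrix with
#'   zero diagonal.
#' @param k Number of axes to return. Default `n - 1`.
#' @param correction `"none"` (default) or `"cailliez"`.
#' @return An object of class `pcoa_ordination`: `coordinates` (tibble with
#'   `sample_id` and `axis1..k`), `eigenvalues`, `prop_explained`.
#' @export
pcoa_ordination <- function(d, k = NULL, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  if (!inherits(d, "dist")) {
    m <- as.matrix(d)
    if (!isSymmetric(unname(m)) || any(diag(m) != 0)) {
      abort("`d` must be a symmetric matrix with zero diagonal.")
    }
    d <- stats::as.dist(m)
  }
  n <- attr(d, "Size")
  if (is.null(k)) k <- n - 1L
  add <- correction == "cailliez"
  # cmdscale warns when fewer than k eigenvalues are positive; negative
  # eigenvalues are expected for non-Euclidean dissimilarities and reported
  fit <- suppressWarnings(cmdscale(d, k = k, eig = TRUE, add = add))

  eig <- fit$eig
  pos <- eig[eig > .Machine$double.eps * max(abs(eig))]
  naxes <- ncol(fit$points)
  prop <- eig[seq_len(naxes)] / sum(pos)
  prop[eig[seq_len(naxes)] <= 0] <- 0

  coords <- tibble::as_tibble(fit$points,
                              .name_repair = ~ paste0("axis", seq_len(naxes)))
  coords <- dplyr::bind_cols(
    tibble::tibble(sample_id = labels(d) %||% as.character(seq_len(n))),
    coords
  )
  structure(
    list(coordinates = coords, eigenvalues = eig, prop_explained = prop,
         correction = correction),
    class = "pcoa_ordination"
  )
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat("<pcoa_ordination>\n")
  cat(sprintf("  %d samples; axis 1-2 explain %.1f%% + %.1f%% of variance\n",
              nrow(x$coordinates), 100 * x$prop_explained[1],
              100 * (x$prop_explained[2] %||% 0)))
  if (any(x$eigenvalues < 0)) {
    cat(sprintf("  %d negative eigenvalue(s) excluded from proportions\n",
                sum(x$eigenvalues < 0)))
  }
  invisible(x)
}

#' @rdname pcoa_ordination
#' @param x,object A `pcoa_ordination`.
#' @param ... Unused.
#' @method tidy pcoa_ordination
#' @export
tidy.pcoa_ordination <- function(x, ...) x$coordinates

#' @rdname pcoa_ordination
#' @method glance pcoa_ordination
#' @export
glance.pcoa_ordination <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$coordinates),
    n_positive_eig = sum(x$eigenvalues > 0),
    n_negative_eig = sum(x$eigenvalues < 0),
    prop_axis1 = x$prop_explained[1],
    prop_axis2 = x$prop_explained[2] %||% NA_real_,
    correction = x$correction
  )
}
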