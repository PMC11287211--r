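# Internal helpers shared across modules.

# Collect validation failures and report them together rather than
# one-at-a-time; `what` names the object being validated.
check_all <- function(failures, what) {
  failures <- failures[!vapply(failures, is.null, logical(1))]
  if (length(failures) > 0) {
    abort(c(
      paste0("Invalid ", what, ":"),
      setNames(unlist(failures), rep("x", length(unlist(failures))))
    ))
  }
  invisible(TRUE)
}

fail_if <- function(cond, msg) if (isTRUE(cond)) msg else NULL

assert_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  if (nonneg && x < 0) abort(sprintf("`%s` must be >= 0.", name))
  invisible(x)
}

# Seed handling: all stochastic functions take an explicit `seed` and restore
# the caller's RNG state on exit.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Parse semicolon-delimited taxonomy lineages
#'
#' Splits QIIME-style lineage strings (`"Proteobacteria;Alphaproteobacteria;..."`)
#' into rank columns. Missing or empty ranks are filled with
#' `"unassigned_<rank>"` so that per-rank marginal counts always sum.
#'
#' @param lineage Character vector of semicolon-delimited lineages.
#' @param ranks Character vector of rank names, outermost first.
#' @return A tibble with one column per rank.
#' @examples
#' parse_lineage("Actinobacteria;Actinomycetia;Actinomycetales",
#'               ranks = c("phylum", "class", "order"))
#' @export
parse_lineage <- function(lineage,
                          ranks = c("phylum", "class", "order", "family", "genus")) {
  parts <- strsplit(as.character(lineage), ";", fixed = TRUE)
  out <- lapply(seq_along(ranks), function(i) {
    v <- vapply(parts, function(p) {
      x <- if (length(p) >= i) trimws(p[[i]]) else ""
      # tolerate greengenes-style rank prefixes such as "p__Actinobacteria"
      x <- sub("^[a-z]__", "", x)
      x
    }, character(1))
    v[is.na(v) | v == ""] <- paste0("unassigned_", ranks[i])
    v
  })
  names(out) <- ranks
  tibble::as_tibble(out)
}
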