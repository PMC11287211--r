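#' Marker-gene configuration for corrinoid role classification
#'
#' Defines the annotation identifiers (KEGG KO and Pfam) used to recognise
#' corrinoid biosynthesis capacity and corrinoid-dependent functions, together
#' with the corrinoid-independent alternative for each paired function.
#'
#' The biosynthesis markers are three corrin-ring synthesis steps, each with an
#' anaerobic/aerobic ortholog pair collapsing onto one KO: cbiC/cobH (K06042),
#' cbiF/cobM (K05936), cbiL/cobI (K03394). Their presence is highly correlated
#' with the complete de novo pathway, so one or more detections count a genome
#' as a potential producer.
#'
#' Class II (corrinoid-dependent) ribonucleotide reductase is detected through
#' Pfam PF08471 rather than KO K00525: K00525 conflates the Class I and
#' Class II enzymes, so it is deliberately absent from every default set
#' (including the Class I set; the beta subunit K00526 carries Class I
#' detection instead, alongside the anaerobic Class III K21636).
#'
#' The full identifier list for every corrinoid-dependent function is
#' community-curated and evolving; the defaults here seed the focal functions
#' and are fully editable, either through the arguments or via a YAML file
#' (see [read_marker_config()]; a template ships in
#' `system.file("extdata", "corrinoid_markers.yml", package = "corrisoil")`).
#'
#' @param biosynthesis Character vector of biosynthesis marker identifiers.
#' @param dependent Named list: function name -> identifiers of the
#'   corrinoid-dependent enzyme. Must contain a `ribonucleotide_reductase`
#'   entry keyed to PF08471 (not K00525). Functions without a
#'   corrinoid-independent alternative (e.g. archaeal methyltransferases) may
#'   appear here unpaired.
#' @param independent Named list: function name -> identifiers of the
#'   corrinoid-independent alternative. Names must be a subset of
#'   `names(dependent)`.
#' @return A validated object of class `marker_config`.
#' @examples
#' cfg <- marker_config()
#' cfg$dependent$ribonucleotide_reductase
#' @export
marker_config <- function(
    biosynthesis = c("K06042", "K05936", "K03394"),
    dependent = list(
      methionine_synthase      = "K00548",
      methylmalonyl_coa_mutase = c("K01847", "K01848", "K01849"),
      epoxyqueuosine_reductase = "K18979",
      ribonucleotide_reductase = "PF08471",
      corrinoid_methyltransferase = c("K00577", "K00584")
    ),
    independent = list(
      methionine_synthase      = "K00549",
      methylmalonyl_coa_mutase = c("K01659", "K03417", "K01720"),
      epoxyqueuosine_reductase = "K25284",
      ribonucleotide_reductase = c("K00526", "K21636")
    )) {
  biosynthesis <- unique(as.character(biosynthesis))
  dependent <- lapply(dependent, function(x) unique(as.character(x)))
  independent <- lapply(independent, function(x) unique(as.character(x)))

  shared <- intersect(names(independent), names(dependent))
  overlap_fns <- shared[vapply(
    shared,
    function(f) length(intersect(dependent[[f]], independent[[f]])) > 0,
    logical(1)
  )]

  check_all(list(
    fail_if(length(biosynthesis) == 0, "`biosynthesis` must be nonempty."),
    fail_if(is.null(names(dependent)) || any(names(dependent) == ""),
            "`dependent` must be a fully named list."),
    fail_if(length(independent) > 0 &&
              (is.null(names(independent)) || any(names(independent) == "")),
            "`independent` must be a fully named list."),
    fail_if(!all(names(independent) %in% names(dependent)),
            paste("every `independent` function must pair with a `dependent`",
                  "function of the same name")),
    fail_if(length(overlap_fns) > 0,
            paste0("identifier(s) appear in both the dependent and ",
                   "independent set of: ", paste(overlap_fns, collapse = ", "))),
    fail_if("K00525" %in% dependent$ribonucleotide_reductase,
            "K00525 conflates Class I and II RNR; use PF08471 instead.")
  ), "marker_config")

  structure(
    list(biosynthesis = biosynthesis, dependent = dependent,
         independent = independent),
    class = "marker_config"
  )
}

#' @export
print.marker_config <- function(x, ...) {
  cat("<marker_config>\n")
  cat("  biosynthesis markers:", paste(x$biosynthesis, collapse = ", "), "\n")
  cat("  corrinoid-dependent functions:\n")
  for (f in names(x$dependent)) {
    alt <- if (f %in% names(x$independent)) {
      paste0("  |  independent alt: ", paste(x$independent[[f]], collapse = ", "))
    } else "  |  (no independent alternative)"
    cat("    ", f, ": ", paste(x$dependent[[f]], collapse = ", "), alt, "\n",
        sep = "")
  }
  invisible(x)
}

#' Read a marker configuration from a YAML file
#'
#' The file must contain top-level keys `biosynthesis`, `dependent` and
#' `independent` mirroring the arguments of [marker_config()].
#'
#' @param path Path to a YAML file.
#' @return A validated `marker_config`.
#' @export
read_marker_config <- function(path) {
  if (!file.exists(path)) abort(paste0("marker config file not found: ", path))
  y <- yaml::read_yaml(path)
  missing <- setdiff(c("biosynthesis", "dependent", "independent"), names(y))
  if (length(missing) > 0) {
    abort(paste0("marker config missing key(s): ", paste(missing, collapse = ", ")))
  }
  marker_config(biosynthesis = y$biosynthesis, dependent = y$dependent,
                independent = y$independent)
}
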