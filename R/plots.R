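#' Plot a PCoA ordination
#'
#' Scatter of the first two principal coordinates with the percent variance
#' explained on each axis label; points can be coloured by a grouping vector
#' (e.g. corrinoid treatment).
#'
#' @param object A [pcoa_ordination()].
#' @param colour Optional grouping vector, one value per sample.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pcoa_ordination
#' @export
autoplot.pcoa_ordination <- function(object, colour = NULL, ...) {
  df <- object$coordinates
  lab <- function(i) sprintf("PCo%d (%.1f%%)", i,
                             100 * object$prop_explained[i])
  p <- if (is.null(colour)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$axis1, y = .data$axis2))
  } else {
    df$group <- colour
    ggplot2::ggplot(df, ggplot2::aes(x = .data$axis1, y = .data$axis2,
                                     colour = .data$group))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = lab(1), y = lab(2), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a serial-extraction partition fit
#'
#' Observed aqueous concentrations by round on a log scale, the geometric
#' decay implied by the fitted mean K_d, and the window of rounds used.
#'
#' @param object A `partition_fit` from [estimate_kd()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot partition_fit
#' @export
autoplot.partition_fit <- function(object, ...) {
  s <- object$series
  ratio <- object$geometry$vol_aq / object$geometry$vol_soil
  n0 <- object$rounds_used[1]
  a0 <- s$aq_conc_nM[s$round == n0]
  fit_line <- tibble::tibble(
    round = seq(object$rounds_used[1], object$rounds_used[2]),
    aq_conc_nM = a0 / (1 + object$kd_mean * ratio)^(seq(object$rounds_used[1],
                                                        object$rounds_used[2]) - n0)
  )
  ggplot2::ggplot(s, ggplot2::aes(x = .data$round, y = .data$aq_conc_nM)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = fit_line, colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "extraction round",
                  y = "aqueous corrinoid (nM cobalamin equivalents)",
                  subtitle = sprintf("K_d = %.3g +/- %.3g (rounds %d-%d)",
                                     object$kd_mean, object$kd_sd,
                                     object$rounds_used[1],
                                     object$rounds_used[2])) +
    ggplot2::theme_minimal()
}

#' Bar plot of responsive-taxon fractions across taxonomy ranks
#'
#' @param fractions A tibble binding [responsive_fraction_count()] rows over
#'   ranks (columns `rank`, `fraction`).
#' @return A ggplot.
#' @export
plot_responsive_fractions <- function(fractions) {
  fractions$rank <- factor(fractions$rank, levels = unique(fractions$rank))
  ggplot2::ggplot(fractions,
                  ggplot2::aes(x = .data$rank, y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "corrinoid-responsive taxa") +
    ggplot2::theme_minimal()
}
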