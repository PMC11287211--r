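#' Fit a bioassay standard curve
#'
#' Calibrates the growth response (OD600 after 24 h) of a
#' corrinoid-requiring indicator strain against known cobalamin
#' concentrations. The curve is a monotone piecewise-linear interpolant of
#' mean OD versus log10(concentration) — a transparent, auditably monotone
#' choice that makes no parametric assumption about the dose-response shape.
#'
#' Censoring thresholds:
#' * limit of detection (OD): blank mean + `lod_multiplier` x blank sd;
#'   sample readings at or below it are censored `below_LOD`;
#' * saturation: readings above the highest calibration OD are censored
#'   `above_saturation` (the response plateaus near `saturation_conc`,
#'   1 nM cobalamin by default).
#'
#' The quantitation range spans the lowest standard responding above the
#' blank mean up to the concentration at which the curve enters its plateau
#' (first standard with OD at or above `plateau_frac` of the maximum mean OD;
#' the top standard if none does before it).
#'
#' @param calibration Data frame with columns `conc_nM` and `od600`;
#'   replicate rows per concentration are averaged.
#' @param blanks Numeric vector of zero-corrinoid OD600 readings, or a data
#'   frame with an `od600` column.
#' @param saturation_conc Concentration (nM) at which the response is
#'   considered saturated. Default 1 nM.
#' @param lod_multiplier Blank-sd multiplier for the LOD OD. Default 3.
#' @param plateau_frac Fraction of the maximum mean OD that defines entry
#'   into the plateau. Default 0.95.
#' @param monotone_tol Tolerated OD decrease between successive mean ODs
#'   before the fit is rejected as non-monotone. Default 0.01.
#' @return An object of class `standard_curve`.
#' @examples
#' cal <- data.frame(conc_nM = c(0.01, 0.1, 1), od600 = c(0.12, 0.40, 0.80))
#' curve <- fit_standard_curve(cal, blanks = c(0.09, 0.10, 0.11))
#' curve$lod_od
#' @export
fit_standard_curve <- function(calibration, blanks, saturation_conc = 1.0,
                               lod_multiplier = 3, plateau_frac = 0.95,
                               monotone_tol = 0.01) {
  calibration <- tibble::as_tibble(calibration)
  if (!all(c("conc_nM", "od600") %in% names(calibration))) {
    abort("`calibration` needs columns `conc_nM` and `od600`.")
  }
  if (is.data.frame(blanks)) blanks <- blanks$od600
  blanks <- as.numeric(blanks)
  assert_scalar_number(saturation_conc, "saturation_conc", positive = TRUE)

  pts <- calibration |>
    dplyr::filter(!is.na(.data$od600)) |>
    dplyr::group_by(conc_nM = .data$conc_nM) |>
    dplyr::summarise(od_mean = mean(.data$od600),
                     od_sd = sd(.data$od600),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$conc_nM)

  check_all(list(
    fail_if(nrow(pts) < 3, "need calibration points at >= 3 concentrations."),
    fail_if(length(blanks) < 2, "need >= 2 blank readings."),
    fail_if(any(pts$conc_nM <= 0), "calibration concentrations must be > 0."),
    fail_if(any(diff(pts$od_mean) < -monotone_tol),
            "mean OD decreases with concentration beyond tolerance."),
    fail_if(diff(range(pts$od_mean)) <= monotone_tol,
            "calibration ODs do not increase with concentration.")
  ), "standard curve calibration")

  blank_mean <- mean(blanks)
  blank_sd <- sd(blanks)
  lod_od <- blank_mean + lod_multiplier * blank_sd
  plateau_od <- max(pts$od_mean)

  responding <- pts$conc_nM[pts$od_mean > blank_mean]
  if (length(responding) == 0) {
    abort("no calibration point responds above the blank mean.")
  }
  at_plateau <- pts$conc_nM[pts$od_mean >= plateau_frac * plateau_od]
  quant_range <- c(min(responding), min(at_plateau))

  # inversion needs strictly increasing ODs across the knots actually used
  used <- pts[pts$conc_nM >= quant_range[1] & pts$conc_nM <= quant_range[2], ]
  if (nrow(used) < 2 || any(diff(used$od_mean) <= 0)) {
    abort("calibration not strictly increasing within the quantitation range.")
  }

  structure(
    list(points = pts, blank_mean = blank_mean, blank_sd = blank_sd,
         lod_od = lod_od, plateau_od = plateau_od,
         saturation_conc = saturation_conc, plateau_frac = plateau_frac,
         quant_range = quant_range, knots = used),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("<standard_curve>\n")
  cat(sprintf("  %d calibration concentrations, %.3g-%.3g nM\n",
              nrow(x$points), min(x$points$conc_nM), max(x$points$conc_nM)))
  cat(sprintf("  blank OD %.3f +/- %.3f; LOD OD %.3f\n",
              x$blank_mean, x$blank_sd, x$lod_od))
  cat(sprintf("  quantitation range [%.3g, %.3g] nM\n",
              x$quant_range[1], x$quant_range[2]))
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param x,object A `standard_curve`.
#' @param ... Unused.
#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) x$points

#' @rdname fit_standard_curve
#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble::tibble(
    n_points = nrow(x$points), blank_mean = x$blank_mean,
    blank_sd = x$blank_sd, lod_od = x$lod_od, plateau_od = x$plateau_od,
    quant_lo_nM = x$quant_range[1], quant_hi_nM = x$quant_range[2],
    saturation_conc = x$saturation_conc
  )
}

# forward interpolant: OD at a concentration (nM)
predict_od <- function(curve, conc_nM) {
  approx(log10(curve$knots$conc_nM), curve$knots$od_mean,
         xout = log10(conc_nM), rule = 2)$y
}

#' Convert OD readings to cobalamin-equivalent concentrations
#'
#' Inverse-interpolates OD600 readings on a fitted [fit_standard_curve()].
#' Each reading receives exactly one of: a concentration (`flag = "none"`), a
#' `below_LOD` flag (OD at or below the LOD OD, or below the lowest usable
#' calibration response), or an `above_saturation` flag (OD above the highest
#' calibration OD). Outputs are cobalamin equivalents: the indicator strain
#' responds to distinct corrinoids with different sensitivities, and no
#' corrinoid-specific correction is attempted.
#'
#' @param od Numeric vector of OD600 readings.
#' @param curve A `standard_curve`.
#' @param sample_id Optional identifiers (recycled against `od`).
#' @return A tibble: `sample_id`, `od_used`, `conc_nM` (NA when censored),
#'   `flag` (`"none"`, `"below_LOD"`, `"above_saturation"`).
#' @export
od_to_concentration <- function(od, curve, sample_id = NULL) {
  stopifnot(inherits(curve, "standard_curve"))
  od <- as.numeric(od)
  if (any(od < 0, na.rm = TRUE)) abort("negative OD readings are invalid.")
  if (is.null(sample_id)) sample_id <- paste0("sample_", seq_along(od))

  k <- curve$knots
  hi_od <- max(k$od_mean)
  flag <- dplyr::case_when(
    od <= curve$lod_od | od < min(k$od_mean) ~ "below_LOD",
    od > hi_od ~ "above_saturation",
    .default = "none"
  )
  conc <- rep(NA_real_, length(od))
  ok <- flag == "none"
  if (any(ok)) {
    conc[ok] <- 10^approx(k$od_mean, log10(k$conc_nM), xout = od[ok])$y
  }
  tibble::tibble(sample_id = as.character(sample_id), od_used = od,
                 conc_nM = conc, flag = flag)
}

#' Quantify a bioassay plate against a standard curve
#'
#' Averages replicate OD readings per sample (default) and inverts them with
#' [od_to_concentration()]; `average_replicates = FALSE` inverts each well
#' separately.
#'
#' @param plate Data frame with columns `sample_id` and `od600`.
#' @param curve A `standard_curve`.
#' @param average_replicates Average replicate wells before inversion?
#' @return A tibble as from [od_to_concentration()] (plus `n_replicates`
#'   when averaging).
#' @export
quantify_plate <- function(plate, curve, average_replicates = TRUE) {
  plate <- tibble::as_tibble(plate)
  if (!all(c("sample_id", "od600") %in% names(plate))) {
    abort("`plate` needs columns `sample_id` and `od600`.")
  }
  if (average_replicates) {
    agg <- plate |>
      dplyr::group_by(sample_id = .data$sample_id) |>
      dplyr::summarise(od600 = mean(.data$od600), n_replicates = dplyr::n(),
                       .groups = "drop")
    out <- od_to_concentration(agg$od600, curve, sample_id = agg$sample_id)
    out$n_replicates <- agg$n_replicates
    out
  } else {
    od_to_concentration(plate$od600, curve, sample_id = plate$sample_id)
  }
}
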