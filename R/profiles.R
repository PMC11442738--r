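#' Parametric seasonal flux profile for a crop
#'
#' A `crop_profile` holds the noise-free "truth" used by the synthetic scene
#' generator: a Gaussian-bump daily ET curve (mm d^-1), a logistic rise/fall
#' canopy-fraction curve in \[0, 1\], a baseline water-use efficiency, and the
#' observation-noise parameters (per-pixel Gaussian noise, missing-day rate).
#'
#' The ET curve is `et_base + et_peak * exp(-0.5 * ((d - peak_day)/et_width)^2)`
#' so it is nonnegative for nonnegative `et_base` and `et_peak`. The canopy
#' curve is `canopy_max * plogis((d - green_up)/k) * plogis((senescence - d)/k)`
#' with `k = canopy_steepness` days, which stays strictly inside \[0, 1\].
#'
#' @param name Crop label (e.g. `"chia"`, `"alfalfa"`).
#' @param season_start,season_end Planting and harvest dates (`Date` or
#'   coercible); `season_start` must precede `season_end`.
#' @param et_base Baseline ET in mm d^-1 (soil evaporation floor).
#' @param et_peak Peak-season ET amplitude above baseline, mm d^-1.
#' @param peak_day Date of peak ET; defaults to mid-season.
#' @param et_width Gaussian width of the ET peak, days.
#' @param canopy_max Maximum canopy fraction, in \[0, 1\].
#' @param green_up Date at which canopy reaches half of `canopy_max` on the
#'   way up; defaults to 20% into the season.
#' @param senescence Date of the half-maximum on the way down; defaults to
#'   10% before season end.
#' @param canopy_steepness Logistic time constant, days.
#' @param wue_base Water-use efficiency, g C per kg H2O.
#' @param pixel_noise_sd Per-pixel per-day Gaussian noise SD on ET, mm d^-1.
#'   Noise on the other simulated layers scales proportionally, so
#'   `pixel_noise_sd = 0` gives a fully noise-free scene.
#' @param missing_day_rate Probability in \[0, 1\] that a given day's layer is
#'   absent (satellite revisit gap).
#' @return An object of class `crop_profile`.
#' @seealso [et_curve()], [canopy_curve()], [generate_site_season()],
#'   [true_season_ratio()]
#' @examples
#' chia <- crop_profile("chia", "2022-06-01", "2022-09-30")
#' plot(et_curve(chia, seq(as.Date("2022-06-01"), as.Date("2022-09-30"), 1)))
#' @export
crop_profile <- function(name, season_start, season_end,
                         et_base = 1.5, et_peak = 4.0, peak_day = NULL,
                         et_width = 30,
                         canopy_max = 0.9, green_up = NULL, senescence = NULL,
                         canopy_steepness = 8,
                         wue_base = 2.0,
                         pixel_noise_sd = 1.0, missing_day_rate = 0.3) {
  season_start <- as.Date(season_start)
  season_end <- as.Date(season_end)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("`name` must be a single non-empty string")
  if (!(season_start < season_end))
    stop("`season_start` must precede `season_end`")
  if (et_base < 0 || et_peak < 0) stop("ET curve parameters must be >= 0")
  if (canopy_max < 0 || canopy_max > 1) stop("`canopy_max` must be in [0, 1]")
  if (pixel_noise_sd < 0) stop("`pixel_noise_sd` must be >= 0")
  if (missing_day_rate < 0 || missing_day_rate > 1)
    stop("`missing_day_rate` must be in [0, 1]")
  if (wue_base < 0) stop("`wue_base` must be >= 0")
  len <- as.numeric(season_end - season_start)
  peak_day <- if (is.null(peak_day)) season_start + round(len / 2) else as.Date(peak_day)
  green_up <- if (is.null(green_up)) season_start + round(0.2 * len) else as.Date(green_up)
  senescence <- if (is.null(senescence)) season_end - round(0.1 * len) else as.Date(senescence)
  structure(list(
    name = name, season_start = season_start, season_end = season_end,
    et_base = et_base, et_peak = et_peak, peak_day = peak_day,
    et_width = et_width, canopy_max = canopy_max, green_up = green_up,
    senescence = senescence, canopy_steepness = canopy_steepness,
    wue_base = wue_base, pixel_noise_sd = pixel_noise_sd,
    missing_day_rate = missing_day_rate
  ), class = "crop_profile")
}

#' @export
print.crop_profile <- function(x, ...) {
  cat(sprintf(
    "<crop_profile '%s'> season %s to %s\n  ET %.2f + %.2f mm/d (peak %s, width %g d); canopy max %.2f; WUE %.2f g C/kg\n  pixel noise sd %.2f mm/d; missing-day rate %.2f\n",
    x$name, format(x$season_start), format(x$season_end),
    x$et_base, x$et_peak, format(x$peak_day), x$et_width,
    x$canopy_max, x$wue_base, x$pixel_noise_sd, x$missing_day_rate))
  invisible(x)
}

#' Noise-free daily ET curve of a crop profile
#'
#' @param profile A [crop_profile()].
#' @param dates `Date` vector.
#' @return Numeric vector of ET in mm d^-1, one value per date, always >= 0.
#' @export
et_curve <- function(profile, dates) {
  stopifnot(inherits(profile, "crop_profile"))
  d <- as.numeric(as.Date(dates) - profile$peak_day)
  profile$et_base + profile$et_peak * exp(-0.5 * (d / profile$et_width)^2)
}

#' Noise-free daily canopy-fraction curve of a crop profile
#'
#' @inheritParams et_curve
#' @return Numeric vector of canopy fractions in \[0, 1\].
#' @export
canopy_curve <- function(profile, dates) {
  stopifnot(inherits(profile, "crop_profile"))
  d <- as.Date(dates)
  up <- stats::plogis(as.numeric(d - profile$green_up) / profile$canopy_steepness)
  down <- stats::plogis(as.numeric(profile$senescence - d) / profile$canopy_steepness)
  profile$canopy_max * up * down
}

#' Ground-truth seasonal ET ratio of two crop profiles
#'
#' Day-by-day sum of the noise-free ET curve of `profile_a` over a window,
#' divided by the same sum for `profile_b`. This is the quantity the
#' zonal-stats -> monthly-mean -> season-total pipeline is expected to
#' recover from a synthetic scene, and the reference value in
#' parameter-recovery tests.
#'
#' @param profile_a,profile_b [crop_profile()] objects (numerator,
#'   denominator).
#' @param window Length-2 vector of dates `c(start, end)`.
#' @return The ratio of seasonal ET totals (dimensionless).
#' @export
true_season_ratio <- function(profile_a, profile_b, window) {
  stopifnot(inherits(profile_a, "crop_profile"),
            inherits(profile_b, "crop_profile"))
  window <- as.Date(window)
  if (length(window) != 2L || !(window[1] <= window[2]))
    stop("`window` must be c(start, end) with start <= end")
  days <- seq(window[1], window[2], by = "day")
  num <- sum(et_curve(profile_a, days))
  den <- sum(et_curve(profile_b, days))
  if (den == 0) stop("denominator profile has zero seasonal consumption")
  num / den
}
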