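#' Ratio of a crop's seasonal value to chia's
#'
#' For water-consumption variables (ET, transpiration) the conventional
#' orientation is crop:chia, where values above 1 mean chia used less
#' water; for efficiency variables (WUE, transpiration-only WUE) it is
#' chia:crop, where values above 1 mean chia fixed more carbon per unit
#' water.
#'
#' @param crop_value,chia_value Seasonal statistics, both > 0 (vectorized).
#' @param orientation `"crop_over_chia"` or `"chia_over_crop"`.
#' @return The ratio(s).
#' @export
season_ratio <- function(crop_value, chia_value,
                         orientation = c("crop_over_chia", "chia_over_crop")) {
  orientation <- match.arg(orientation)
  if (any(crop_value <= 0, na.rm = TRUE) || any(chia_value <= 0, na.rm = TRUE))
    stop("seasonal values must be > 0")
  if (orientation == "crop_over_chia") crop_value / chia_value
  else chia_value / crop_value
}

#' Summarize per-season ratios across site-seasons
#'
#' Mean ratio across seasons with its standard error (sample SD over
#' sqrt(n); `NA` with a message for a single season) and a
#' percent-difference rendering: for crop:chia ratios,
#' `(1 - 1/mean) * 100` "% less water used by chia"; for chia:crop ratios,
#' `(mean - 1) * 100` "% higher for chia". Both the raw ratio and the
#' percent are always reported so neither convention loses information.
#'
#' @param ratios Numeric vector of per-season ratios, all > 0, optionally
#'   named by site-season.
#' @param orientation As in [season_ratio()].
#' @param parameter,crop Optional labels carried into the summary.
#' @param verbose Report a single-season SE (default `TRUE`).
#' @return An object of class `ratio_summary`: list with `mean`, `se`,
#'   `n_seasons`, `percent`, `percent_label`, `orientation`, `parameter`,
#'   `crop`, `ratios`.
#' @examples
#' summarize_ratios(c(1.1, 1.2, 1.3, 1.4), "crop_over_chia",
#'                  parameter = "ET_total", crop = "alfalfa")
#' @export
summarize_ratios <- function(ratios,
                             orientation = c("crop_over_chia", "chia_over_crop"),
                             parameter = NULL, crop = NULL, verbose = TRUE) {
  orientation <- match.arg(orientation)
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) == 0L) stop("no ratios supplied")
  if (any(ratios <= 0)) stop("ratios must be > 0")
  n <- length(ratios)
  m <- mean(ratios)
  se <- if (n >= 2L) stats::sd(ratios) / sqrt(n) else {
    if (verbose) message("single season: standard error undefined")
    NA_real_
  }
  if (orientation == "crop_over_chia") {
    pct <- (1 - 1 / m) * 100
    lab <- "% less water used by chia"
  } else {
    pct <- (m - 1) * 100
    lab <- "% higher for chia"
  }
  structure(list(mean = m, se = se, n_seasons = n, percent = pct,
                 percent_label = lab, orientation = orientation,
                 parameter = parameter, crop = crop, ratios = ratios),
            class = "ratio_summary")
}

#' @export
print.ratio_summary <- function(x, ...) {
  hdr <- paste(c(x$crop, x$parameter), collapse = " ")
  if (nzchar(hdr)) hdr <- paste0(hdr, " ")
  cat(sprintf("<ratio_summary> %s(%s)\n", hdr,
              sub("_over_", ":", x$orientation)))
  cat(sprintf("  mean ratio %.4f (SE %s, n = %d) -> %.1f%s\n",
              x$mean,
              if (is.na(x$se)) "NA" else sprintf("%.4f", x$se),
              x$n_seasons, x$percent, x$percent_label))
  invisible(x)
}

#' @export
as.data.frame.ratio_summary <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(parameter = x$parameter %||% NA_character_,
             crop = x$crop %||% NA_character_,
             orientation = x$orientation, mean = x$mean, se = x$se,
             n_seasons = x$n_seasons, percent = x$percent)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-day crop/chia ratio series
#'
#' Joins two daily series on their dates, computes the per-date ratio in
#' the requested orientation, and reports the mean of the daily ratios.
#' Dates present in only one series are dropped with a message; days with a
#' nonpositive value are dropped with a warning (the ratio is undefined).
#'
#' @param crop,chia Data frames with columns `date` and `value`.
#' @param orientation As in [season_ratio()].
#' @param verbose Report dropped dates (default `TRUE`).
#' @return List with `ratios` (data frame `date`, `ratio`) and `mean`.
#' @export
daily_ratio_series <- function(crop, chia,
                               orientation = c("crop_over_chia",
                                               "chia_over_crop"),
                               verbose = TRUE) {
  orientation <- match.arg(orientation)
  stopifnot(is.data.frame(crop), is.data.frame(chia),
            all(c("date", "value") %in% names(crop)),
            all(c("date", "value") %in% names(chia)))
  m <- merge(crop[, c("date", "value")], chia[, c("date", "value")],
             by = "date", suffixes = c("_crop", "_chia"))
  if (nrow(m) == 0L) stop("no overlapping dates between the two series")
  dropped <- nrow(crop) + nrow(chia) - 2L * nrow(m)
  if (verbose && dropped > 0L)
    message(dropped, " unmatched daily record(s) dropped")
  bad <- is.na(m$value_crop) | is.na(m$value_chia) |
    m$value_crop <= 0 | m$value_chia <= 0
  if (any(bad)) {
    warning(sum(bad), " day(s) with missing or nonpositive values dropped")
    m <- m[!bad, , drop = FALSE]
    if (nrow(m) == 0L) stop("no valid overlapping days remain")
  }
  r <- season_ratio(m$value_crop, m$value_chia, orientation)
  list(ratios = data.frame(date = m$date, ratio = r), mean = mean(r))
}

#' Regress daily crop/chia ratios on air temperature
#'
#' Ordinary least-squares fit of `ratio ~ temperature`, with the two-tailed
#' t-test of the slope (`t = slope / SE(slope)` on n - 2 degrees of
#' freedom) used to judge whether temperature modulates the crops' relative
#' performance.
#'
#' @param temps Either a numeric vector of temperatures (deg C) paired with
#'   `ratios`, or a data frame with columns `date` and `tair_c` joined to
#'   `ratios` by date.
#' @param ratios Either a numeric vector, or a data frame with columns
#'   `date` and `ratio` (as produced by [daily_ratio_series()]).
#' @param parameter,crop Optional labels.
#' @return An object of class `temp_regression`: `slope`, `intercept`,
#'   `t_statistic`, `p_value`, `n_points`, plus the underlying `lm` fit.
#' @export
temp_regression <- function(temps, ratios, parameter = NULL, crop = NULL) {
  if (is.data.frame(temps) || is.data.frame(ratios)) {
    stopifnot(is.data.frame(temps), is.data.frame(ratios),
              all(c("date", "tair_c") %in% names(temps)),
              all(c("date", "ratio") %in% names(ratios)))
    m <- merge(temps[, c("date", "tair_c")], ratios[, c("date", "ratio")],
               by = "date")
    x <- m$tair_c; y <- m$ratio
  } else {
    if (length(temps) != length(ratios))
      stop("`temps` and `ratios` must have equal length")
    x <- temps; y <- ratios
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 matched (temperature, ratio) points")
  if (stats::var(x) == 0) stop("temperature has zero variance")
  fit <- stats::lm(y ~ x)
  cf <- summary(fit)$coefficients
  structure(list(parameter = parameter, crop = crop,
                 slope = cf["x", "Estimate"],
                 intercept = cf["(Intercept)", "Estimate"],
                 t_statistic = cf["x", "t value"],
                 p_value = cf["x", "Pr(>|t|)"],
                 n_points = n, fit = fit),
            class = "temp_regression")
}

#' @export
print.temp_regression <- function(x, ...) {
  hdr <- paste(c(x$crop, x$parameter), collapse = " ")
  cat(sprintf("<temp_regression>%s\n",
              if (nzchar(hdr)) paste0(" ", hdr) else ""))
  cat(sprintf("  ratio = %.4g + %.4g * T;  t = %.3f, p = %.4g (n = %d)\n",
              x$intercept, x$slope, x$t_statistic, x$p_value, x$n_points))
  invisible(x)
}
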