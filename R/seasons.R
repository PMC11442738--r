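#' Growing-season window for one crop at one site-season
#'
#' @param crop Crop label the window applies to.
#' @param site_season Identifier of the site x year combination.
#' @param start,end Window dates (planting to harvest); `start < end`.
#' @return An object of class `season_window`.
#' @export
season_window <- function(crop, site_season, start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (!(start < end)) stop("`start` must precede `end`")
  structure(list(crop = as.character(crop),
                 site_season = as.character(site_season),
                 start = start, end = end),
            class = "season_window")
}

#' Monthly daily-means of flux variables within a season window
#'
#' Aggregation deliberately runs pixels -> field mean (in the zonal step),
#' fields of the same crop -> crop-day mean, days -> month mean, so that
#' months with dense and sparse satellite coverage carry equal weight in the
#' season statistics (an uneven distribution of overpasses cannot dominate
#' the season). Months inside the window with no observations for a
#' variable are omitted with a message.
#'
#' @param flux Data frame from [flux_series()] (or any frame with `crop`,
#'   `date` and the requested variable columns).
#' @param window A [season_window()].
#' @param variables Variables to aggregate (those absent from `flux` are
#'   skipped).
#' @param verbose Report omitted months (default `TRUE`).
#' @return Data frame with one row per month x variable: `site_season`,
#'   `crop`, `month` (`"YYYY-MM"`), `variable`, `mean`, `n_obs` (days with
#'   data), `days_in_window` (window days falling in that month) and
#'   `days_in_month` (calendar length).
#' @export
monthly_means <- function(flux, window,
                          variables = c("et", "transpiration", "wue", "wue_t"),
                          verbose = TRUE) {
  stopifnot(is.data.frame(flux), inherits(window, "season_window"),
            all(c("crop", "date") %in% names(flux)))
  d <- flux[flux$crop == window$crop &
              flux$date >= window$start & flux$date <= window$end, ,
            drop = FALSE]
  variables <- intersect(variables, names(flux))
  if (length(variables) == 0L) stop("none of `variables` present in `flux`")
  if (nrow(d) == 0L)
    stop(sprintf("no observations for crop '%s' in window %s..%s",
                 window$crop, format(window$start), format(window$end)))
  win_days <- seq(window$start, window$end, by = "day")
  dw <- table(format(win_days, "%Y-%m"))
  months <- names(dw)
  dim_full <- vapply(months, function(m) {
    first <- as.Date(paste0(m, "-01"))
    as.integer(format(seq(first, by = "month", length.out = 2)[2] - 1, "%d"))
  }, integer(1))

  out <- list()
  for (v in variables) {
    dv <- d[!is.na(d[[v]]), c("date", v)]
    if (nrow(dv) == 0L) next
    # pool fields of the same crop per day first
    daily <- stats::aggregate(dv[[v]], by = list(date = dv$date), FUN = mean)
    mo <- format(daily$date, "%Y-%m")
    mmean <- tapply(daily$x, mo, mean)
    nobs <- tapply(daily$x, mo, length)
    present <- months[months %in% names(mmean)]
    absent <- setdiff(months, present)
    if (verbose && length(absent))
      message(sprintf("variable '%s': no observations in month(s) %s (omitted)",
                      v, paste(absent, collapse = ", ")))
    if (!length(present)) next
    out[[v]] <- data.frame(site_season = window$site_season,
                           crop = window$crop, month = present, variable = v,
                           mean = unname(mmean[present]),
                           n_obs = as.integer(nobs[present]),
                           days_in_window = as.integer(dw[present]),
                           days_in_month = dim_full[match(present, months)])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Growing-season total from monthly means
#'
#' Each month's daily mean is multiplied by the number of days and summed.
#' By default an edge month truncated by the season window contributes only
#' the days of the window inside it (`days_in_window`); seasons that start
#' late in a month or end early in one are therefore not overcounted.
#' `full_month = TRUE` switches to calendar month lengths for sensitivity
#' checks.
#'
#' @param means Data frame from [monthly_means()].
#' @param variable Which variable to total (default `"et"`).
#' @param full_month Weight months by calendar length instead of in-window
#'   days.
#' @return The seasonal total (same unit as the variable, times days; for
#'   ET in L ha^-1 d^-1 this is L ha^-1 per season).
#' @export
season_total <- function(means, variable = "et", full_month = FALSE) {
  m <- means[means$variable == variable, , drop = FALSE]
  if (nrow(m) == 0L) stop("no monthly means for variable '", variable, "'")
  days <- if (full_month) m$days_in_month else m$days_in_window
  sum(m$mean * days)
}

#' Growing-season daily mean from monthly means
#'
#' Unweighted mean of the monthly means (not day-weighted), so each month
#' contributes equally regardless of its observation density.
#'
#' @inheritParams season_total
#' @return The season-average daily value.
#' @export
season_daily_mean <- function(means, variable = "et") {
  m <- means[means$variable == variable, , drop = FALSE]
  if (nrow(m) == 0L) stop("no monthly means for variable '", variable, "'")
  mean(m$mean)
}

#' Summarize one or more site-seasons
#'
#' Runs [monthly_means()] for each window and assembles the per
#' crop x site-season statistics used by the ratio analysis: ET and
#' transpiration season totals, season daily means, and WUE /
#' transpiration-only WUE season means.
#'
#' @param flux Data frame from [flux_series()].
#' @param windows A [season_window()] or list of them.
#' @param full_month Passed to [season_total()].
#' @param verbose Passed to [monthly_means()].
#' @return Data frame with one row per window: `site_season`, `crop`,
#'   `et_total`, `t_total` (L ha^-1 per season; `NA` when the variable is
#'   unavailable), `et_daily_mean`, `t_daily_mean`, `wue_mean`,
#'   `wue_t_mean`, `months_used`.
#' @export
season_summary <- function(flux, windows, full_month = FALSE, verbose = TRUE) {
  if (inherits(windows, "season_window")) windows <- list(windows)
  rows <- lapply(windows, function(w) {
    mm <- monthly_means(flux, w, verbose = verbose)
    g <- function(fun, v) {
      if (is.null(mm) || !v %in% mm$variable) return(NA_real_)
      fun(mm, v)
    }
    data.frame(
      site_season = w$site_season, crop = w$crop,
      et_total = g(function(m, v) season_total(m, v, full_month), "et"),
      t_total = g(function(m, v) season_total(m, v, full_month), "transpiration"),
      et_daily_mean = g(season_daily_mean, "et"),
      t_daily_mean = g(season_daily_mean, "transpiration"),
      wue_mean = g(season_daily_mean, "wue"),
      wue_t_mean = g(season_daily_mean, "wue_t"),
      months_used = length(unique(mm$month)))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
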