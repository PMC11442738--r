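#' Normalized difference vegetation index
#'
#' `(nir - red) / (nir + red)` from surface reflectances. Records where
#' `red + nir == 0` are undefined and returned as `NA` (the caller drops
#' them); a message reports how many.
#'
#' @param red,nir Surface reflectances, >= 0, equal length.
#' @param verbose Report undefined records (default `TRUE`).
#' @return NDVI values in \[-1, 1\] (`NA` where undefined).
#' @export
compute_ndvi <- function(red, nir, verbose = TRUE) {
  if (length(red) != length(nir)) stop("`red` and `nir` must have equal length")
  if (any(red < 0, na.rm = TRUE) || any(nir < 0, na.rm = TRUE))
    stop("reflectances must be >= 0")
  s <- red + nir
  bad <- !is.na(s) & s == 0
  if (verbose && any(bad))
    message(sum(bad), " NDVI record(s) undefined (red + nir = 0), set to NA")
  out <- (nir - red) / s
  out[bad] <- NA_real_
  out
}

#' Water-use efficiency from carbon uptake and water loss
#'
#' Mean of the available GPP sources (e.g. the two daily GPP products from
#' complementary satellite overpasses) divided by the mass flux of water,
#' giving g C per kg H2O. Records with `et_mass <= 0` are undefined and
#' returned as `NA` with a message.
#'
#' @param gpp Primary GPP source, g C m^-2 d^-1.
#' @param et_mass Water flux in kg H2O m^-2 d^-1 (numerically equal to ET in
#'   mm d^-1).
#' @param gpp2 Optional second GPP source, averaged with the first where
#'   both are present.
#' @param verbose Report undefined records (default `TRUE`).
#' @return WUE in g C per kg H2O.
#' @export
derive_wue <- function(gpp, et_mass, gpp2 = NULL, verbose = TRUE) {
  g <- if (is.null(gpp2)) gpp else rowMeans(cbind(gpp, gpp2), na.rm = TRUE)
  g[is.nan(g)] <- NA_real_
  if (length(g) != length(et_mass)) stop("GPP and ET lengths differ")
  bad <- !is.na(et_mass) & et_mass <= 0
  if (verbose && any(bad))
    message(sum(bad), " WUE record(s) undefined (ET <= 0), set to NA")
  out <- g / et_mass
  out[bad] <- NA_real_
  out
}

#' Convert a water flux to liters per hectare per day
#'
#' The canonical internal water unit is L ha^-1 d^-1, so that seasonal
#' totals read directly as liters per hectare. 1 mm of water over 1 ha is
#' 10,000 L. Latent-heat-flux inputs (W m^-2) are first converted to depth
#' using `86400 s d^-1 / (lambda * 1e6 J kg^-1)` mm per W m^-2 with
#' `lambda = 2.45` MJ kg^-1 by default.
#'
#' @param value Flux values, >= 0.
#' @param unit One of `"mm_per_day"`, `"W_per_m2"`, `"L_per_ha_day"`.
#' @param latent_heat_mj_per_kg Latent heat of vaporization, MJ kg^-1.
#' @return Values in L ha^-1 d^-1.
#' @examples
#' to_liters_per_ha(1, "mm_per_day")   # 10,000
#' to_liters_per_ha(28.4, "W_per_m2")  # about 10,015
#' @export
to_liters_per_ha <- function(value, unit = c("mm_per_day", "W_per_m2",
                                             "L_per_ha_day"),
                             latent_heat_mj_per_kg = 2.45) {
  unit <- match.arg(unit)
  if (any(value < 0, na.rm = TRUE)) stop("`value` must be >= 0")
  switch(unit,
         mm_per_day = value * 1e4,
         W_per_m2 = value * 86400 / (latent_heat_mj_per_kg * 1e6) * 1e4,
         L_per_ha_day = value)
}

#' Partition ET and WUE into their transpiration-only components
#'
#' Multiplies each record's ET and WUE by that day's canopy fraction:
#' `transpiration = et * canopy_fraction` and
#' `wue_t = wue * canopy_fraction`. Under a canopy fraction in \[0, 1\] this
#' bounds transpiration by ET. Records with a canopy fraction outside
#' \[0, 1\] are rejected (dropped with a warning).
#'
#' @param series Data frame with columns `et`, `canopy_fraction` and
#'   optionally `wue`.
#' @return The data frame with `transpiration` (same unit as `et`) and,
#'   when `wue` is present, `wue_t` columns added; rows with `NA` canopy
#'   fraction keep `NA` partitioned values.
#' @export
partition_canopy <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("et", "canopy_fraction") %in% names(series)))
  fc <- series$canopy_fraction
  bad <- !is.na(fc) & (fc < 0 | fc > 1)
  if (any(bad)) {
    warning(sum(bad), " record(s) with canopy fraction outside [0, 1] rejected")
    series <- series[!bad, , drop = FALSE]
    fc <- series$canopy_fraction
  }
  series$transpiration <- series$et * fc
  if ("wue" %in% names(series)) series$wue_t <- series$wue * fc
  series
}

#' Build a per-field daily flux series from zonal statistics
#'
#' Pivots the long [zonal_daily_stats()] table to one row per field x day
#' and derives the analysis variables: NDVI from `red`/`nir`, canopy
#' fraction (directly, or mapped from NDVI when no canopy product exists),
#' WUE (preferring the sensor's own WUE product, falling back to the
#' GPP/ET quotient), ET converted to L ha^-1 d^-1, and the
#' canopy-partitioned `transpiration` and `wue_t`.
#'
#' Canopy products are sparser than ET products, so "that day's canopy
#' fraction" is operationalized with a pairing tolerance: an ET day without
#' a canopy observation borrows the nearest one within
#' `pairing_window_days` days (ties to the earlier day); beyond the window
#' the day's partitioned values stay `NA`.
#'
#' @param stats Long data frame from [zonal_daily_stats()] (after
#'   [drop_empty()]), with variables among `et`, `canopy`, `wue`, `gpp`,
#'   `gpp2`, `red`, `nir`.
#' @param et_unit Unit of the `et` variable (see [to_liters_per_ha()]).
#' @param canopy_unit `"fraction"` (\[0, 1\]) or `"percent"` (\[0, 100\],
#'   divided by 100 on input).
#' @param pairing_window_days Maximum day offset for canopy/ET pairing.
#' @param ndvi_to_canopy How to fill canopy fraction from NDVI when no
#'   canopy product exists: `"none"`, `"direct"` (NDVI clipped to \[0, 1\])
#'   or `"rescale"` (linear map from `ndvi_range` to \[0, 1\], clipped).
#' @param ndvi_range Length-2 `c(min, max)` for `"rescale"`.
#' @param latent_heat_mj_per_kg Passed to [to_liters_per_ha()].
#' @param verbose Report dropped/undefined records (default `TRUE`).
#' @return Data frame with one row per field x day: `field_id`, `crop`,
#'   `date`, `et` (L ha^-1 d^-1), `et_mm`, `canopy_fraction`, `gpp`, `wue`,
#'   `ndvi`, `transpiration` (L ha^-1 d^-1), `wue_t`.
#' @export
flux_series <- function(stats, et_unit = "mm_per_day",
                        canopy_unit = c("fraction", "percent"),
                        pairing_window_days = 8,
                        ndvi_to_canopy = c("none", "direct", "rescale"),
                        ndvi_range = c(0.1, 0.8),
                        latent_heat_mj_per_kg = 2.45,
                        verbose = TRUE) {
  stopifnot(is.data.frame(stats),
            all(c("field_id", "crop", "date", "variable", "mean") %in% names(stats)))
  canopy_unit <- match.arg(canopy_unit)
  ndvi_to_canopy <- match.arg(ndvi_to_canopy)
  if (!"et" %in% stats$variable) stop("`stats` must contain an 'et' variable")

  wide <- stats::reshape(
    stats[, c("field_id", "crop", "date", "variable", "mean")],
    direction = "wide", idvar = c("field_id", "crop", "date"),
    timevar = "variable")
  names(wide) <- sub("^mean\\.", "", names(wide))
  attr(wide, "reshapeWide") <- NULL
  wide <- wide[order(wide$field_id, wide$date), , drop = FALSE]
  rownames(wide) <- NULL
  has <- function(v) v %in% names(wide)
  col <- function(v) if (has(v)) wide[[v]] else rep(NA_real_, nrow(wide))

  ndvi <- if (has("red") && has("nir"))
    compute_ndvi(col("red"), col("nir"), verbose = verbose)
  else rep(NA_real_, nrow(wide))

  fc <- col("canopy")
  if (canopy_unit == "percent") fc <- fc / 100
  if (all(is.na(fc)) && ndvi_to_canopy != "none") {
    fc <- switch(ndvi_to_canopy,
                 direct = pmin(pmax(ndvi, 0), 1),
                 rescale = pmin(pmax((ndvi - ndvi_range[1]) /
                                       (ndvi_range[2] - ndvi_range[1]), 0), 1))
  }

  # nearest-neighbour canopy pairing within the tolerance window, per field
  need <- which(!is.na(wide$et) & is.na(fc))
  if (length(need) && any(!is.na(fc))) {
    for (f in unique(wide$field_id[need])) {
      rows_f <- which(wide$field_id == f)
      obs <- rows_f[!is.na(fc[rows_f])]
      if (!length(obs)) next
      for (i in intersect(need, rows_f)) {
        dd <- abs(as.numeric(wide$date[obs] - wide$date[i]))
        j <- which.min(dd)
        if (dd[j] <= pairing_window_days) fc[i] <- fc[obs[j]]
      }
    }
  }

  et_mm <- switch(et_unit,
                  mm_per_day = col("et"),
                  W_per_m2 = col("et") * 86400 / (latent_heat_mj_per_kg * 1e6),
                  L_per_ha_day = col("et") / 1e4,
                  stop("unknown `et_unit`: ", et_unit))
  et_l <- to_liters_per_ha(et_mm, "mm_per_day")

  gpp <- col("gpp")
  wue <- col("wue")
  if (any(is.na(wue)) && (has("gpp") || has("gpp2"))) {
    wue_q <- derive_wue(gpp, et_mm, gpp2 = if (has("gpp2")) col("gpp2"),
                        verbose = verbose)
    wue <- ifelse(is.na(wue), wue_q, wue)
  }

  out <- data.frame(field_id = wide$field_id, crop = wide$crop,
                    date = wide$date, et = et_l, et_mm = et_mm,
                    canopy_fraction = fc, gpp = gpp, wue = wue, ndvi = ndvi)
  partition_canopy(out)
}
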