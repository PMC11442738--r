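#' Regional seasonal water consumption
#'
#' Scales a per-hectare season total to a regional inventory area.
#'
#' @param per_ha_season_total Seasonal water use, L ha^-1 per season (>= 0,
#'   vectorized).
#' @param area_ha Cultivated area, hectares (>= 0).
#' @return Liters per season for the region.
#' @export
regional_consumption <- function(per_ha_season_total, area_ha) {
  if (any(per_ha_season_total < 0, na.rm = TRUE) || any(area_ha < 0, na.rm = TRUE))
    stop("inputs must be >= 0")
  per_ha_season_total * area_ha
}

#' Water savings implied by a crop:chia ratio
#'
#' Replacing a fraction `w` of a crop's regional consumption with chia
#' scales the replaced share by `1/R` (chia uses `1/R` of the crop's
#' water when the crop:chia ratio is `R`), saving
#' `w * regional_total * (1 - 1/R)` liters. Negative savings (R < 1, chia
#' uses more) are reported, not clamped, as happens for some
#' transpiration-basis worst cases.
#'
#' @param regional_total Regional seasonal consumption, liters.
#' @param ratio Crop:chia ratio, > 0 (use the min/mean/max across seasons
#'   for the scenario cases).
#' @param w Replacement weight in \[0, 1\].
#' @return Liters saved per season (negative if chia uses more).
#' @export
savings_from_ratio <- function(regional_total, ratio, w) {
  if (any(ratio <= 0, na.rm = TRUE)) stop("`ratio` must be > 0")
  if (any(w < 0 | w > 1, na.rm = TRUE)) stop("`w` must be in [0, 1]")
  w * regional_total * (1 - 1 / ratio)
}

#' Water savings from a per-hectare savings figure
#'
#' Entry point for worked examples where the per-hectare savings
#' (crop minus chia seasonal use per hectare) is already known:
#' `w * area_ha * per_ha_savings`.
#'
#' @param per_ha_savings Savings per replaced hectare, L ha^-1 per season.
#' @param area_ha Regional crop area, hectares.
#' @param w Replacement weight in \[0, 1\].
#' @return Liters saved per season.
#' @examples
#' # replacing 10% of 14,100 ha saving 130,900 L/ha
#' savings_from_per_ha(130900, 14100, 0.10)
#' @export
savings_from_per_ha <- function(per_ha_savings, area_ha, w) {
  if (any(w < 0 | w > 1, na.rm = TRUE)) stop("`w` must be in [0, 1]")
  w * area_ha * per_ha_savings
}

#' Household equivalence of a water saving
#'
#' Number of households whose annual consumption equals the saving,
#' rounded down. The default annual figure of 142,000 L per household per
#' year is a derived constant, not a sourced statistic: it is back-computed
#' so that a saving of 184.6 million liters corresponds to 1,300
#' households.
#'
#' @param savings_liters Liters saved (>= 0 for a meaningful count).
#' @param annual_household_use_liters Annual household consumption, L
#'   (> 0).
#' @return Whole number of households.
#' @export
household_equivalent <- function(savings_liters,
                                 annual_household_use_liters = 142000) {
  if (any(annual_household_use_liters <= 0))
    stop("`annual_household_use_liters` must be > 0")
  floor(savings_liters / annual_household_use_liters)
}

#' Batch water-savings projection over a regional inventory
#'
#' Applies [savings_from_per_ha()] to every crop in an inventory at each
#' replacement weight, and appends a combined `"all"` row per weight.
#'
#' @param inventory Data frame with columns `crop`, `area_ha` and
#'   `per_ha_savings_l` (see [swus_chia_example()]).
#' @param weights Replacement weights in \[0, 1\].
#' @return Data frame with columns `crop`, `weight`, `area_ha`,
#'   `per_ha_savings_l`, `total_savings_l`.
#' @export
project_savings <- function(inventory, weights = c(0.1, 0.25, 0.5, 1)) {
  stopifnot(is.data.frame(inventory),
            all(c("crop", "area_ha", "per_ha_savings_l") %in% names(inventory)))
  out <- lapply(weights, function(w) {
    tot <- savings_from_per_ha(inventory$per_ha_savings_l,
                               inventory$area_ha, w)
    rbind(data.frame(crop = inventory$crop, weight = w,
                     area_ha = inventory$area_ha,
                     per_ha_savings_l = inventory$per_ha_savings_l,
                     total_savings_l = tot),
          data.frame(crop = "all", weight = w,
                     area_ha = sum(inventory$area_ha),
                     per_ha_savings_l = sum(inventory$per_ha_savings_l),
                     total_savings_l = sum(tot)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Worked-example inventory for the chia-viable Southwest US region
#'
#' The 2022 crop areas inside the chia-viable region of the Southwest
#' United States and the mean ET-based per-hectare savings from replacing
#' each crop with chia, used as fixed inputs by the regional projection
#' worked example.
#'
#' @return Data frame with columns `crop`, `area_ha`, `per_ha_savings_l`.
#' @examples
#' project_savings(swus_chia_example(), weights = 0.10)
#' @export
swus_chia_example <- function() {
  data.frame(crop = c("alfalfa", "corn", "soybean"),
             area_ha = c(14100, 5390, 14),
             per_ha_savings_l = c(130900, 102400, 121800))
}

#' Best/mean/worst economic scenarios for replacing a crop with chia
#'
#' Gross income per hectare of each crop is a range (yield range times
#' price range); the water saved by growing chia instead is credited at an
#' agricultural water price. Scenarios are built adversarially for chia:
#' the best case matches chia's highest gross against the crop's lowest
#' gross net of the largest water credit, and the worst case the reverse;
#' the mean case uses the midpoints of the yield and price ranges and the
#' mean water saving. By construction `delta_worst <= delta_mean <=
#' delta_best`.
#'
#' @param crop Crop label being replaced.
#' @param chia_yield,crop_yield Length-2 `c(min, max)` yields, t ha^-1.
#' @param chia_price,crop_price Length-2 `c(min, max)` prices, $ t^-1.
#' @param savings_range Length-3 `c(min, mean, max)` per-hectare seasonal
#'   water savings, L ha^-1 (negative entries allowed: chia may use more
#'   water in a worst case).
#' @param water_price Agricultural water price, $ L^-1.
#' @param area_ha Regional crop area for the weighted totals (default 1).
#' @param weights Replacement weights for the totals.
#' @return An object of class `economic_scenario` with `delta_worst`,
#'   `delta_mean`, `delta_best` ($ per replaced hectare) and a `totals`
#'   data frame (`weight`, scenario deltas scaled by `weight * area_ha`).
#' @export
economic_scenarios <- function(crop, chia_yield, chia_price,
                               crop_yield, crop_price,
                               savings_range, water_price,
                               area_ha = 1, weights = 1) {
  rng <- function(x, what) {
    if (length(x) != 2L || any(x < 0) || x[1] > x[2])
      stop("`", what, "` must be a nonnegative c(min, max) range")
    x
  }
  chia_yield <- rng(chia_yield, "chia_yield")
  chia_price <- rng(chia_price, "chia_price")
  crop_yield <- rng(crop_yield, "crop_yield")
  crop_price <- rng(crop_price, "crop_price")
  if (length(savings_range) != 3L || is.unsorted(savings_range))
    stop("`savings_range` must be c(min, mean, max), nondecreasing")
  if (water_price < 0) stop("`water_price` must be >= 0")

  gross <- function(y, p) c(min = y[1] * p[1],
                            mean = mean(y) * mean(p),
                            max = y[2] * p[2])
  chia_g <- gross(chia_yield, chia_price)
  crop_g <- gross(crop_yield, crop_price)
  credit <- savings_range * water_price  # $/ha water cost avoided by chia

  delta_best <- chia_g["max"] - (crop_g["min"] - credit[3])
  delta_mean <- chia_g["mean"] - (crop_g["mean"] - credit[2])
  delta_worst <- chia_g["min"] - (crop_g["max"] - credit[1])

  totals <- do.call(rbind, lapply(weights, function(w) {
    data.frame(weight = w,
               total_worst = unname(delta_worst) * w * area_ha,
               total_mean = unname(delta_mean) * w * area_ha,
               total_best = unname(delta_best) * w * area_ha)
  }))
  structure(list(crop = crop,
                 delta_worst = unname(delta_worst),
                 delta_mean = unname(delta_mean),
                 delta_best = unname(delta_best),
                 chia_gross = chia_g, crop_gross = crop_g,
                 water_credit = stats::setNames(credit, c("min", "mean", "max")),
                 area_ha = area_ha, totals = totals),
            class = "economic_scenario")
}

#' @export
print.economic_scenario <- function(x, ...) {
  cat(sprintf("<economic_scenario> replacing %s with chia\n", x$crop))
  cat(sprintf("  change in profit per replaced hectare: worst %s, mean %s, best %s\n",
              fmt_usd(x$delta_worst), fmt_usd(x$delta_mean),
              fmt_usd(x$delta_best)))
  invisible(x)
}

fmt_usd <- function(x) {
  sprintf("%s$%s", if (x < 0) "-" else "",
          format(round(abs(x)), big.mark = ",", scientific = FALSE))
}

#' Round to significant figures for report display
#'
#' Large liter totals are displayed at 4 significant figures in reports;
#' raw values are always kept unrounded in the data frames.
#'
#' @param x Numeric vector.
#' @param sig Significant figures (default 4).
#' @return Rounded values.
#' @export
report_round <- function(x, sig = 4) signif(x, sig)
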