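# Shared fixture builders and independent oracles for the suite.

# Minimal raster stack compatible with zonal_daily_stats(): named list of
# pixels-x-days matrices sharing one date vector.
make_stack <- function(grid, values, dates) {
  list(grid = grid,
       layers = lapply(values, function(m) list(dates = dates, values = m)))
}

# Independent scalar crossing-number point-in-polygon test (different
# comparison convention from the package's vectorized even-odd routine;
# they agree for points off the boundary).
oracle_pip <- function(px, py, coords) {
  n <- nrow(coords)
  cnt <- 0L
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    x1 <- coords[k, 1]; y1 <- coords[k, 2]
    x2 <- coords[k2, 1]; y2 <- coords[k2, 2]
    if ((y1 <= py && y2 > py) || (y2 <= py && y1 > py)) {
      t <- (py - y1) / (y2 - y1)
      if (px < x1 + t * (x2 - x1)) cnt <- cnt + 1L
    }
  }
  cnt %% 2L == 1L
}

# Star-shaped simple polygon with continuous random vertices (boundary
# never passes exactly through a pixel center).
random_polygon <- function(n, cx, cy, rmin, rmax) {
  ang <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, rmin, rmax)
  cbind(cx + r * cos(ang), cy + r * sin(ang))
}

# Small two-crop noise-free scene used by several suites.
demo_profiles <- function(noise = 0, miss = 0, r_scale = 1.25) {
  list(
    crop_profile("chia", "2022-06-05", "2022-09-20", et_base = 2.5,
                 et_peak = 3.5, pixel_noise_sd = noise,
                 missing_day_rate = miss),
    crop_profile("crop", "2022-06-05", "2022-09-20",
                 et_base = 2.5 * r_scale, et_peak = 3.5 * r_scale,
                 pixel_noise_sd = noise, missing_day_rate = miss))
}
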