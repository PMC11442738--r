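test_that("noise-free scenes carry exact curve values and are seed-deterministic", {
  p <- crop_profile("chia", "2022-06-01", "2022-08-31",
                    pixel_noise_sd = 0, missing_day_rate = 0)
  g <- grid_spec(8, 8)
  sc <- generate_site_season(p, g, c("2022-06-01", "2022-08-31"), seed = 11)

  # every field pixel equals the crop's curve value that day
  fid <- which(as.vector(!is.na(sc$class_map)))
  et <- sc$layers$et
  expect_equal(et$values[fid, ],
               matrix(rep(et_curve(p, et$dates), each = length(fid)),
                      length(fid)),
               tolerance = 0)
  fc <- sc$layers$canopy
  expect_equal(fc$values[fid, ],
               matrix(rep(canopy_curve(p, fc$dates), each = length(fid)),
                      length(fid)),
               tolerance = 0)
  # GPP layer consistent with WUE * ET by construction
  expect_equal(sc$layers$gpp$values, sc$layers$wue$values * sc$layers$et$values)

  sc2 <- generate_site_season(p, g, c("2022-06-01", "2022-08-31"), seed = 11)
  expect_identical(sc, sc2)
  # a different seed changes the stochastic parts (here only temperature,
  # since the profile is noise-free)
  sc3 <- generate_site_season(p, g, c("2022-06-01", "2022-08-31"), seed = 12)
  expect_false(identical(sc$temperature$tair_c, sc3$temperature$tair_c))
  p_noisy <- crop_profile("chia", "2022-06-01", "2022-08-31",
                          pixel_noise_sd = 1, missing_day_rate = 0)
  n1 <- generate_site_season(p_noisy, g, c("2022-06-01", "2022-08-31"), seed = 11)
  n2 <- generate_site_season(p_noisy, g, c("2022-06-01", "2022-08-31"), seed = 12)
  expect_false(identical(n1$layers$et$values, n2$layers$et$values))
})

test_that("field-mean ET at 10,000 pixels respects the CLT bound", {
  p <- crop_profile("big", "2022-07-01", "2022-07-05", et_base = 5,
                    et_peak = 2, pixel_noise_sd = 1, missing_day_rate = 0)
  g <- grid_spec(102, 102)  # one field of 100 x 100 = 10,000 pixels
  sc <- generate_site_season(p, g, c("2022-07-01", "2022-07-05"), seed = 4)
  st <- zonal_daily_stats(sc, variables = "et")
  expect_true(all(st$n_pixels == 10000L))
  truth <- et_curve(p, st$date)
  expect_true(all(abs(st$mean - truth) <= 3 * (1 / sqrt(10000))))
})

test_that("true_season_ratio matches identity, constant-curve and brute-force cases", {
  w <- c("2022-06-01", "2022-08-31")
  a <- crop_profile("a", w[1], w[2], et_base = 5, et_peak = 0)
  expect_equal(true_season_ratio(a, a, w), 1.0)

  b <- crop_profile("b", w[1], w[2], et_base = 4, et_peak = 0)
  expect_equal(true_season_ratio(a, b, w), 1.25)

  # asymmetric peaked curves vs day-by-day summation oracle
  p1 <- crop_profile("p1", w[1], w[2], et_base = 1.2, et_peak = 5,
                     peak_day = "2022-06-20", et_width = 18)
  p2 <- crop_profile("p2", w[1], w[2], et_base = 2.0, et_peak = 3,
                     peak_day = "2022-08-05", et_width = 40)
  days <- seq(as.Date(w[1]), as.Date(w[2]), by = "day")
  oracle <- sum(p1$et_base + p1$et_peak *
                  exp(-0.5 * (as.numeric(days - p1$peak_day) / p1$et_width)^2)) /
    sum(p2$et_base + p2$et_peak *
          exp(-0.5 * (as.numeric(days - p2$peak_day) / p2$et_width)^2))
  expect_equal(true_season_ratio(p1, p2, w), oracle, tolerance = 1e-12)

  flat0 <- crop_profile("z", w[1], w[2], et_base = 0, et_peak = 0)
  expect_error(true_season_ratio(a, flat0, w), "zero")
})

test_that("generated layers stay physical across seeds and noise levels", {
  for (seed in 1:5) {
    p <- crop_profile("x", "2022-06-01", "2022-07-31", pixel_noise_sd = 2,
                      missing_day_rate = 0.4)
    sc <- generate_site_season(p, grid_spec(6, 6),
                               c("2022-06-01", "2022-07-31"), seed = seed)
    expect_true(all(sc$layers$et$values >= 0))
    expect_true(all(sc$layers$canopy$values >= 0 & sc$layers$canopy$values <= 1))
    expect_true(!is.unsorted(sc$layers$et$dates))
    expect_false(anyDuplicated(sc$dates) > 0)
  }
})

test_that("missing days thin coverage without shifting the expected monthly mean", {
  p_dense <- crop_profile("x", "2022-06-01", "2022-06-30", et_base = 2,
                          et_peak = 3, pixel_noise_sd = 0,
                          missing_day_rate = 0)
  g <- grid_spec(6, 6)
  w <- season_window("x", "S", "2022-06-01", "2022-06-30")
  dense <- monthly_means(flux_series(drop_empty(
    zonal_daily_stats(generate_site_season(p_dense, g,
                                           c("2022-06-01", "2022-06-30"),
                                           seed = 1, variables = "et")),
    verbose = FALSE), verbose = FALSE), w, variables = "et")$mean

  p_gap <- crop_profile("x", "2022-06-01", "2022-06-30", et_base = 2,
                        et_peak = 3, pixel_noise_sd = 0,
                        missing_day_rate = 0.5)
  sims <- sapply(1:40, function(s) {
    sc <- generate_site_season(p_gap, g, c("2022-06-01", "2022-06-30"),
                               seed = 100 + s, variables = "et")
    st <- drop_empty(zonal_daily_stats(sc), verbose = FALSE)
    monthly_means(flux_series(st, verbose = FALSE), w,
                  variables = "et")$mean
  })
  # subsampled means scatter around the dense value without systematic shift
  expect_gt(sd(sims), 0)
  expect_lt(abs(mean(sims) - dense), 4 * sd(sims) / sqrt(length(sims)))
})

test_that("generator rejects invalid inputs", {
  p <- crop_profile("x", "2022-06-01", "2022-06-30")
  expect_error(generate_site_season(list(), grid_spec(6, 6),
                                    c("2022-06-01", "2022-06-30"), seed = 1),
               "empty")
  expect_error(grid_spec(0, 5), "positive")
  expect_error(generate_site_season(p, grid_spec(6, 6),
                                    c("2022-06-10", "2022-06-30"), seed = 1),
               "cover")
  expect_error(generate_site_season(p, grid_spec(6, 6),
                                    c("2022-06-01", "2022-06-30")),
               "seed")
  expect_error(crop_profile("x", "2022-06-30", "2022-06-01"), "precede")
  expect_error(crop_profile("x", "2022-06-01", "2022-06-30",
                            missing_day_rate = 1.5), "missing_day_rate")
})
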