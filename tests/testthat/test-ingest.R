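test_that("zonal means match hand-computed small cases", {
  g <- grid_spec(3, 3, pixel_m = 10)
  vals <- matrix(0, 9, 1)
  vals[5, 1] <- 7  # pixel (row 2, col 2), center (15, 15)
  stack <- make_stack(g, list(et = vals), as.Date("2022-06-01"))

  one <- field_boundary("f1", "corn", cbind(c(10, 20, 20, 10), c(10, 10, 20, 20)))
  st <- zonal_daily_stats(stack, list(one))
  expect_equal(st$mean, 7.0)
  expect_equal(st$n_pixels, 1L)

  # rows 1:2 x cols 1:2 hold {2, 4, 6, 8}
  vals2 <- matrix(0, 9, 1); vals2[c(1, 2, 4, 5), 1] <- c(2, 4, 6, 8)
  stack2 <- make_stack(g, list(et = vals2), as.Date("2022-06-01"))
  four <- field_boundary("f2", "corn", cbind(c(0, 20, 20, 0), c(0, 0, 20, 20)))
  st2 <- zonal_daily_stats(stack2, list(four))
  expect_equal(st2$mean, 5.0)
  expect_equal(st2$n_pixels, 4L)
})

test_that("zonal means agree with a brute-force pixel-center loop and mgcv", {
  set.seed(71)
  g <- grid_spec(20, 20, pixel_m = 70)
  ctr <- pixel_centers(g)
  for (i in 1:5) {
    vals <- matrix(rnorm(400), 400, 1)
    stack <- make_stack(g, list(et = vals), as.Date("2022-06-01"))
    poly <- random_polygon(9, cx = 700, cy = 700, rmin = 200, rmax = 650)
    b <- field_boundary("f", "x", poly)
    st <- zonal_daily_stats(stack, list(b))
    inside <- vapply(seq_len(400),
                     function(k) oracle_pip(ctr$x[k], ctr$y[k], poly),
                     logical(1))
    expect_equal(st$mean, mean(vals[inside, 1]), tolerance = 1e-12)
    expect_equal(st$n_pixels, sum(inside))
    if (requireNamespace("mgcv", quietly = TRUE)) {
      io <- mgcv::in.out(rbind(poly, poly[1, ]), cbind(ctr$x, ctr$y))
      expect_equal(point_in_polygon(ctr$x, ctr$y, poly), as.logical(io))
    }
  }
})

test_that("zonal stats are permutation-invariant and conserve masked totals", {
  p <- demo_profiles(noise = 1, miss = 0)
  sc <- generate_site_season(p, grid_spec(10, 10),
                             c("2022-06-05", "2022-09-20"), seed = 3,
                             variables = "et")
  st1 <- zonal_daily_stats(sc)
  st2 <- zonal_daily_stats(sc, boundaries = rev(sc$fields))
  key <- function(d) d[order(d$field_id, d$variable, d$date), ]
  expect_equal(key(st1), key(st2), ignore_attr = TRUE)

  # conservation: sum over fields of mean * count equals the total over all
  # field pixels, per date
  ctr <- pixel_centers(sc$grid)
  inside_any <- Reduce(`|`, lapply(sc$fields, function(b)
    point_in_polygon(ctr$x, ctr$y, b$coords)))
  totals <- colSums(sc$layers$et$values[inside_any, , drop = FALSE])
  agg <- tapply(st1$mean * st1$n_pixels, st1$date, sum)
  expect_equal(as.vector(agg[as.character(sc$layers$et$dates)]),
               unname(totals), tolerance = 1e-12)
})

test_that("a boundary outside the grid is flagged, not silently dropped", {
  g <- grid_spec(3, 3, pixel_m = 10)
  stack <- make_stack(g, list(et = matrix(1, 9, 1)), as.Date("2022-06-01"))
  far <- field_boundary("far", "x", cbind(c(100, 110, 110), c(100, 100, 110)))
  expect_warning(st <- zonal_daily_stats(stack, list(far)), "no pixel centers")
  expect_equal(st$n_pixels, 0L)
  expect_true(is.na(st$mean))
})

test_that("class-area tabulation counts pixels, respects clipping, and handles empty maps", {
  cm <- matrix(NA_character_, 10, 10)
  cm[1:10, 1:10] <- "corn"
  tab <- tabulate_class_areas(cm, 0.49)
  expect_equal(tab$pixel_count, 100L)
  expect_equal(tab$area_ha, 49.0)

  expect_equal(nrow(tabulate_class_areas(matrix(NA_character_, 3, 3), 0.49)), 0L)

  set.seed(5)
  cm3 <- matrix(sample(c("corn", "alfalfa", "soy", NA), 100, replace = TRUE), 10, 10)
  tab3 <- tabulate_class_areas(cm3, 0.49)
  for (cr in tab3$crop)  # exhaustive-scan oracle
    expect_equal(tab3$pixel_count[tab3$crop == cr],
                 sum(cm3 == cr, na.rm = TRUE))

  # clip-then-tabulate == tabulate-then-subset to in-region pixels
  g <- grid_spec(10, 10, pixel_m = 10)
  region <- cbind(c(0, 50, 50, 0), c(0, 0, 50, 50))  # lower-left 5x5 block
  tab_clip <- tabulate_class_areas(cm3, 1, grid = g, region = region)
  sub <- cm3[1:5, 1:5]
  for (cr in tab_clip$crop)
    expect_equal(tab_clip$pixel_count[tab_clip$crop == cr],
                 sum(sub == cr, na.rm = TRUE))
})

test_that("drop_empty removes only empty or non-finite records", {
  rec <- data.frame(field_id = "f", crop = "c", date = as.Date("2022-06-01") + 0:4,
                    variable = "et", mean = c(1, 2, NA, 4, 5),
                    n_pixels = c(3L, 3L, 0L, 3L, 3L))
  expect_message(out <- drop_empty(rec), "1 empty")
  expect_equal(nrow(out), 4L)
  expect_true(all(out$n_pixels >= 1L))

  ok <- rec[rec$n_pixels > 0, ]
  expect_identical(drop_empty(ok, verbose = FALSE), ok)
})

test_that("an empty month for one variable is absent downstream", {
  dates <- seq(as.Date("2022-06-01"), as.Date("2022-07-31"), by = "day")
  g <- grid_spec(3, 3, pixel_m = 10)
  vals <- matrix(5, 9, length(dates))
  vals[, format(dates, "%m") == "07"] <- NA  # July nodata
  stack <- make_stack(g, list(et = vals), dates)
  b <- field_boundary("f", "corn", cbind(c(0, 30, 30, 0), c(0, 0, 30, 30)))
  st <- drop_empty(zonal_daily_stats(stack, list(b)), verbose = FALSE)
  fl <- flux_series(st, verbose = FALSE)
  w <- season_window("corn", "S", "2022-06-01", "2022-07-31")
  expect_message(mm <- monthly_means(fl, w, variables = "et"), "2022-07")
  expect_equal(mm$month, "2022-06")
})
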